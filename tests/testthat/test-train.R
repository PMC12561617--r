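test_that("early stopping fires after `patience` epochs without improvement", {
  # mocked validation losses: best at epoch 2, patience 2 => stop at epoch 4
  losses <- c(1.0, 0.9, 0.95, 0.96)
  states <- lapply(seq_along(losses), function(t)
    ansaedge:::early_stop_state(losses[1:t], patience = 2))
  expect_equal(sapply(states, `[[`, "stop"), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(states[[4]]$best_epoch, 2)
  # monotone improvement never stops
  expect_false(ansaedge:::early_stop_state(c(1, 0.9, 0.8, 0.7), 2)$stop)
})

test_that("training is deterministic under a fixed seed and restores best weights", {
  imgs <- generate_synthetic_dataset(8, num_classes = 3, size = 16, seed = 77)
  parts <- list(train = imgs[seq(1, 24, by = 2)], val = imgs[seq(2, 24, by = 2)])
  cfg <- train_config(learning_rate = 1e-3, batch_size = 8, max_epochs = 4,
                      patience = 3, seed = 5)
  run <- function() {
    net <- build_model(tiny_attention_spec(), seed = 5)
    train_network(net, parts, cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(lapply(f1$net$layers, `[[`, "W"),
                   lapply(f2$net$layers, `[[`, "W"))
  expect_equal(f1$history, f2$history)

  # returned weights achieve the minimum validation loss seen in training
  vb <- ansaedge:::as_image_batch(parts$val, levels = f1$levels)
  expect_equal(ansaedge:::evaluate_loss(f1$net, vb)$loss,
               min(f1$history$val_loss), tolerance = 1e-8)
  expect_error(train_network(build_model(tiny_attention_spec(), seed = 1),
                             list(train = list(), val = imgs[1:2]), cfg),
               "empty training")
})

test_that("evaluation wires predictions into the confusion matrix correctly", {
  imgs <- generate_synthetic_dataset(5, num_classes = 3, size = 16, seed = 6)
  net <- build_model(tiny_attention_spec(), seed = 6)
  ev <- evaluate_model(net, imgs)
  expect_equal(sum(ev$confusion), 15)
  expect_equal(rowSums(ev$confusion), c(glioma = 5, meningioma = 5,
                                        pituitary = 5))
  expect_equal(ev$metrics$accuracy, sum(diag(ev$confusion)) / 15)
})

test_that("Monte Carlo summaries collapse to zero spread under forced seeds", {
  imgs <- generate_synthetic_dataset(6, num_classes = 3, size = 16, seed = 8)
  spec <- tiny_attention_spec()
  cfg <- train_config(learning_rate = 1e-3, batch_size = 9, max_epochs = 2,
                      patience = 1)
  sm <- suppressWarnings(monte_carlo(spec, imgs, runs = 3, seeds = c(2, 2, 2),
                                     cfg = cfg))
  expect_length(sm$reports, 3)
  expect_true(all(sm$sd < 1e-12))
  expect_warning(monte_carlo(spec, imgs, runs = 2, seeds = c(1, 1), cfg = cfg),
                 "duplicate")

  # distinct seeds: mean/sd equal an independent recomputation
  sm2 <- monte_carlo(spec, imgs, runs = 2, seeds = c(1, 2), cfg = cfg)
  accs <- sapply(sm2$reports, `[[`, "accuracy")
  expect_equal(unname(sm2$mean["accuracy"]), mean(accs))
  expect_equal(unname(sm2$sd["accuracy"]), stats::sd(accs))
})

test_that("five-fold cross-validation tests every sample exactly once", {
  imgs <- generate_synthetic_dataset(10, num_classes = 3, size = 16, seed = 9)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 16, max_epochs = 2,
                      patience = 1)
  sm <- five_fold_cv(tiny_attention_spec(), imgs, seed = 4, cfg = cfg)
  expect_length(sm$reports, 5)
  expect_equal(attr(sm, "n_tested"), 30L)
  counts <- sapply(sm$reports, function(r) sum(r$per_class$tp +
    r$per_class$fp + r$per_class$fn + r$per_class$tn) / nrow(r$per_class))
  expect_equal(sum(counts), 30)
})

test_that("head adaptation trains only the replacement output layer", {
  src <- generate_synthetic_dataset(8, num_classes = 3, size = 16, seed = 10)
  tgt <- generate_synthetic_dataset(8, num_classes = 4, size = 16, seed = 11)
  net <- build_model(tiny_attention_spec(3), seed = 10)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 8, max_epochs = 2,
                      patience = 1, seed = 3)
  fit <- train_network(net, list(train = src, val = src), cfg)

  tgt_parts <- list(train = tgt[1:20], val = tgt[21:26], test = tgt[27:32])
  ad <- adapt_head_and_eval(fit$net, tgt_parts, 4, cfg)
  expect_true(ad$trained)
  L <- length(ad$net$layers)
  expect_equal(nrow(ad$net$layers[[L]]$W), 4)
  for (i in seq_len(L - 1)) {
    l0 <- fit$net$layers[[i]]; l1 <- ad$net$layers[[i]]
    if (!is.null(l0$W)) expect_identical(l0$W, l1$W)
  }

  # matching class counts: evaluate directly, no training
  same <- adapt_head_and_eval(fit$net,
                              list(test = src[c(1, 2, 9, 10, 17, 18)]), 3, cfg)
  expect_false(same$trained)
  expect_identical(lapply(same$net$layers, `[[`, "W"),
                   lapply(fit$net$layers, `[[`, "W"))
  expect_error(adapt_head_and_eval(fit$net, tgt_parts, 2, cfg), "classes")
})

test_that("inference timing returns positive per-image milliseconds", {
  imgs <- generate_synthetic_dataset(4, num_classes = 3, size = 16, seed = 12)
  net <- build_model(tiny_attention_spec(), seed = 12)
  t1 <- inference_time_per_image(net, imgs, repeats = 2, warmup = 1)
  expect_true(is.finite(t1) && t1 > 0)
})
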