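make_k3_net <- function(input_size = 32) {
  build_model(model_spec(
    backbone_config(filters = c(64, 128, 32, 32),
                    kernel_sizes = c(3, 3, 3, 3),
                    input_size = input_size),
    num_classes = 3, head_hidden = 8), seed = 1)
}

test_that("depthwise-separable rewrite follows the closed parameter form", {
  net <- make_k3_net()
  r <- to_depthwise_separable(net)
  # conv2 is 64 -> 128 with K = 3: Cin K^2 + Cin Cout weights
  expect_equal(r$report$details$conv2$weights_after, 8768)
  expect_equal(r$report$details$conv2$weights_before, 64 * 128 * 9)
  for (nm in names(r$report$details)) {
    d <- r$report$details[[nm]]
    expect_lt(d$weights_after, d$weights_before)
  }
  # every backbone conv was split; 1x1 convs (none here) stay untouched
  types <- sapply(r$net$layers, `[[`, "name")
  expect_true(all(c("conv1_dw", "conv1_pw", "conv4_dw", "conv4_pw") %in% types))

  # forward shape is preserved
  x <- array(stats::runif(32 * 32 * 2), c(32, 32, 1, 2))
  expect_equal(dim(ansaedge:::net_forward(r$net, x)$out),
               dim(ansaedge:::net_forward(net, x)$out))

  # attention-block convs are untouched by default
  att <- build_model(reduced_spec(3, 32), seed = 1)
  ratt <- to_depthwise_separable(att)
  sabs_before <- sum(grepl("^sab", sapply(att$layers, `[[`, "name")))
  sabs_after <- sum(grepl("^sab", sapply(ratt$net$layers, `[[`, "name")))
  expect_equal(sabs_before, sabs_after)
})

test_that("reduced-feature-map rewrite shrinks filters and nothing else", {
  spec <- reference_attention_spec(3)
  red <- to_reduced_feature_maps(spec)
  expect_equal(red$backbone$filters, c(8L, 16L, 32L, 64L))
  expect_equal(red$backbone$kernel_sizes, spec$backbone$kernel_sizes)
  expect_equal(red$attention_blocks, spec$attention_blocks)
  n_full <- count_parameters(build_model(
    reference_attention_spec(3, backbone_config(input_size = 64)), seed = 1))
  n_red <- count_parameters(build_model(
    reference_attention_spec(3, backbone_config(filters = c(8, 16, 32, 64),
                                           input_size = 64)), seed = 1))
  expect_lt(n_red, n_full)
  # attention parameters do not depend on the filter counts
  att_params <- function(net) sum(sapply(net$layers, function(l)
    if (l$type == "l2sab") length(l$W) + length(l$b) else 0))
  expect_equal(
    att_params(build_model(reference_attention_spec(3,
      backbone_config(input_size = 64)), seed = 1)),
    att_params(build_model(reference_attention_spec(3,
      backbone_config(filters = c(8, 16, 32, 64), input_size = 64)),
      seed = 1)))
})

test_that("LoRA freezes bases, exposes r(d_in + d_out) factors, and is a no-op at init", {
  # closed form on a lone dense layer: 100 -> 50 at rank 4 gives 600
  net <- structure(list(spec = NULL,
                        layers = list(ansaedge:::layer_dense("fc", 100, 50))),
                   class = "ansa_net")
  r <- attach_lora(net, rank = 4)
  expect_equal(count_parameters(r$net, trainable_only = TRUE), 600L)
  expect_equal(r$report$trainable_after, 600L)
  expect_lt(r$report$trainable_after, r$report$params_before)

  set.seed(10)
  full <- build_model(tiny_attention_spec(), seed = 10)
  x <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
  base_logits <- ansaedge:::net_forward(full, x)$out
  # rank 2 exceeds the single-output l2-SAB convs, which clamp with a warning
  lr <- suppressWarnings(attach_lora(full, rank = 2))
  expect_equal(ansaedge:::net_forward(lr$net, x)$out, base_logits,
               tolerance = 1e-6)

  # one optimizer step: bases bit-identical, factors changed
  net2 <- lr$net
  slots <- ansaedge:::trainable_slots(net2)
  expect_true(all(sapply(slots, function(s) s$path[1] == "lora")))
  state <- ansaedge:::adam_state(net2, slots)
  fw <- ansaedge:::net_forward(net2, x)
  ls <- ansaedge:::softmax_xent(fw$out, c(1L, 2L))
  bw <- ansaedge:::net_backward(net2, fw$caches, ls$dlogits)
  upd <- ansaedge:::adam_step(net2, bw$grads, slots, state, 1e-2, 1)
  for (i in seq_along(net2$layers)) {
    l0 <- lr$net$layers[[i]]; l1 <- upd$net$layers[[i]]
    if (!l0$type %in% c("conv", "dense", "l2sab")) next
    expect_identical(l0$W, l1$W)
    expect_false(isTRUE(all.equal(l0$lora$B, l1$lora$B)))
  }

  expect_warning(attach_lora(full, rank = 1000), "clamped")
})

test_that("CP-ALS reconstructs exactly representable kernels and is monotone in rank", {
  set.seed(20)
  u <- stats::rnorm(5); v <- stats::rnorm(5); w <- stats::rnorm(3); z <- stats::rnorm(8)
  rank1 <- outer(outer(outer(u, v), w), z)
  dim(rank1) <- c(5, 5, 3, 8)
  fit <- cp_als(rank1, rank = 1, iters = 50)
  expect_lt(fit$rel_error, 1e-6)

  kern <- array(stats::rnorm(5 * 5 * 3 * 8), c(5, 5, 3, 8))
  set.seed(77); e2 <- cp_als(kern, rank = 2, iters = 40)$rel_error
  set.seed(77); e4 <- cp_als(kern, rank = 4, iters = 40)$rel_error
  set.seed(77); e8 <- cp_als(kern, rank = 8, iters = 40)$rel_error
  expect_lte(e4, e2 + 1e-8)
  expect_lte(e8, e4 + 1e-8)
})

test_that("CP rewrite of the first conv preserves shapes and bounds deviation", {
  net <- make_k3_net(input_size = 16)
  x <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
  y0 <- ansaedge:::net_forward(net, x)$out

  # exactly representable first kernel: rewritten net computes the same map
  l1 <- net$layers[[1]]
  d <- dim(l1$W)
  set.seed(30)
  r1 <- outer(stats::rnorm(d[1]), stats::rnorm(d[2]))
  r1 <- outer(outer(r1, stats::rnorm(d[3])), stats::rnorm(d[4]))
  dim(r1) <- d
  net$layers[[1]]$W <- r1
  rc <- suppressWarnings(cp_decompose_first_conv(net, rank = 1, iters = 60))
  expect_lt(rc$report$details$rel_error, 1e-6)
  expect_lt(rc$report$max_output_deviation, 1e-4)
  expect_equal(dim(ansaedge:::net_forward(rc$net, x)$out), c(3L, 2L))

  # approximate case: deviation reported and finite, structure is the
  # pointwise -> depthwise(Kx1) -> depthwise(1xK) -> pointwise chain
  net2 <- make_k3_net(input_size = 16)
  rc2 <- suppressWarnings(cp_decompose_first_conv(net2, rank = 4, iters = 30))
  nms <- sapply(rc2$net$layers[1:4], `[[`, "name")
  expect_equal(nms, c("conv1_cp_pwin", "conv1_cp_dwh",
                      "conv1_cp_dww", "conv1_cp_pwout"))
  expect_true(is.finite(rc2$report$max_output_deviation))
})

test_that("magnitude pruning zeroes the globally smallest weights", {
  # the documented four-weight example
  net <- structure(list(spec = NULL, layers = list(
    ansaedge:::layer_dense("fc", 2, 2,
                           W = matrix(c(0.1, -0.5, 0.2, -0.05), 2, 2),
                           b = numeric(2)))), class = "ansa_net")
  pr <- magnitude_prune(net, 0.5)
  expect_equal(pr$net$layers[[1]]$W, matrix(c(0, -0.5, 0.2, 0), 2, 2))

  full <- build_model(tiny_attention_spec(), seed = 40)
  w_before <- lapply(full$layers, `[[`, "W")
  expect_equal(magnitude_prune(full, 0)$net |> weight_sparsity(), 0)
  expect_equal(magnitude_prune(full, 1)$net |> weight_sparsity(), 1)
  for (f in c(0.3, 0.5, 0.7)) {
    pr <- magnitude_prune(full, f)
    total <- pr$report$details$weights_total
    expect_lte(abs(weight_sparsity(pr$net) - f), 1 / total)
    # surviving weights all dominate pruned ones in magnitude
    kept <- pruned <- c()
    for (i in ansaedge:::prunable_indices(pr$net)) {
      l <- pr$net$layers[[i]]
      orig <- abs(w_before[[i]])
      kept <- c(kept, orig[l$mask == 1])
      pruned <- c(pruned, orig[l$mask == 0])
    }
    expect_gte(min(kept), max(pruned))
  }
})

test_that("fine-tuning a pruned net keeps zeros and reduces training loss", {
  set.seed(50)
  imgs <- generate_synthetic_dataset(6, num_classes = 3, size = 16, seed = 50)
  net <- build_model(tiny_attention_spec(), seed = 50)
  # pre-train briefly so pruning acts on a non-trivial weight profile
  cfg <- train_config(learning_rate = 1e-3, batch_size = 6, max_epochs = 3,
                      patience = 2, seed = 50)
  net <- train_network(net, list(train = imgs, val = imgs), cfg)$net
  pr <- magnitude_prune(net, 0.5)
  batch <- ansaedge:::as_image_batch(imgs)
  loss_after_prune <- ansaedge:::evaluate_loss(pr$net, batch)$loss
  ft <- finetune_pruned(pr$net, pr$mask, list(train = imgs, val = imgs),
                        train_config(learning_rate = 1e-3, batch_size = 6,
                                     max_epochs = 5, patience = 4, seed = 51))
  expect_equal(weight_sparsity(ft$net), weight_sparsity(pr$net))
  for (i in ansaedge:::prunable_indices(ft$net)) {
    l <- ft$net$layers[[i]]
    expect_true(all(l$W[pr$mask[[l$name]] == 0] == 0))
  }
  loss_after_ft <- ansaedge:::evaluate_loss(ft$net, batch)$loss
  expect_lte(loss_after_ft, loss_after_prune + 1e-8)
  expect_error(finetune_pruned(build_model(tiny_attention_spec(), seed = 1),
                               list(), list(train = imgs, val = imgs)),
               "mask")
})
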