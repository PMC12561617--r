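# Correctness of the network engine: analytic gradients against central
# differences through every layer type, and optimizer/mask interactions.

test_that("analytic gradients match central differences through the full net", {
  set.seed(2)
  net <- build_model(tiny_attention_spec(), seed = 3)
  x <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- c(1L, 3L)
  lossfun <- function(n) {
    fw <- ansaedge:::net_forward(n, x)
    ansaedge:::softmax_xent(fw$out, y)$loss
  }
  fw <- ansaedge:::net_forward(net, x)
  ls <- ansaedge:::softmax_xent(fw$out, y)
  bw <- ansaedge:::net_backward(net, fw$caches, ls$dlogits, record_dx = TRUE)
  slots <- ansaedge:::trainable_slots(net)
  eps <- 1e-5
  errs <- c()
  for (s in slots) {
    p <- ansaedge:::get_slot(net, s)
    g <- ansaedge:::grad_slot(bw$grads, s)
    for (k in seq_len(min(3, length(p)))) {
      i <- sample(length(p), 1)
      pp <- p; pp[i] <- p[i] + eps
      lp <- lossfun(ansaedge:::set_slot(net, s, pp))
      pp[i] <- p[i] - eps
      lm <- lossfun(ansaedge:::set_slot(net, s, pp))
      num <- (lp - lm) / (2 * eps)
      errs <- c(errs, abs(num - g[i]) / max(1e-6, abs(num), abs(g[i])))
    }
  }
  # channel max/min pooling makes the loss piecewise smooth; central
  # differences can land on a kink for a few parameters, so assert a tight
  # bound on the bulk and a loose one on the worst case
  expect_lt(stats::median(errs), 1e-6)
  expect_lt(stats::quantile(errs, 0.9), 1e-4)
  expect_lt(max(errs), 0.2)

  # input gradient at random positions
  gin <- bw$dxs[[1]]
  for (k in 1:5) {
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- x[i] + eps
    lp <- ansaedge:::softmax_xent(ansaedge:::net_forward(net, xp)$out, y)$loss
    xp[i] <- x[i] - eps
    lm <- ansaedge:::softmax_xent(ansaedge:::net_forward(net, xp)$out, y)$loss
    expect_equal(gin[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("grouped and rectangular convolutions match a naive oracle", {
  set.seed(4)
  naive <- function(x, w, b, pad, groups) {
    d <- dim(x); wd <- dim(w)
    coutg <- wd[4] / groups
    xp <- array(0, c(d[1] + pad[1] + pad[2], d[2] + pad[3] + pad[4], d[3], d[4]))
    xp[pad[1] + seq_len(d[1]), pad[3] + seq_len(d[2]), , ] <- x
    ho <- dim(xp)[1] - wd[1] + 1; wo <- dim(xp)[2] - wd[2] + 1
    y <- array(0, c(ho, wo, wd[4], d[4]))
    for (n in seq_len(d[4])) for (oc in seq_len(wd[4])) {
      g <- ceiling(oc / coutg)
      for (i in seq_len(ho)) for (j in seq_len(wo)) {
        acc <- if (length(b)) b[oc] else 0
        for (c in seq_len(wd[3]))
          acc <- acc + sum(w[, , c, oc] *
                           xp[i:(i + wd[1] - 1), j:(j + wd[2] - 1),
                              (g - 1) * wd[3] + c, n])
        y[i, j, oc, n] <- acc
      }
    }
    y
  }
  x <- array(stats::rnorm(7 * 9 * 4 * 2), c(7, 9, 4, 2))
  cases <- list(
    list(w = array(stats::rnorm(3 * 3 * 4 * 5), c(3, 3, 4, 5)),
         b = stats::rnorm(5), pad = c(1L, 1L, 1L, 1L), groups = 1L),
    list(w = array(stats::rnorm(5 * 1 * 1 * 4), c(5, 1, 1, 4)),
         b = numeric(0), pad = c(2L, 2L, 0L, 0L), groups = 4L),
    list(w = array(stats::rnorm(1 * 4 * 1 * 4), c(1, 4, 1, 4)),
         b = numeric(0), pad = c(0L, 0L, 1L, 2L), groups = 4L),
    list(w = array(stats::rnorm(2 * 2 * 2 * 6), c(2, 2, 2, 6)),
         b = stats::rnorm(6), pad = c(0L, 1L, 0L, 1L), groups = 2L))
  for (cs in cases) {
    got <- ansaedge:::.conv2d_forward_cpp(x, cs$w, cs$b, cs$pad, cs$groups)
    expect_equal(got, naive(x, cs$w, cs$b, cs$pad, cs$groups),
                 tolerance = 1e-12)
  }
})

test_that("prune masks survive optimizer updates exactly", {
  set.seed(6)
  net <- build_model(tiny_attention_spec(), seed = 6)
  pr <- magnitude_prune(net, 0.5)
  net <- pr$net
  slots <- ansaedge:::trainable_slots(net)
  state <- ansaedge:::adam_state(net, slots)
  x <- array(stats::runif(16 * 16 * 4), c(16, 16, 1, 4))
  y <- c(1L, 2L, 3L, 1L)
  for (t in 1:5) {
    fw <- ansaedge:::net_forward(net, x)
    ls <- ansaedge:::softmax_xent(fw$out, y)
    bw <- ansaedge:::net_backward(net, fw$caches, ls$dlogits)
    upd <- ansaedge:::adam_step(net, bw$grads, slots, state, 1e-2, t)
    net <- upd$net; state <- upd$state
  }
  for (i in ansaedge:::prunable_indices(net)) {
    l <- net$layers[[i]]
    expect_true(all(l$W[l$mask == 0] == 0))
  }
  expect_equal(weight_sparsity(net), pr$report$details$sparsity,
               tolerance = 1e-3)
})

test_that("softmax cross-entropy loss and gradient are consistent", {
  set.seed(7)
  logits <- matrix(stats::rnorm(12), 3, 4)
  y <- c(1L, 3L, 2L, 2L)
  ls <- ansaedge:::softmax_xent(logits, y)
  p <- apply(logits, 2, function(v) exp(v - max(v)) / sum(exp(v - max(v))))
  expect_equal(ls$loss, -mean(log(p[cbind(y, 1:4)])), tolerance = 1e-12)
  eps <- 1e-6
  for (k in 1:5) {
    i <- sample(length(logits), 1)
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    num <- (ansaedge:::softmax_xent(lp, y)$loss -
            ansaedge:::softmax_xent(lm, y)$loss) / (2 * eps)
    expect_equal(ls$dlogits[i], num, tolerance = 1e-6)
  }
})
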