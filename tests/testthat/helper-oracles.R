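# Independent scalar-loop oracles used to cross-check the vectorized /
# compiled implementations, plus small builders shared across test files.

# channel pooling by explicit triple loop over an H x W x C array
oracle_channel_pool <- function(f, mode) {
  d <- dim(f)
  out <- matrix(0, d[1], d[2])
  for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
    v <- f[h, w, ]
    out[h, w] <- if (mode == "max") max(v) else min(v)
  }
  out
}

# direct 2-D convolution with explicit loops (single channel in/out)
oracle_conv2d_1ch <- function(m, w, bias, pad) {
  k <- nrow(w)
  mp <- matrix(0, nrow(m) + pad[1] + pad[2], ncol(m) + pad[3] + pad[4])
  mp[pad[1] + seq_len(nrow(m)), pad[3] + seq_len(ncol(m))] <- m
  ho <- nrow(mp) - k + 1
  wo <- ncol(mp) - k + 1
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) for (j in seq_len(wo))
    out[i, j] <- sum(mp[i:(i + k - 1), j:(j + k - 1)] * w) + bias
  out
}

# full spatial-attention composition computed with scalar operations only
oracle_spatial_attention <- function(f, params) {
  mx <- oracle_channel_pool(f, "max")
  mn <- oracle_channel_pool(f, "min")
  l2 <- function(m) m / max(sqrt(sum(m^2)), params$eps)
  k <- params$kernel_size
  pad <- c((k - 1) %/% 2, (k - 1) - (k - 1) %/% 2,
           (k - 1) %/% 2, (k - 1) - (k - 1) %/% 2)
  pre <- oracle_conv2d_1ch(l2(mx) - l2(mn), params$weights, params$bias, pad)
  1 / (1 + exp(-pre))
}

# GCT gating with explicit per-channel loops
oracle_gct <- function(f, params) {
  d <- dim(f)
  z <- numeric(d[3])
  for (c in seq_len(d[3])) z[c] <- mean(f[, , c])
  zhat <- (z - mean(z)) / (sqrt(mean((z - mean(z))^2)) + params$eps)
  a <- exp(-zhat^2 / (2 * params$c^2))
  out <- f
  for (c in seq_len(d[3])) out[, , c] <- f[, , c] * a[c]
  out
}

# per-class one-vs-rest metrics from a confusion matrix, brute force
oracle_metrics <- function(cm) {
  total <- sum(cm)
  K <- nrow(cm)
  res <- matrix(0, K, 4, dimnames = list(NULL, c("precision", "recall",
                                                 "f1", "specificity")))
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    s <- if (tn + fp > 0) tn / (tn + fp) else 0
    if (sum(cm[k, ]) + sum(cm[, k]) == 0) p <- r <- f1 <- s <- 0
    res[k, ] <- c(p, r, f1, s)
  }
  list(accuracy = sum(diag(cm)) / total, per_class = res,
       macro = colMeans(res))
}

# a small network that exercises every layer type quickly
tiny_attention_spec <- function(num_classes = 3) {
  model_spec(
    backbone = backbone_config(filters = c(3, 4), kernel_sizes = c(3, 3),
                               input_size = 16, in_channels = 1),
    attention_blocks = list(attention_block_config(c(4, 3, 2)),
                            attention_block_config(c(2, 1, 1))),
    use_gct = TRUE, head_hidden = 5, num_classes = num_classes)
}

random_feature_map <- function(h = 16, w = 16, c = 8) {
  array(stats::rnorm(h * w * c), c(h, w, c))
}
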