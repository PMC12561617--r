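# Model compression transforms: each takes a built network (or a spec) and
# returns a rewritten network plus a compression_report with parameter
# accounting and a functional diagnostic on a probe batch.

compression_report <- function(method, params_before, params_after,
                               trainable_after, max_output_deviation = NA_real_,
                               details = list()) {
  structure(list(method = method,
                 params_before = as.integer(params_before),
                 params_after = as.integer(params_after),
                 trainable_after = as.integer(trainable_after),
                 max_output_deviation = max_output_deviation,
                 details = details),
            class = "compression_report")
}

#' @export
print.compression_report <- function(x, ...) {
  cat(sprintf("%s: %d -> %d parameters (%d trainable)",
              x$method, x$params_before, x$params_after, x$trainable_after))
  if (is.finite(x$max_output_deviation))
    cat(sprintf(", max probe deviation %.3g", x$max_output_deviation))
  cat("\n")
  invisible(x)
}

probe_deviation <- function(net_a, net_b, n = 2L, seed = 7L) {
  bb <- net_a$spec$backbone
  set.seed(seed)
  x <- array(stats::rnorm(bb$input_size^2 * bb$in_channels * n),
             c(bb$input_size, bb$input_size, bb$in_channels, n))
  max(abs(net_forward(net_a, x)$out - net_forward(net_b, x)$out))
}

#' Rewrite backbone convolutions as depthwise-separable pairs
#'
#' Replaces every backbone convolution with spatial extent (`K > 1`) by a
#' depthwise convolution (`K x K`, one filter per input channel, no bias)
#' followed by a pointwise `1 x 1` convolution carrying the bias. A
#' standard convolution holding `Cin * Cout * K^2` weights becomes
#' `Cin * K^2 + Cin * Cout`, while output shapes are unchanged. The
#' single-channel convolutions inside attention blocks are left untouched
#' by default. The rewritten layers are freshly initialized (this is an
#' architectural rewrite to be retrained, not a weight factorization), so
#' the probe deviation in the report is expected to be large.
#'
#' @param net An `ansa_net`.
#' @param include_attention Also rewrite l2-SAB convolutions (default
#'   `FALSE`; they are single-channel and gain nothing).
#' @return `list(net, report)`.
#' @export
to_depthwise_separable <- function(net, include_attention = FALSE) {
  before <- count_parameters(net)
  layers <- list()
  per_layer <- list()
  for (l in net$layers) {
    is_bb_conv <- l$type == "conv" && l$groups == 1L &&
      (dim(l$W)[1] > 1L || dim(l$W)[2] > 1L)
    if (!is_bb_conv) {
      layers[[length(layers) + 1L]] <- l
      next
    }
    d <- dim(l$W) # Kh, Kw, Cin, Cout
    cin <- d[3]; cout <- d[4]
    dw <- layer_conv(paste0(l$name, "_dw"), cin, cin, d[1], d[2],
                     pad = l$pad, groups = cin, bias = FALSE, stage = l$stage)
    pw <- layer_conv(paste0(l$name, "_pw"), cin, cout, 1L, 1L,
                     pad = c(0L, 0L, 0L, 0L), bias = !is.null(l$b),
                     stage = l$stage)
    layers[[length(layers) + 1L]] <- dw
    layers[[length(layers) + 1L]] <- pw
    per_layer[[l$name]] <- list(
      weights_before = prod(d),
      weights_after = cin * d[1] * d[2] + cin * cout)
  }
  out <- net
  out$layers <- layers
  rep <- compression_report("DSC", before, count_parameters(out),
                            count_parameters(out, trainable_only = TRUE),
                            probe_deviation(net, out),
                            details = per_layer)
  list(net = out, report = rep)
}

#' Reduce backbone feature maps
#'
#' Returns the specification with the convolutional filter counts reduced
#' from 64-128-256-512 to 8-16-32-64; nothing else changes. Attention
#' blocks are unaffected (their parameter count depends only on the l2-SAB
#' kernel sizes).
#'
#' @param spec A `model_spec` on the default four-stage backbone.
#' @return A `model_spec` with filters `c(8, 16, 32, 64)`.
#' @export
to_reduced_feature_maps <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(spec$backbone$filters) != 4)
    stop("reduced-feature-map rewrite expects a four-stage backbone")
  bb <- spec$backbone
  model_spec(
    backbone = backbone_config(c(8L, 16L, 32L, 64L), bb$kernel_sizes,
                               bb$input_size, bb$in_channels),
    attention_blocks = spec$attention_blocks, use_gct = spec$use_gct,
    head_hidden = spec$head_hidden, num_classes = spec$num_classes)
}

#' Attach low-rank adaptation (LoRA) factors
#'
#' Every convolutional and dense layer keeps its base weights frozen and
#' gains trainable factors `A` (`d_out x r`) and `B` (`r x d_in`), with
#' `B` zero-initialized so the adapted forward pass initially equals the
#' base forward pass exactly. For convolutions the factorization acts on
#' the unfolded `Cout x (Cin K^2)` weight matrix. Ranks larger than
#' `min(d_in, d_out)` are clamped with a warning.
#'
#' @param net An `ansa_net`.
#' @param rank LoRA rank (default 8).
#' @return `list(net, report)`; `trainable_after` counts only the factors.
#' @export
attach_lora <- function(net, rank = 8) {
  stopifnot(rank >= 1)
  before <- count_parameters(net)
  clamped <- FALSE
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (!l$type %in% c("conv", "dense", "l2sab")) next
    if (l$type == "dense") {
      d_out <- nrow(l$W); d_in <- ncol(l$W)
    } else if (l$type == "conv") {
      d <- dim(l$W); d_out <- d[4]; d_in <- prod(d[1:3])
    } else { # l2sab: single-channel conv, d_out = 1
      d_out <- 1L; d_in <- l$k^2
    }
    r <- min(rank, d_in, d_out)
    if (r < rank) clamped <- TRUE
    l$lora <- list(rank = r,
                   A = matrix(stats::rnorm(d_out * r, sd = 1 / sqrt(d_in)),
                              d_out, r),
                   B = matrix(0, r, d_in))
    l$frozen <- TRUE
    net$layers[[i]] <- l
  }
  if (clamped)
    warning("LoRA rank clamped to min(d_in, d_out) on some layers")
  rep <- compression_report("PEFT_LORA", before, count_parameters(net),
                            count_parameters(net, trainable_only = TRUE),
                            max_output_deviation = NA_real_)
  list(net = net, report = rep)
}

# ---- canonical polyadic decomposition --------------------------------------

unfold_tensor <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(x, perm), d[mode], prod(d[-mode]))
}

# Khatri-Rao product of a list of factor matrices, last matrix varying
# slowest (matches the column ordering of unfold_tensor's non-mode axes)
khatri_rao_list <- function(mats) {
  out <- mats[[1]]
  for (k in seq_along(mats)[-1]) {
    a <- mats[[k]]
    out <- sapply(seq_len(ncol(out)),
                  function(r) kronecker(a[, r], out[, r]))
  }
  out
}

cp_reconstruct <- function(factors, lambda) {
  R <- length(lambda)
  d <- vapply(factors, nrow, 0L)
  x <- array(0, d)
  for (r in seq_len(R)) {
    v <- factors[[1]][, r]
    for (k in seq_along(factors)[-1]) v <- outer(v, factors[[k]][, r])
    x <- x + lambda[r] * array(v, d)
  }
  x
}

#' Canonical polyadic decomposition by alternating least squares
#'
#' Factorizes an N-way array `X` into `R` rank-1 terms,
#' `X ~ sum_r lambda_r u1_r o u2_r o ... o uN_r`, by cyclically solving
#' the linear least-squares problem for each factor matrix
#' (minimizing `||X - Xhat||_F`). Factor columns are normalized to unit
#' length after every sweep, with the scale absorbed into `lambda`.
#'
#' @param x Numeric array (3 or more modes).
#' @param rank Number of rank-1 components `R >= 1`.
#' @param iters Maximum ALS sweeps (default 50).
#' @param tol Relative-error change below which iteration stops.
#' @return `list(factors, lambda, rel_error, converged, iterations)`;
#'   `rel_error` is `||X - Xhat||_F / ||X||_F`.
#' @export
cp_als <- function(x, rank, iters = 50, tol = 1e-8) {
  stopifnot(rank >= 1, length(dim(x)) >= 3)
  d <- dim(x)
  nx <- sqrt(sum(x^2))
  if (nx == 0) stop("cannot decompose an all-zero tensor")
  factors <- lapply(d, function(dn)
    matrix(stats::rnorm(dn * rank), dn, rank))
  lambda <- rep(1, rank)
  unfolds <- lapply(seq_along(d), function(n) unfold_tensor(x, n))
  rel_prev <- Inf
  rel <- Inf
  it <- 0L
  converged <- FALSE
  while (it < iters) {
    it <- it + 1L
    for (n in seq_along(d)) {
      others <- factors[-n]
      kr <- khatri_rao_list(others)
      gram <- Reduce(`*`, lapply(others, crossprod))
      un <- unfolds[[n]] %*% kr %*% solve_psd(gram)
      nrm <- sqrt(colSums(un^2))
      nrm[nrm == 0] <- 1
      factors[[n]] <- sweep(un, 2, nrm, "/")
      lambda <- nrm
    }
    rel <- sqrt(sum((x - cp_reconstruct(factors, lambda))^2)) / nx
    if (abs(rel_prev - rel) < tol) { converged <- TRUE; break }
    rel_prev <- rel
  }
  list(factors = factors, lambda = lambda, rel_error = rel,
       converged = converged, iterations = it)
}

# ridge-stabilized solve for the (possibly rank-deficient) ALS gram matrix
solve_psd <- function(g) {
  tryCatch(solve(g), error = function(e)
    solve(g + diag(1e-10 * max(diag(g)), nrow(g))))
}

#' CP-decompose the first convolution of a network
#'
#' Decomposes the first convolutional kernel (`Kh x Kw x Cin x Cout`) into
#' `R` rank-1 terms by [cp_als()] and replaces the layer by the equivalent
#' sequence `pointwise(Cin -> R) -> depthwise(Kh x 1) -> depthwise(1 x Kw)
#' -> pointwise(R -> Cout)`, the last carrying the original bias. When the
#' reconstruction is exact the rewritten network computes the same function
#' as the original; otherwise the output deviation is governed by the
#' relative reconstruction error reported.
#'
#' @param net An `ansa_net`.
#' @param rank CP rank; default `max(1, Cout / 4)` of the first conv.
#' @param iters Maximum ALS sweeps.
#' @return `list(net, report)`; the report's `details$rel_error` holds the
#'   relative reconstruction error, and a warning is raised if ALS did not
#'   converge within `iters`.
#' @export
cp_decompose_first_conv <- function(net, rank = NULL, iters = 50) {
  idx <- which(vapply(net$layers, function(l)
    l$type == "conv" && l$groups == 1L, TRUE))[1]
  if (is.na(idx)) stop("network has no convolutional layer")
  l <- net$layers[[idx]]
  d <- dim(l$W) # Kh, Kw, Cin, Cout
  if (is.null(rank)) rank <- max(1L, d[4] %/% 4L)
  rank <- as.integer(rank)
  fit <- cp_als(l$W, rank, iters = iters)
  if (!fit$converged)
    warning("CP-ALS did not converge in ", iters,
            " sweeps; using best factors (rel_error = ",
            signif(fit$rel_error, 3), ")")
  U <- fit$factors # modes: Kh, Kw, Cin, Cout
  R <- rank
  pw_in <- layer_conv(paste0(l$name, "_cp_pwin"), d[3], R, 1L, 1L,
                      pad = c(0L, 0L, 0L, 0L), bias = FALSE, stage = l$stage,
                      W = array(t(U[[3]]), c(1L, 1L, d[3], R)))
  dw_h <- layer_conv(paste0(l$name, "_cp_dwh"), R, R, d[1], 1L,
                     pad = c(l$pad[1:2], 0L, 0L), groups = R, bias = FALSE,
                     stage = l$stage,
                     W = array(U[[1]], c(d[1], 1L, 1L, R)))
  dw_w <- layer_conv(paste0(l$name, "_cp_dww"), R, R, 1L, d[2],
                     pad = c(0L, 0L, l$pad[3:4]), groups = R, bias = FALSE,
                     stage = l$stage,
                     W = array(t(U[[2]]), c(1L, d[2], 1L, R)))
  w_out <- array(0, c(1L, 1L, R, d[4]))
  w_out[1, 1, , ] <- t(U[[4]] %*% diag(fit$lambda, nrow = R, ncol = R))
  pw_out <- layer_conv(paste0(l$name, "_cp_pwout"), R, d[4], 1L, 1L,
                       pad = c(0L, 0L, 0L, 0L), bias = !is.null(l$b),
                       stage = l$stage, W = w_out, b = l$b)
  before <- count_parameters(net)
  out <- net
  out$layers <- append(net$layers[-idx],
                       list(pw_in, dw_h, dw_w, pw_out), after = idx - 1L)
  rep <- compression_report("CPTD", before, count_parameters(out),
                            count_parameters(out, trainable_only = TRUE),
                            probe_deviation(net, out),
                            details = list(rank = R,
                                           rel_error = fit$rel_error,
                                           converged = fit$converged))
  list(net = out, report = rep)
}

# ---- magnitude pruning -----------------------------------------------------

prunable_indices <- function(net) {
  which(vapply(net$layers, function(l)
    l$type %in% c("conv", "dense", "l2sab"), TRUE))
}

#' Global magnitude pruning
#'
#' Ranks every weight (biases excluded) of all convolutional, dense and
#' l2-SAB layers by absolute value and masks the smallest `fraction` of
#' them to zero, globally across layers. The returned mask is stored on
#' the network so subsequent fine-tuning keeps pruned positions at exactly
#' zero.
#'
#' @param net An `ansa_net`.
#' @param fraction Fraction of weights to prune, in `[0, 1]`.
#' @return `list(net, mask, report)`; `mask` is a named list of binary
#'   arrays congruent to each layer's weights, with attribute
#'   `target_fraction`.
#' @export
magnitude_prune <- function(net, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  idx <- prunable_indices(net)
  mags <- unlist(lapply(idx, function(i) abs(as.vector(net$layers[[i]]$W))))
  total <- length(mags)
  k <- floor(fraction * total)
  keep <- rep(1, total)
  if (k > 0) keep[order(mags)[seq_len(k)]] <- 0 # stable: ties by position
  mask <- list()
  offset <- 0L
  for (i in idx) {
    W <- net$layers[[i]]$W
    m <- keep[offset + seq_along(W)]
    offset <- offset + length(W)
    dim(m) <- dim(W)
    mask[[net$layers[[i]]$name]] <- m
    net$layers[[i]]$mask <- m
    net$layers[[i]]$W <- W * m
  }
  attr(mask, "target_fraction") <- fraction
  rep <- compression_report(
    "PRUNE", count_parameters(net), count_parameters(net),
    count_parameters(net, trainable_only = TRUE),
    details = list(fraction = fraction, weights_total = total,
                   weights_zeroed = k, sparsity = k / total))
  list(net = net, mask = mask, report = rep)
}

#' Fine-tune a pruned network
#'
#' Continues training with the prune mask enforced: after every optimizer
#' step, masked positions are reset to exactly zero (the optimizer itself
#' also receives masked gradients), so the sparsity pattern is invariant
#' under any number of steps.
#'
#' @param net A pruned `ansa_net` (from [magnitude_prune()]).
#' @param mask The mask returned by [magnitude_prune()].
#' @param data `list(train = ..., val = ...)` of `labeled_image` lists.
#' @param cfg A [train_config()].
#' @return `list(net, history)` as from [train_network()].
#' @export
finetune_pruned <- function(net, mask, data, cfg = train_config()) {
  for (i in prunable_indices(net)) {
    l <- net$layers[[i]]
    m <- mask[[l$name]]
    if (is.null(m) || !identical(dim(m) %||% length(m),
                                 dim(l$W) %||% length(l$W)))
      stop("mask does not match network layer ", l$name)
    net$layers[[i]]$mask <- m
    net$layers[[i]]$W <- l$W * m
  }
  train_network(net, data, cfg)
}

#' Measured sparsity of a network's prunable weights
#'
#' @param net An `ansa_net`.
#' @return Fraction of exactly-zero weights across conv/dense/l2-SAB layers.
#' @export
weight_sparsity <- function(net) {
  w <- unlist(lapply(prunable_indices(net),
                     function(i) as.vector(net$layers[[i]]$W)))
  mean(w == 0)
}
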