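#' @useDynLib ansaedge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Feature maps are stored in R's image convention: H x W x C arrays for a
# single image and H x W x C x N for a batch. The channel axis is always
# the third dimension.

#' l2-SAB parameters
#'
#' Bundles the parameters of one l2-normalized spatial attention block
#' (l2-SAB): the kernel size `K` of its single-channel convolution, the
#' `K x K` convolution weights, and a scalar bias. The attention map is
#' `sigmoid(conv(l2(maxpool_c(F)) - l2(minpool_c(F))))`, where the pooling
#' runs over the channel axis and `l2()` normalizes each pooled map by its
#' Euclidean norm.
#'
#' @param kernel_size Positive integer, the convolution kernel size `K`.
#'   Even values are supported via asymmetric zero padding so that the
#'   spatial shape is preserved.
#' @param weights Optional `K x K` numeric matrix of convolution weights.
#'   When `NULL`, weights are drawn from a scaled normal (He) distribution
#'   using the current RNG state.
#' @param bias Scalar convolution bias; zero by default so that a freshly
#'   initialized block on a constant-channel input yields an attention map
#'   of exactly 0.5 everywhere.
#' @param eps Positive guard used in the l2 normalization of the pooled
#'   maps, protecting the all-zero map.
#' @return An object of class `l2sab_params`.
#' @export
l2sab_params <- function(kernel_size, weights = NULL, bias = 0, eps = 1e-6) {
  stopifnot(kernel_size >= 1, eps > 0)
  k <- as.integer(kernel_size)
  if (is.null(weights)) {
    weights <- matrix(stats::rnorm(k * k, sd = sqrt(2 / (k * k))), k, k)
  }
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(k, k)) || !all(is.finite(weights)))
    stop("weights must be a finite ", k, " x ", k, " matrix")
  structure(list(kernel_size = k, weights = weights,
                 bias = as.numeric(bias), eps = eps),
            class = "l2sab_params")
}

#' GCT parameters
#'
#' Parameters of the Gaussian Context Transformer channel gate. The gate is
#' parameter-free in the learning sense: `c` is a fixed hyperparameter that
#' controls the spread of the Gaussian excitation, and `eps` guards the
#' across-channel standardization against zero variance.
#'
#' @param c Positive spread of the Gaussian excitation.
#' @param eps Positive standard-deviation guard.
#' @return An object of class `gct_params`.
#' @export
gct_params <- function(c = 2, eps = 1e-6) {
  stopifnot(c > 0, eps > 0)
  structure(list(c = as.numeric(c), eps = eps), class = "gct_params")
}

check_feature_map <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3L)
    stop("feature map must be an H x W x C array")
  if (any(dim(f) < 1L) || length(f) == 0L)
    stop("feature map must be non-empty")
  if (!all(is.finite(f))) stop("feature map contains non-finite values")
  invisible(dim(f))
}

#' Pool a feature map across channels
#'
#' Reduces an `H x W x C` feature map to a single `H x W` map by taking the
#' elementwise maximum (or minimum) over the channel axis at each spatial
#' location. These are the two pooled maps whose l2-normalized difference
#' drives the spatial attention block.
#'
#' @param f Numeric `H x W x C` array.
#' @param mode `"max"` or `"min"`.
#' @return An `H x W` numeric matrix.
#' @export
channel_pool <- function(f, mode = c("max", "min")) {
  mode <- match.arg(mode)
  d <- check_feature_map(f)
  m <- matrix(f, d[1] * d[2], d[3])
  s <- if (mode == "max") m[cbind(seq_len(nrow(m)), max.col(m, "first"))]
       else                m[cbind(seq_len(nrow(m)), max.col(-m, "first"))]
  matrix(s, d[1], d[2])
}

#' l2-normalize a 2-D map
#'
#' Divides a map by the larger of its Euclidean norm (over all entries) and
#' `eps`, so the all-zero map is returned unchanged and every other map is
#' scaled to unit norm.
#'
#' @param m Numeric matrix (or 2-D array).
#' @param eps Positive norm guard.
#' @return A matrix of the same shape.
#' @export
l2_normalize_map <- function(m, eps = 1e-6) {
  stopifnot(is.numeric(m), all(is.finite(m)))
  m / max(sqrt(sum(m^2)), eps)
}

# asymmetric "same" padding: left/top get floor((K-1)/2), right/bottom the
# remainder, so even kernels also preserve H x W
same_pad <- function(kh, kw = kh) {
  c((kh - 1L) %/% 2L, (kh - 1L) - (kh - 1L) %/% 2L,
    (kw - 1L) %/% 2L, (kw - 1L) - (kw - 1L) %/% 2L)
}

# thin R wrapper over the C++ conv kernel; x may be H x W x C or H x W x C x N
conv2d <- function(x, w, bias = NULL, pad = c(0L, 0L, 0L, 0L), groups = 1L) {
  squeeze <- FALSE
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
    squeeze <- TRUE
  }
  if (is.null(bias)) bias <- numeric(0)
  y <- .conv2d_forward_cpp(x, w, as.numeric(bias),
                           as.integer(pad), as.integer(groups))
  if (squeeze) {
    d <- dim(y)
    dim(y) <- d[1:3]
  }
  y
}

#' Spatial attention map of the l2-SAB
#'
#' Computes the spatial attention map
#' `Ms = sigmoid(conv_KxK(l2(maxpool_c(F)) - l2(minpool_c(F))))`: the
#' channel-max and channel-min maps are each l2-normalized, subtracted, and
#' passed through a single-channel `K x K` convolution (shape-preserving
#' zero padding) followed by a sigmoid. Every entry is strictly inside
#' (0, 1).
#'
#' @param f Numeric `H x W x C` feature map.
#' @param params An [l2sab_params()] object.
#' @return An `H x W` matrix with entries in (0, 1).
#' @export
spatial_attention <- function(f, params) {
  stopifnot(inherits(params, "l2sab_params"))
  d <- check_feature_map(f)
  k <- params$kernel_size
  if (d[1] < 1 || d[2] < 1 || k > d[1] + sum(same_pad(k)[1:2]) ||
      k > d[2] + sum(same_pad(k)[3:4]))
    stop("feature map smaller than the effective kernel support")
  dmap <- l2_normalize_map(channel_pool(f, "max"), params$eps) -
          l2_normalize_map(channel_pool(f, "min"), params$eps)
  w <- array(params$weights, c(k, k, 1L, 1L))
  pre <- conv2d(array(dmap, c(d[1], d[2], 1L)), w, params$bias, same_pad(k))
  matrix(stats::plogis(pre), d[1], d[2])
}

#' Apply an l2-SAB block to a feature map
#'
#' Gates every channel of `f` by the shared spatial attention map:
#' `F'[h,w,c] = Ms[h,w] * F[h,w,c]`.
#'
#' @inheritParams spatial_attention
#' @return A feature map of the same shape as `f`.
#' @export
l2_sab_apply <- function(f, params) {
  ms <- spatial_attention(f, params)
  f * as.vector(ms) # column-major recycling broadcasts over channels
}

#' Apply the Gaussian Context Transformer channel gate
#'
#' Computes the global average `z_c` of each channel, standardizes the
#' channel contexts across channels (`zhat = (z - mean(z)) / (sd(z) + eps)`,
#' population standard deviation), and scales channel `c` by the Gaussian
#' excitation `a_c = exp(-zhat_c^2 / (2 c^2))`. Gates lie in (0, 1], so the
#' transform never increases the magnitude of an activation and never flips
#' its sign; channels whose mean activation sits at the across-channel
#' average pass through unchanged.
#'
#' @param f Numeric `H x W x C` feature map.
#' @param params A [gct_params()] object.
#' @return A feature map of the same shape as `f`.
#' @export
gct_apply <- function(f, params) {
  stopifnot(inherits(params, "gct_params"))
  d <- check_feature_map(f)
  a <- gct_gates(matrix(f, d[1] * d[2], d[3]), params$c, params$eps)
  f * rep(a, each = d[1] * d[2])
}

# gates for one image given its (H*W) x C matrix view
gct_gates <- function(m, c, eps) {
  z <- colMeans(m)
  sdz <- sqrt(mean((z - mean(z))^2)) # population sd across channels
  zhat <- (z - mean(z)) / (sdz + eps)
  exp(-zhat^2 / (2 * c^2))
}
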