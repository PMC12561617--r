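# Split protocols: 70-10-20 holdout and five-fold partitions, seeded and
# optionally stratified by class.

#' Split specification
#'
#' @param mode `"holdout_70_10_20"` or `"kfold_5"`.
#' @param seed Integer seed for the shuffle.
#' @param stratified Preserve per-class proportions in every part.
#' @return A `split_spec` object.
#' @export
split_spec <- function(mode = c("holdout_70_10_20", "kfold_5"),
                       seed = 1L, stratified = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  code
}

holdout_sizes <- function(n) {
  c(train = floor(0.7 * n), val = floor(0.1 * n),
    test = n - floor(0.7 * n) - floor(0.1 * n))
}

#' Partition a dataset
#'
#' For holdout mode, a seeded shuffle followed by sizes
#' `(floor(0.7 n), floor(0.1 n), rest)` for train/validation/test; for
#' k-fold mode, five disjoint folds whose sizes differ by at most one. In
#' stratified mode the same rule is applied within each class and the
#' parts are concatenated, keeping per-class proportions within one image
#' of the global ones.
#'
#' @param images List of [labeled_image()]s.
#' @param spec A [split_spec()].
#' @return For holdout: `list(train, val, test)` of image lists. For
#'   k-fold: a list of five image lists (`fold1` ... `fold5`). Both carry
#'   an `"indices"` attribute with the positions in `images`.
#' @export
split_images <- function(images, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(images)
  if (spec$mode == "holdout_70_10_20" && n < 10)
    stop("holdout split needs at least 10 images")
  if (spec$mode == "kfold_5" && n < 5)
    stop("five-fold split needs at least 5 images")
  idx_groups <- if (spec$stratified) {
    labs <- image_labels(images)
    lapply(split(seq_len(n), labs), identity)
  } else list(seq_len(n))

  if (spec$mode == "holdout_70_10_20") {
    parts <- list(train = integer(), val = integer(), test = integer())
    with_seed(spec$seed, {
      for (g in idx_groups) {
        g <- g[sample.int(length(g))]
        sz <- holdout_sizes(length(g))
        parts$train <- c(parts$train, g[seq_len(sz["train"])])
        parts$val <- c(parts$val, g[sz["train"] + seq_len(sz["val"])])
        parts$test <- c(parts$test, g[sz["train"] + sz["val"] +
                                        seq_len(sz["test"])])
      }
    })
    out <- lapply(parts, function(ii) {
      r <- images[ii]
      attr(r, "indices") <- ii
      r
    })
    return(out)
  }

  folds <- vector("list", 5L)
  with_seed(spec$seed, {
    start <- 0L # rotate the first fold across classes so global fold
                # sizes still differ by at most one under stratification
    for (g in idx_groups) {
      g <- g[sample.int(length(g))]
      assign_fold <- ((seq_along(g) - 1L + start) %% 5L) + 1L
      start <- (start + length(g)) %% 5L
      for (k in seq_len(5L)) folds[[k]] <- c(folds[[k]], g[assign_fold == k])
    }
  })
  names(folds) <- paste0("fold", seq_len(5L))
  lapply(folds, function(ii) {
    r <- images[ii]
    attr(r, "indices") <- ii
    r
  })
}
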