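# Repeated-training protocols: Monte Carlo over fresh splits, five-fold
# cross-validation, cross-dataset head adaptation, and the attention
# ablation grid.

macro_metric_names <- c("accuracy", "precision", "recall", "f1", "specificity")

#' Summarize repeated runs
#'
#' @param reports List of `metrics_report`s (one per run).
#' @return A `run_summary`: the reports plus mean and standard deviation
#'   of each macro metric.
#' @export
run_summary <- function(reports) {
  stopifnot(length(reports) >= 1)
  vals <- sapply(reports, function(r) unlist(r[macro_metric_names]))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(macro_metric_names))
  rownames(vals) <- macro_metric_names
  structure(list(reports = reports,
                 mean = rowMeans(vals),
                 sd = apply(vals, 1, stats::sd)),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("%d runs\n", length(x$reports)))
  for (m in names(x$mean))
    cat(sprintf("  %-11s %.4f +/- %.4f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Monte Carlo evaluation over fresh 70-10-20 splits
#'
#' Repeats the full cycle `runs` times: a fresh seeded 70-10-20 split, a
#' fresh weight initialization, training, and evaluation on the held-out
#' test part. Mean and standard deviation of each macro metric are
#' reported.
#'
#' @param spec A `model_spec`.
#' @param images List of [labeled_image()]s.
#' @param runs Number of repetitions (default 10).
#' @param seeds Integer vector of per-run seeds (default `1:runs`);
#'   duplicated seeds raise a warning.
#' @param cfg A [train_config()].
#' @param stratified Stratify the splits by class.
#' @return A `run_summary`.
#' @export
monte_carlo <- function(spec, images, runs = 10, seeds = seq_len(runs),
                        cfg = train_config(), stratified = FALSE) {
  stopifnot(length(seeds) == runs)
  if (anyDuplicated(seeds)) warning("duplicate seeds across Monte Carlo runs")
  levels <- sort(unique(image_labels(images)))
  reports <- lapply(seeds, function(s) {
    parts <- split_images(images, split_spec("holdout_70_10_20", seed = s,
                                             stratified = stratified))
    net <- build_model(spec, seed = s)
    cfg$seed <- s
    fit <- train_network(net, list(train = parts$train, val = parts$val), cfg)
    evaluate_model(fit$net, parts$test, levels = levels)$metrics
  })
  run_summary(reports)
}

#' Five-fold cross-validation
#'
#' Partitions the data into five folds, trains on four and tests on the
#' remaining one, rotating over all folds; every image is tested exactly
#' once. Early stopping uses a 10% carve-out of each training split as
#' validation.
#'
#' @inheritParams monte_carlo
#' @param seed Seed for the fold assignment and per-fold training.
#' @return A `run_summary` of five reports, with attribute `"n_tested"`,
#'   the pooled number of test predictions (equal to `length(images)`).
#' @export
five_fold_cv <- function(spec, images, seed = 1L, cfg = train_config(),
                         stratified = FALSE) {
  folds <- split_images(images, split_spec("kfold_5", seed = seed,
                                           stratified = stratified))
  levels <- sort(unique(image_labels(images)))
  n_tested <- 0L
  reports <- lapply(seq_len(5L), function(k) {
    test <- folds[[k]]
    rest <- unlist(folds[-k], recursive = FALSE)
    n_val <- max(1L, floor(0.1 * length(rest)))
    vi <- with_seed(seed + k, sample.int(length(rest), n_val))
    net <- build_model(spec, seed = seed + k)
    cfg$seed <- seed + k
    fit <- train_network(net, list(train = rest[-vi], val = rest[vi]), cfg)
    n_tested <<- n_tested + length(test)
    evaluate_model(fit$net, test, levels = levels)$metrics
  })
  out <- run_summary(reports)
  attr(out, "n_tested") <- n_tested
  out
}

#' Adapt a trained network's head to a new dataset and evaluate
#'
#' Cross-dataset transfer: when the target class count differs from the
#' source network's, the final dense layer is replaced by a fresh one with
#' `num_classes_target` outputs and ONLY that layer is trained (all other
#' weights frozen, bit-identical before and after); when the class counts
#' match, the network is evaluated directly with no fine-tuning.
#'
#' @param net_src A trained `ansa_net`.
#' @param target_data `list(train = , val = , test = )` of labeled images
#'   from the target dataset (train/val unused when class counts match).
#' @param num_classes_target Declared class count of the target dataset.
#' @param cfg A [train_config()] for the head fine-tune.
#' @return `list(metrics, net, trained)`: the evaluation report on
#'   `target_data$test`, the (possibly head-replaced) network, and whether
#'   any training occurred.
#' @export
adapt_head_and_eval <- function(net_src, target_data, num_classes_target,
                                cfg = train_config()) {
  levels <- sort(unique(image_labels(c(target_data$train, target_data$test))))
  if (length(levels) > num_classes_target)
    stop("target labels imply more classes (", length(levels),
         ") than declared (", num_classes_target, ")")
  if (net_src$spec$num_classes == num_classes_target) {
    return(list(metrics = evaluate_model(net_src, target_data$test,
                                         levels = levels)$metrics,
                net = net_src, trained = FALSE))
  }
  net <- net_src
  L <- length(net$layers)
  stopifnot(net$layers[[L]]$type == "dense")
  for (i in seq_len(L - 1L)) {
    if (net$layers[[i]]$type %in% c("conv", "dense", "l2sab"))
      net$layers[[i]]$frozen <- TRUE
  }
  n_in <- ncol(net$layers[[L]]$W)
  net$layers[[L]] <- layer_dense("fc2", n_in, num_classes_target)
  net$spec$num_classes <- as.integer(num_classes_target)
  all_levels <- sort(unique(image_labels(c(target_data$train, target_data$val,
                                           target_data$test))))
  fit <- train_network(net, list(
    train = as_image_batch(target_data$train, levels = all_levels),
    val = as_image_batch(target_data$val, levels = all_levels)), cfg)
  list(metrics = evaluate_model(fit$net, target_data$test,
                                levels = all_levels)$metrics,
       net = fit$net, trained = TRUE)
}

#' Attention ablation grid
#'
#' Trains and evaluates the ten variants of [ablation_variants()]
#' (attention block count 0-4, GCT on/off) with shared seeds, averaging
#' metrics over `seeds`. With zero blocks the GCT setting is irrelevant
#' and the two rows coincide exactly under shared seeds.
#'
#' @param spec A four-block `model_spec`.
#' @param images List of labeled images.
#' @param seeds Integer vector of seeds (one training run per seed per
#'   variant).
#' @param cfg A [train_config()].
#' @param stratified Stratify the splits.
#' @return A data frame with one row per variant: `n_blocks`, `use_gct`,
#'   and the mean macro metrics over seeds.
#' @export
ablation_run <- function(spec, images, seeds = 1L, cfg = train_config(),
                         stratified = FALSE) {
  variants <- ablation_variants(spec)
  levels <- sort(unique(image_labels(images)))
  rows <- lapply(variants, function(v) {
    reports <- lapply(seeds, function(s) {
      parts <- split_images(images, split_spec("holdout_70_10_20", seed = s,
                                               stratified = stratified))
      net <- build_model(v, seed = s)
      cfg$seed <- s
      fit <- train_network(net, list(train = parts$train, val = parts$val),
                           cfg)
      evaluate_model(fit$net, parts$test, levels = levels)$metrics
    })
    sm <- run_summary(reports)
    data.frame(n_blocks = attr(v, "n_blocks"), use_gct = attr(v, "use_gct"),
               t(sm$mean))
  })
  do.call(rbind, rows)
}
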