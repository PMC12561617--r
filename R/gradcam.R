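# Grad-CAM: gradient-weighted class activation maps for inspecting where
# the classifier looks.

#' Grad-CAM heatmap
#'
#' Computes the gradient of the target-class score (raw logit) with
#' respect to the activations of a backbone stage, averages the gradient
#' spatially per channel to obtain channel weights, forms the rectified
#' weighted sum of the activation channels, bilinearly upsamples it to the
#' input size, and min-max normalizes to `[0, 1]`. An all-zero map before
#' normalization stays all-zero.
#'
#' @param net An `ansa_net`.
#' @param image A [labeled_image()] or an `H x W` pixel matrix.
#' @param target_class Integer class index for the score; defaults to the
#'   predicted class.
#' @param target_layer Backbone stage name (`"conv1"` ... `"conv4"`). The
#'   activation is taken after the stage's attention block when one is
#'   present. The default is the deepest stage whose feature map is at
#'   least 8 x 8 (the last stage at full 256 x 256 resolution); deeper
#'   maps at small input sizes quantize the lesion below one cell and
#'   cannot localize it.
#' @return A `heatmap` object: `values` (input-sized matrix in `[0, 1]`),
#'   `target_class`, `target_layer`.
#' @export
grad_cam <- function(net, image, target_class = NULL, target_layer = NULL) {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  stopifnot(is.matrix(px))
  x <- array(px, c(dim(px), 1L, 1L))
  valid <- stage_names(net)
  if (is.null(target_layer)) {
    sizes <- nrow(px) / 2^seq_along(valid)
    ok <- which(sizes >= 8)
    target_layer <- valid[if (length(ok)) max(ok) else length(valid)]
  }
  if (!target_layer %in% valid)
    stop("unknown target layer '", target_layer, "'; valid layers: ",
         paste(valid, collapse = ", "))
  stage <- as.integer(sub("conv", "", target_layer))
  si <- stage_output_index(net, stage)

  fw <- net_forward(net, x, record = TRUE)
  logits <- fw$out
  if (is.null(target_class)) target_class <- which.max(logits)
  stopifnot(target_class >= 1, target_class <= nrow(logits))
  dlog <- matrix(0, nrow(logits), 1)
  dlog[target_class, 1] <- 1
  bw <- net_backward(net, fw$caches, dlog, record_dx = TRUE)

  act <- fw$outs[[si]]            # H' x W' x C x 1
  grad <- bw$dxs[[si + 1L]]       # gradient w.r.t. that activation
  C <- dim(act)[3]
  alpha <- vapply(seq_len(C), function(c) mean(grad[, , c, 1]), 0)
  cam <- matrix(0, dim(act)[1], dim(act)[2])
  for (c in seq_len(C)) cam <- cam + alpha[c] * act[, , c, 1]
  cam <- pmax(cam, 0)
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(cam),
                                           nrow(px), ncol(px)))
  up <- matrix(as.numeric(up), nrow(px), ncol(px))
  rng <- range(up)
  values <- if (rng[2] <= 0) up * 0
            else if (rng[2] == rng[1]) up * 0 + 1
            else (up - rng[1]) / (rng[2] - rng[1])
  structure(list(values = values, target_class = target_class,
                 target_layer = target_layer),
            class = "heatmap")
}

# perceptual blue->red colormap used for overlays
jet_map <- function(v) {
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "cyan", "green",
                                 "yellow", "red", "#7F0000"))
  ramp(as.vector(v)) / 255
}

#' Overlay a heatmap on a grayscale image
#'
#' Alpha-blends the color-mapped heatmap over the grayscale image
#' (rendered as RGB): `out = (1 - alpha) * image + alpha * colormap(heat)`.
#' With `alpha = 0` the output is the plain image; with `alpha = 1` the
#' pure color-mapped heatmap.
#'
#' @param image A [labeled_image()] or `H x W` matrix in `[0, 1]`.
#' @param heatmap A `heatmap` from [grad_cam()] (or a matching matrix).
#' @param alpha Blend weight in `[0, 1]`.
#' @param file Optional path; when given the overlay is written as PNG.
#' @return The `H x W x 3` RGB array, invisibly when writing to file.
#' @export
overlay <- function(image, heatmap, alpha = 0.5, file = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  stopifnot(all(dim(px) == dim(hv)))
  cols <- jet_map(hv)
  out <- array(0, c(dim(px), 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * px + alpha * matrix(cols[, ch], nrow(px))
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(file)) {
    png::writePNG(out, file)
    return(invisible(out))
  }
  out
}

#' Grad-CAM localization score against ground-truth masks
#'
#' For every correctly classified tumor image (one with a non-null mask),
#' computes the Grad-CAM heatmap and checks whether its peak falls inside
#' the ground-truth blob mask. Returns the fraction of hits, along with
#' the mean mask area fraction (the chance level for a uniformly random
#' peak).
#'
#' Scoring follows the pointing-game protocol of the saliency literature:
#' a hit requires the peak to fall inside the mask or within a small
#' tolerance margin of it (the customary 15-pixel margin at 224 x 224,
#' scaled to the image side), which absorbs the cell quantization of the
#' upsampled CAM grid.
#'
#' @param net A trained `ansa_net`.
#' @param images Labeled images with masks (e.g. synthetic phantoms).
#' @param levels Class levels matching the network's outputs.
#' @param target_layer Passed to [grad_cam()].
#' @param tolerance_px Pointing-game margin in pixels; default
#'   `round(15 * size / 224)`.
#' @return `list(score, n_eval, chance)`; `chance` is the mean mask area
#'   fraction, the hit rate of a uniformly random peak without margin.
#' @export
gradcam_localization <- function(net, images, levels = NULL,
                                 target_layer = NULL, tolerance_px = NULL) {
  if (is.null(levels)) levels <- sort(unique(image_labels(images)))
  batch <- as_image_batch(images, levels)
  pred <- predict(net, batch$x, type = "class")
  if (is.null(tolerance_px))
    tolerance_px <- round(15 * nrow(images[[1]]$pixels) / 224)
  hits <- 0L
  n_eval <- 0L
  area <- 0
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (is.null(im$mask) || pred[i] != batch$y[i]) next
    hm <- grad_cam(net, im, target_class = pred[i],
                   target_layer = target_layer)
    peak <- which(hm$values == max(hm$values), arr.ind = TRUE)[1, ]
    n_eval <- n_eval + 1L
    area <- area + mean(im$mask)
    inmask <- if (im$mask[peak[1], peak[2]] > 0) TRUE else {
      w <- which(im$mask > 0, arr.ind = TRUE)
      min((w[, 1] - peak[1])^2 + (w[, 2] - peak[2])^2) <= tolerance_px^2
    }
    if (max(hm$values) > 0 && inmask) hits <- hits + 1L
  }
  if (n_eval == 0) stop("no correctly classified masked images to evaluate")
  list(score = hits / n_eval, n_eval = n_eval, chance = area / n_eval)
}
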