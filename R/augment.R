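# Augmentation stage: each original image receives exactly one transformed
# copy, with the transformation drawn uniformly from seven candidates, so
# the image count doubles deterministically.

#' Augmentation specification
#'
#' The seven candidate transformations applied during dataset doubling:
#' vertical flip, horizontal flip, rotation (angle drawn uniformly in
#' +/- `rotation` degrees), horizontal and vertical shifts (fractions of
#' the image side, drawn uniformly in +/- the stated range), zoom (scale
#' factor in `1 +/- zoom`), and shear (factor in +/- `shear`).
#'
#' @param rotation Maximum rotation in degrees (default 90).
#' @param width_shift,height_shift Maximum shift fractions (default 0.1).
#' @param zoom Maximum zoom fraction (default 0.2).
#' @param shear Maximum shear factor (default 0.2).
#' @param seed Integer seed driving both the per-image transformation
#'   choice and the transformation parameters.
#' @return An `augmentation_spec` object.
#' @export
augmentation_spec <- function(rotation = 90, width_shift = 0.1,
                              height_shift = 0.1, zoom = 0.2, shear = 0.2,
                              seed = 1L) {
  structure(list(rotation = rotation, width_shift = width_shift,
                 height_shift = height_shift, zoom = zoom, shear = shear,
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

aug_transform_names <- c("vertical_flip", "horizontal_flip", "rotation",
                         "width_shift", "height_shift", "zoom", "shear")

# apply one named transformation to a pixel matrix; `par` is the sampled
# parameter (ignored by the flips). Flips and shifts are plain index
# operations; rotation, zoom and shear interpolate through EBImage.
apply_aug_transform <- function(pixels, name, par) {
  d <- dim(pixels)
  out <- switch(name,
    vertical_flip = pixels[d[1]:1, , drop = FALSE],
    horizontal_flip = pixels[, d[2]:1, drop = FALSE],
    rotation = EBImage::rotate(EBImage::Image(pixels), par,
                               output.dim = d, bg.col = 0),
    width_shift = shift_matrix(pixels, 0L, as.integer(round(par * d[2]))),
    height_shift = shift_matrix(pixels, as.integer(round(par * d[1])), 0L),
    zoom = {
      z <- EBImage::resize(EBImage::Image(pixels),
                           round(d[1] * par), round(d[2] * par))
      recenter_crop(EBImage::imageData(z), d)
    },
    shear = {
      m <- matrix(c(1, par, 0, 0, 1, 0), 3, 2)
      EBImage::affine(EBImage::Image(pixels), m, output.dim = d, bg.col = 0)
    },
    stop("unknown transformation: ", name))
  m <- if (is.matrix(out)) out else EBImage::imageData(out)
  pmin(pmax(matrix(as.numeric(m), d[1], d[2]), 0), 1)
}

# integer translation with zero fill (dr rows down, dc columns right)
shift_matrix <- function(m, dr, dc) {
  d <- dim(m)
  out <- matrix(0, d[1], d[2])
  sr <- max(1, 1 - dr):min(d[1], d[1] - dr)
  sc <- max(1, 1 - dc):min(d[2], d[2] - dc)
  if (length(sr) && length(sc)) out[sr + dr, sc + dc] <- m[sr, sc]
  out
}

# crop or zero-pad a matrix back to target dims, centered
recenter_crop <- function(m, d) {
  out <- matrix(0, d[1], d[2])
  sr <- max(1, (nrow(m) - d[1]) %/% 2 + 1)
  sc <- max(1, (ncol(m) - d[2]) %/% 2 + 1)
  tr <- max(1, (d[1] - nrow(m)) %/% 2 + 1)
  tc <- max(1, (d[2] - ncol(m)) %/% 2 + 1)
  nr <- min(d[1], nrow(m)); nc <- min(d[2], ncol(m))
  out[tr:(tr + nr - 1), tc:(tc + nc - 1)] <-
    m[sr:(sr + nr - 1), sc:(sc + nc - 1)]
  out
}

sample_aug_par <- function(spec, name) {
  switch(name,
    vertical_flip = NA_real_,
    horizontal_flip = NA_real_,
    rotation = stats::runif(1, -spec$rotation, spec$rotation),
    width_shift = stats::runif(1, -spec$width_shift, spec$width_shift),
    height_shift = stats::runif(1, -spec$height_shift, spec$height_shift),
    zoom = stats::runif(1, 1 - spec$zoom, 1 + spec$zoom),
    shear = stats::runif(1, -spec$shear, spec$shear))
}

#' Double a dataset by augmentation
#'
#' Returns the original images followed by exactly one augmented copy per
#' original. For each image one of the seven transformations is chosen
#' uniformly (probability 1/7 each) using `spec$seed`; labels are
#' preserved, and ground-truth masks (when present) receive the same
#' geometric transformation, re-binarized at 0.5. Output length is exactly
#' twice the input length.
#'
#' @param images List of [labeled_image()]s.
#' @param spec An [augmentation_spec()].
#' @return A list of `2 * length(images)` labeled images. Augmented copies
#'   carry `source_id` suffixed with the transformation name.
#' @export
augment_double <- function(images, spec = augmentation_spec()) {
  stopifnot(length(images) >= 1, inherits(spec, "augmentation_spec"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  picks <- sample.int(7L, length(images), replace = TRUE)
  copies <- vector("list", length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    nm <- aug_transform_names[picks[i]]
    par <- sample_aug_par(spec, nm)
    px <- apply_aug_transform(im$pixels, nm, par)
    mk <- if (!is.null(im$mask)) {
      mm <- apply_aug_transform(im$mask + 0, nm, par)
      (mm > 0.5) + 0
    }
    copies[[i]] <- labeled_image(px, im$label, mk,
                                 paste0(im$source_id, "+", nm))
  }
  c(images, copies)
}
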