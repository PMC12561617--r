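# Dataset readers. Two on-disk layouts are supported: one-folder-per-class
# JPEG/PNG trees, and per-slice MATLAB v7.3 (HDF5) containers with a
# `cjdata` group holding image, label, patient ID, tumor border and tumor
# mask. Every reader emits intensity-normalized square grayscale images.

#' Labeled image
#'
#' Container for one image: pixels as an `size x size` matrix in `[0, 1]`,
#' a class label, an optional ground-truth lesion mask (synthetic data
#' only) and a source identifier.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param label Class label (character).
#' @param mask Optional binary matrix congruent to `pixels`.
#' @param source_id Character identifier of the image's origin.
#' @return A `labeled_image` object.
#' @export
labeled_image <- function(pixels, label, mask = NULL, source_id = "") {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  if (!is.null(mask)) stopifnot(all(dim(mask) == dim(pixels)))
  structure(list(pixels = pixels, label = as.character(label),
                 mask = mask, source_id = as.character(source_id)),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("labeled_image %dx%d, label '%s'%s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$label,
              if (is.null(x$mask)) "" else ", with mask",
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

# EBImage object -> grayscale matrix in [0, 1]
to_gray_matrix <- function(img, size = NULL) {
  if (EBImage::colorMode(img) == EBImage::Color ||
      length(dim(img)) > 2) {
    img <- EBImage::channel(img, "luminance")
  }
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2) m <- m[, , 1]
  if (!is.null(size) && !all(dim(m) == c(size, size)))
    m <- EBImage::imageData(EBImage::resize(EBImage::Image(m), size, size))
  m <- pmin(pmax(m, 0), 1)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

#' Read a one-folder-per-class image directory
#'
#' Expects `root` to contain one subdirectory per class, each holding
#' JPEG/PNG files. Labels are the subdirectory names; files are visited in
#' deterministic lexicographic order, converted to grayscale (luminance
#' for RGB inputs), resized to `input_size` and normalized to `[0, 1]`.
#'
#' @param root Directory path.
#' @param input_size Target side length (default 256).
#' @return A list of [labeled_image()]s. Empty class directories raise a
#'   warning; unreadable files are skipped with a warning giving the count.
#' @export
read_image_folder <- function(root, input_size = 256) {
  stopifnot(dir.exists(root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop("no class subdirectories under ", root)
  out <- list()
  skipped <- 0L
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(jpe?g|png)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) {
      warning("empty class directory: ", cl)
      next
    }
    for (f in files) {
      img <- tryCatch(EBImage::readImage(f), error = function(e) NULL)
      if (is.null(img)) { skipped <- skipped + 1L; next }
      out[[length(out) + 1L]] <-
        labeled_image(to_gray_matrix(img, input_size), cl,
                      source_id = file.path(cl, basename(f)))
    }
  }
  if (skipped > 0) warning(skipped, " unreadable file(s) skipped")
  out
}

#' Read per-slice MATLAB v7.3 containers
#'
#' Reads a directory of `.mat` files in the HDF5-based v7.3 dialect, each
#' holding a `cjdata` group with fields `image`, `label`, `PID` and
#' optionally `tumorBorder`/`tumorMask`. Labels follow the dataset's
#' public convention 1 = meningioma, 2 = glioma, 3 = pituitary
#' (overridable). The image array is normalized to `[0, 1]` by its own
#' maximum (slices are stored as raw scanner intensities) and resized.
#'
#' @param root Directory containing `.mat` files.
#' @param input_size Target side length (default 256).
#' @param label_map Character vector mapping integer labels to class names.
#' @return A list of [labeled_image()]s in lexicographic file order, with
#'   the patient ID in `source_id`.
#' @export
read_cheng_mat <- function(root, input_size = 256,
                           label_map = c("meningioma", "glioma", "pituitary")) {
  stopifnot(dir.exists(root))
  files <- sort(list.files(root, pattern = "\\.mat$", full.names = TRUE))
  if (!length(files)) stop("no .mat files under ", root)
  lapply(files, function(f) {
    hdr <- readBin(f, "raw", 8L)
    if (!identical(hdr[1:4], as.raw(c(0x89, 0x48, 0x44, 0x46)))) {
      stop("unsupported .mat dialect in ", basename(f),
           ": only HDF5-based (v7.3) containers are supported")
    }
    contents <- rhdf5::h5ls(f)
    fields <- contents$name[contents$group == "/cjdata"]
    for (need in c("image", "label"))
      if (!need %in% fields)
        stop("missing field cjdata/", need, " in ", basename(f))
    img <- rhdf5::h5read(f, "cjdata/image")
    lab <- as.integer(rhdf5::h5read(f, "cjdata/label")[1])
    pid <- if ("PID" %in% fields) {
      raw_pid <- rhdf5::h5read(f, "cjdata/PID")
      if (is.numeric(raw_pid)) intToUtf8(as.integer(raw_pid))
      else paste(as.character(raw_pid), collapse = "")
    } else basename(f)
    if (lab < 1 || lab > length(label_map))
      stop("label ", lab, " out of range in ", basename(f))
    img <- matrix(as.numeric(img), nrow(img), ncol(img))
    if (max(img) > 0) img <- img / max(img)
    labeled_image(to_gray_matrix(EBImage::Image(img), input_size),
                  label_map[lab], source_id = pid)
  })
}

#' Labels of an image list
#'
#' @param images List of `labeled_image`s.
#' @return Character vector of labels.
#' @export
image_labels <- function(images) {
  vapply(images, function(im) im$label, "")
}

# stack a list of labeled_images into an H x W x 1 x N batch + integer labels
as_image_batch <- function(images, levels = NULL) {
  stopifnot(length(images) >= 1)
  d <- dim(images[[1]]$pixels)
  x <- array(0, c(d[1], d[2], 1L, length(images)))
  for (i in seq_along(images)) x[, , 1L, i] <- images[[i]]$pixels
  labs <- image_labels(images)
  if (is.null(levels)) levels <- sort(unique(labs))
  y <- match(labs, levels)
  if (anyNA(y)) stop("labels outside the declared level set")
  list(x = x, y = y, levels = levels)
}
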