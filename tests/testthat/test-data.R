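write_png_gray <- function(path, m) png::writePNG(m, path)

test_that("class-folder reader labels, resizes and orders deterministically", {
  root <- file.path(tempdir(), "folders")
  unlink(root, recursive = TRUE)
  for (cl in c("glioma", "meningioma")) {
    dir.create(file.path(root, cl), recursive = TRUE)
    set.seed(nchar(cl))
    for (i in 1:3)
      write_png_gray(file.path(root, cl, sprintf("s%02d.png", i)),
                     matrix(stats::runif(32 * 32), 32, 32))
  }
  # one oversized file exercising the resize path
  write_png_gray(file.path(root, "glioma", "big.png"),
                 matrix(stats::runif(96 * 96), 96, 96))

  imgs <- read_image_folder(root, input_size = 48)
  expect_length(imgs, 7)
  expect_setequal(unique(image_labels(imgs)), c("glioma", "meningioma"))
  expect_true(all(sapply(imgs, function(im) all(dim(im$pixels) == c(48, 48)))))
  expect_true(all(sapply(imgs, function(im)
    min(im$pixels) >= 0 && max(im$pixels) <= 1)))

  again <- read_image_folder(root, input_size = 48)
  expect_identical(sapply(imgs, `[[`, "source_id"),
                   sapply(again, `[[`, "source_id"))
  expect_identical(imgs[[1]]$pixels, again[[1]]$pixels)

  dir.create(file.path(root, "empty_class"))
  expect_warning(read_image_folder(root, input_size = 48), "empty class")
})

write_mat_fixture <- function(path, image, label, pid = "P001",
                              with_mask = TRUE, with_image = TRUE) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "cjdata")
  if (with_image) rhdf5::h5write(image, path, "cjdata/image")
  rhdf5::h5write(label, path, "cjdata/label")
  rhdf5::h5write(utf8ToInt(pid), path, "cjdata/PID")
  if (with_mask)
    rhdf5::h5write(matrix(0L, nrow(image), ncol(image)), path,
                   "cjdata/tumorMask")
  rhdf5::h5closeAll()
}

test_that("MATLAB v7.3 slice containers are read with the public label map", {
  root <- file.path(tempdir(), "mat")
  unlink(root, recursive = TRUE)
  dir.create(root)
  set.seed(1)
  write_mat_fixture(file.path(root, "a.mat"),
                    matrix(stats::runif(64 * 64) * 900, 64, 64), 2, "P010")
  write_mat_fixture(file.path(root, "b.mat"),
                    matrix(stats::runif(48 * 48) * 400, 48, 48), 1, "P011",
                    with_mask = FALSE)
  write_mat_fixture(file.path(root, "c.mat"),
                    matrix(stats::runif(64 * 64), 64, 64), 3, "P012")

  imgs <- read_cheng_mat(root, input_size = 32)
  expect_length(imgs, 3)
  expect_equal(image_labels(imgs), c("glioma", "meningioma", "pituitary"))
  expect_equal(sapply(imgs, `[[`, "source_id"), c("P010", "P011", "P012"))
  expect_true(all(sapply(imgs, function(im) all(dim(im$pixels) == c(32, 32)))))
  expect_true(all(sapply(imgs, function(im) max(im$pixels) <= 1)))

  again <- read_cheng_mat(root, input_size = 32)
  expect_identical(imgs[[2]]$pixels, again[[2]]$pixels)
})

test_that("malformed .mat containers produce targeted errors", {
  root <- file.path(tempdir(), "matbad")
  unlink(root, recursive = TRUE)
  dir.create(root)
  write_mat_fixture(file.path(root, "noimg.mat"),
                    matrix(1, 8, 8), 2, with_image = FALSE)
  expect_error(read_cheng_mat(root), "cjdata/image")
  unlink(file.path(root, "noimg.mat"))

  # legacy (pre-7.3) dialect: not HDF5
  legacy <- file.path(root, "legacy.mat")
  writeBin(c(charToRaw("MATLAB 5.0 MAT-file"), as.raw(rep(0, 200))), legacy)
  expect_error(read_cheng_mat(root), "v7.3")
})

test_that("augmentation doubles counts, preserves labels and picks uniformly", {
  set.seed(2)
  one <- list(labeled_image(matrix(stats::runif(64), 8, 8), "glioma",
                            source_id = "x"))
  out <- augment_double(one, augmentation_spec(seed = 5))
  expect_length(out, 2)
  expect_equal(image_labels(out), c("glioma", "glioma"))
  expect_identical(out[[1]]$pixels, one[[1]]$pixels)

  imgs <- replicate(7000, labeled_image(matrix(stats::runif(36), 6, 6), "c"),
                    simplify = FALSE)
  aug <- augment_double(imgs, augmentation_spec(seed = 9))
  expect_length(aug, 14000)
  picks <- sub(".*\\+", "", sapply(aug[7001:14000], `[[`, "source_id"))
  freq <- table(picks) / 7000
  expect_length(freq, 7)
  expect_true(all(abs(freq - 1 / 7) < 0.02))

  # reproducible given the seed
  aug2 <- augment_double(imgs, augmentation_spec(seed = 9))
  expect_identical(sapply(aug, `[[`, "source_id"),
                   sapply(aug2, `[[`, "source_id"))
  expect_identical(aug[[9000]]$pixels, aug2[[9000]]$pixels)

  # masks are transformed alongside the pixels
  mk <- matrix(0, 8, 8); mk[3:5, 3:5] <- 1
  masked <- list(labeled_image(matrix(stats::runif(64), 8, 8), "t", mask = mk))
  outm <- augment_double(masked, augmentation_spec(seed = 1))
  expect_false(is.null(outm[[2]]$mask))
  expect_setequal(unique(as.vector(outm[[2]]$mask)), c(0, 1))
})
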