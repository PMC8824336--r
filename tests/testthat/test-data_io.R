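make_disk_dataset <- function(n = 6, size = 32, seed = 1, dir = NULL) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  man <- generate_dataset(synth_config(n_samples = n, image_size = size,
                                       noise_sd = 0, color_jitter = 0,
                                       seed = seed), dir)
  list(dir = dir, man = man)
}

test_that("manifests round-trip through CSV with blanks preserved", {
  d <- make_disk_dataset()
  het <- heterogenize_manifest(d$man, drop_spec(1, 0.5, seed = 4))
  path <- file.path(d$dir, "het.csv")
  write_manifest(het, path)
  back <- load_manifest(path, quiet = TRUE)
  expect_equal(back$sample_id, het$sample_id)
  expect_equal(back$mask_atrium, het$mask_atrium)
  expect_equal(sum(back$mask_atrium == ""), sum(het$mask_atrium == ""))
})

test_that("manifest validation rejects malformed tables", {
  d <- make_disk_dataset()
  man_path <- file.path(d$dir, "manifest.csv")
  m <- read.csv(man_path, colClasses = "character")
  bad <- m; bad$sample_id[2] <- bad$sample_id[1]
  write.csv(bad, file.path(d$dir, "dup.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(d$dir, "dup.csv"), quiet = TRUE),
               "duplicate")
  bad2 <- m; bad2$extra <- "x"
  write.csv(bad2, file.path(d$dir, "extra.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(d$dir, "extra.csv"), quiet = TRUE),
               "unknown manifest column")
  bad3 <- m; bad3$image[1] <- "missing.png"
  write.csv(bad3, file.path(d$dir, "missing.csv"), row.names = FALSE)
  expect_error(load_manifest(file.path(d$dir, "missing.csv"), quiet = TRUE),
               "missing file")
  expect_error(load_manifest(file.path(d$dir, "nonexistent.csv")),
               "not found")
  # availability report counts samples per split
  expect_message(load_manifest(man_path), "train: 5 samples")
})

test_that("samples load with binarized masks and a complement background", {
  d <- make_disk_dataset()
  man <- load_manifest(file.path(d$dir, "manifest.csv"), quiet = TRUE)
  smp <- read_sample(man, man$sample_id[1])
  expect_equal(dim(smp$image), c(32, 32, 3))
  expect_equal(dim(smp$gt), c(32, 32, 4))
  expect_true(all(smp$gt %in% c(0, 1)))
  expect_equal(smp$m, c(1, 1, 1, 1))
  # foreground + background partition every pixel
  expect_true(all(apply(smp$gt, c(1, 2), sum) == 1))
  # a blanked mask yields a zero channel, m = 0, and a wider background
  het <- heterogenize_manifest(man, drop_spec(1, 1, seed = 2))
  attr(het, "dir") <- attr(man, "dir")
  train_id <- het$sample_id[het$split == "train"][1]
  smp2 <- read_sample(het, train_id)
  expect_equal(smp2$m[1], 0)
  expect_true(all(smp2$gt[, , 1] == 0))
  expect_true(all(smp2$gt[, , 4][smp$gt[, , 1] == 1] == 1))
})

test_that("overlapping foreground masks trigger an exclusivity warning", {
  dir <- withr::local_tempdir()
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(dir, "img.png"))
  mask <- matrix(0, 8, 8); mask[1:4, 1:4] <- 1
  png::writePNG(mask, file.path(dir, "a.png"))
  png::writePNG(mask, file.path(dir, "b.png"))
  man <- data.frame(sample_id = "s1", image = "img.png",
                    mask_a = "a.png", mask_b = "b.png", split = "train")
  write_manifest(man, file.path(dir, "m.csv"))
  man <- load_manifest(file.path(dir, "m.csv"), quiet = TRUE)
  expect_warning(read_sample(man, "s1"), "mutual exclusivity")
})

test_that("the identity augmentation reproduces the input exactly", {
  d <- make_disk_dataset(size = 32)
  man <- load_manifest(file.path(d$dir, "manifest.csv"), quiet = TRUE)
  smp <- read_sample(man, man$sample_id[1])
  cfg <- augment_config(rotation_range = 0, width_shift = 0, height_shift = 0,
                        shear_range = 0, zoom_range = 0,
                        horizontal_flip_prob = 0, target_size = c(32, 32))
  out <- augment(smp$image, smp$gt, cfg)
  expect_equal(out$image, smp$image, tolerance = 1e-12)
  expect_identical(out$gt, smp$gt)
})

test_that("a horizontal flip reverses image and masks identically", {
  d <- make_disk_dataset(size = 32)
  man <- load_manifest(file.path(d$dir, "manifest.csv"), quiet = TRUE)
  smp <- read_sample(man, man$sample_id[2])
  cfg <- augment_config(rotation_range = 0, width_shift = 0, height_shift = 0,
                        shear_range = 0, zoom_range = 0,
                        horizontal_flip_prob = 1, target_size = c(32, 32))
  out <- augment(smp$image, smp$gt, cfg)
  expect_equal(out$image, smp$image[, 32:1, ], tolerance = 1e-12)
  expect_identical(out$gt, smp$gt[, 32:1, ])
})

test_that("augmentation draws are reproducible and preserve mask structure", {
  d <- make_disk_dataset(size = 32)
  man <- load_manifest(file.path(d$dir, "manifest.csv"), quiet = TRUE)
  smp <- read_sample(man, man$sample_id[3])
  cfg <- augment_config(seed = 99, target_size = c(32, 32))
  a <- augment(smp$image, smp$gt, cfg)
  b <- augment(smp$image, smp$gt, cfg)
  expect_identical(a, b)
  # masks stay binary and mutually exclusive after resampling
  expect_true(all(a$gt %in% c(0, 1)))
  expect_true(all(apply(a$gt[, , 1:3], c(1, 2), sum) <= 1))
  expect_true(all(a$image >= 0 & a$image <= 1))
  # fresh draws differ without a pinned seed
  cfg2 <- augment_config(target_size = c(32, 32))
  set.seed(1); c1 <- augment(smp$image, smp$gt, cfg2)
  set.seed(2); c2 <- augment(smp$image, smp$gt, cfg2)
  expect_false(identical(c1$image, c2$image))
})

test_that("resizing rescales images and keeps ground truth binary", {
  d <- make_disk_dataset(size = 32)
  man <- load_manifest(file.path(d$dir, "manifest.csv"), quiet = TRUE)
  smp <- read_sample(man, man$sample_id[1])
  out <- resize_sample(smp$image, smp$gt, c(16, 16))
  expect_equal(dim(out$image), c(16, 16, 3))
  expect_equal(dim(out$gt), c(16, 16, 4))
  expect_true(all(out$gt %in% c(0, 1)))
})
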