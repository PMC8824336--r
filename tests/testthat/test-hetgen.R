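test_that("drop plans hit the exact per-class count", {
  ids <- sprintf("s%02d", 1:20)
  spec <- drop_spec(c(1, 2), rho = 0.25, seed = 7)
  plan <- plan_drops(ids, spec, n_classes = 4)
  expect_equal(sum(plan[, 1] == 0), 5)
  expect_equal(sum(plan[, 2] == 0), 5)
  expect_true(all(plan[, 3] == 1))
  expect_true(all(plan[, 4] == 1))
  expect_equal(attr(plan, "P"), 5L)
  # rho = 0: homogeneous limit
  expect_true(all(plan_drops(ids, drop_spec(1:2, 0, seed = 1), 4) == 1))
  # rho = 1: every eligible label dropped
  expect_true(all(plan_drops(ids, drop_spec(1, 1, seed = 1), 4)[, 1] == 0))
  # half-away-from-zero rounding: 10 * 0.25 = 2.5 -> 3
  p <- plan_drops(ids[1:10], drop_spec(1, 0.25, seed = 1), 2)
  expect_equal(sum(p[, 1] == 0), 3)
  expect_error(drop_spec(1, 1.2), "rho")
})

test_that("plans are deterministic in the seed and vary across seeds", {
  ids <- sprintf("s%02d", 1:20)
  p1 <- plan_drops(ids, drop_spec(1:2, 0.25, seed = 7), 3)
  p2 <- plan_drops(ids, drop_spec(1:2, 0.25, seed = 7), 3)
  expect_identical(p1, p2)
  # the plan does not depend on presentation order of the ids
  p3 <- plan_drops(rev(ids), drop_spec(1:2, 0.25, seed = 7), 3)
  expect_identical(p1, p3[ids, , drop = FALSE], ignore_attr = TRUE)
  others <- vapply(1:10, function(s)
    identical(unname(plan_drops(ids, drop_spec(1:2, 0.25, seed = s), 3)),
              unname(p1)), logical(1))
  expect_true(sum(others) <= 1)   # at most the coincidental match
})

test_that("online dropping zeroes channels and recomputes background", {
  ds <- synth_dataset(synth_config(n_samples = 8, image_size = 32,
                                   n_foreground = 2, seed = 5))
  C <- ds$n_classes
  view <- heterogeneous_view(ds$ids, C, drop_spec(1, 0.5, seed = 3),
                             background_index = C)
  dropped_id <- view$ids[view$plan[, 1] == 0][1]
  kept_id <- view$ids[view$plan[, 1] == 1][1]
  gt <- ds$samples[[dropped_id]]$gt
  out <- apply_drops(view, dropped_id, gt)
  expect_equal(out$m[1], 0)
  expect_true(all(out$gt[, , 1] == 0))
  # background absorbs the dropped class's pixels
  expect_true(all(out$gt[, , C][gt[, , 1] == 1] == 1))
  expect_equal(out$m[C], 1)
  # untouched sample passes through bit-identically
  kept <- apply_drops(view, kept_id, ds$samples[[kept_id]]$gt)
  expect_identical(kept$gt, ds$samples[[kept_id]]$gt)
  expect_true(all(kept$m == 1))
  expect_error(apply_drops(view, "nope", gt), "unknown sample")
})

test_that("strict background mode masks the complement background", {
  ds <- synth_dataset(synth_config(n_samples = 4, image_size = 32,
                                   n_foreground = 2, seed = 5))
  C <- ds$n_classes
  view <- heterogeneous_view(ds$ids, C, drop_spec(1, 1, seed = 3),
                             background_index = C, strict_background = TRUE)
  out <- apply_drops(view, ds$ids[1], ds$samples[[1]]$gt)
  expect_equal(out$m[C], 0)
  expect_true(all(out$gt[, , C] == 0))
})

test_that("repeated within-iteration queries are bit-identical", {
  ds <- synth_dataset(synth_config(n_samples = 10, image_size = 32,
                                   n_foreground = 2, seed = 9))
  C <- ds$n_classes
  view <- heterogeneous_view(ds$ids, C,
                             drop_spec(1:2, 0.5, seed = 11,
                                       persistence = "per_epoch"),
                             background_index = C)
  for (id in ds$ids) {   # oversampling: three queries per sample
    a <- apply_drops(view, id, ds$samples[[id]]$gt)
    b <- apply_drops(view, id, ds$samples[[id]]$gt)
    d <- apply_drops(view, id, ds$samples[[id]]$gt)
    expect_identical(a, b)
    expect_identical(a, d)
  }
  expect_equal(memory_size(view), 10)
})

test_that("memory reset starts a new iteration per the persistence mode", {
  ds <- synth_dataset(synth_config(n_samples = 12, image_size = 32,
                                   n_foreground = 2, seed = 13))
  C <- ds$n_classes
  # per-epoch: the plan is redrawn but the count stays exact
  view <- heterogeneous_view(ds$ids, C,
                             drop_spec(1, 0.5, seed = 17,
                                       persistence = "per_epoch"),
                             background_index = C)
  plans <- list(view$plan)
  for (e in 1:5) { reset_memory(view); plans[[e + 1]] <- view$plan }
  for (p in plans) expect_equal(sum(p[, 1] == 0), 6)
  expect_true(any(!vapply(plans[-1], identical, logical(1), plans[[1]])))
  expect_equal(memory_size(view), 0)
  # whole-training: reset is a no-op for the realized labels
  vw <- heterogeneous_view(ds$ids, C,
                           drop_spec(1, 0.5, seed = 17,
                                     persistence = "whole_training"),
                           background_index = C)
  before <- apply_drops(vw, ds$ids[1], ds$samples[[1]]$gt)
  reset_memory(vw)
  after <- apply_drops(vw, ds$ids[1], ds$samples[[1]]$gt)
  expect_identical(before, after)
})

test_that("two independently built views with one seed agree exactly", {
  ids <- sprintf("x%03d", 1:30)
  spec <- drop_spec(c(1, 3), 0.4, seed = 23)
  v1 <- heterogeneous_view(ids, 4, spec)
  v2 <- heterogeneous_view(ids, 4, spec)
  expect_identical(v1$plan, v2$plan)
})

test_that("offline heterogenization blanks manifests without touching files", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(synth_config(n_samples = 10, image_size = 32,
                                       seed = 21), dir)
  files <- list.files(dir, full.names = TRUE)
  sums_before <- tools::md5sum(files)
  het <- heterogenize_manifest(man, drop_spec(c(1, 2), 0.5, seed = 2))
  n_train <- sum(man$split == "train")
  expect_equal(sum(het$mask_atrium == ""), round(0.5 * n_train))
  expect_equal(sum(het$mask_ventricle == ""), round(0.5 * n_train))
  # test rows are never blanked
  expect_true(all(nzchar(het$mask_atrium[het$split == "test"])))
  # untouched classes and all source files intact
  expect_true(all(nzchar(het$mask_bulbus)))
  expect_identical(tools::md5sum(files), sums_before)
})

test_that("fixed views honor a caller-supplied plan", {
  ids <- c("a", "b", "c")
  plan <- matrix(c(1, 0, 1, 0, 1, 1), nrow = 3,
                 dimnames = list(ids, NULL))
  view <- fixed_view(ids, 2, plan)
  gt <- array(1, c(2, 2, 2))
  out <- apply_drops(view, "b", gt)
  expect_equal(out$m, c(0, 1))
  reset_memory(view)
  expect_identical(view$plan, plan)
})
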