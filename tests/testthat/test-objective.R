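test_that("per-class DSC matches hand-computed values and edge cases", {
  gt <- array(0, c(2, 2, 2))
  gt[1, 1, 1] <- 1; gt[1, 2, 1] <- 1
  pred <- array(0, c(2, 2, 2))
  pred[1, 1, 1] <- 1
  # overlap 1, gt area 2, pred area 1: (2*1 + eps)/(3 + eps)
  expect_equal(dsc_class(gt, pred, 1), (2 + 1e-7) / (3 + 1e-7), tolerance = 1e-12)
  # identical nonempty channels score exactly 1
  expect_identical(dsc_class(gt, gt, 1), 1)
  # empty vs empty is 1 by the epsilon guard
  expect_identical(dsc_class(gt, pred, 2), 1)
  expect_error(dsc_class(gt, pred, 3), "out of range")
  expect_error(dsc_class(gt, array(0, c(2, 3, 2)), 1), "mismatch")
})

test_that("DSC is symmetric in its two binary arguments", {
  set.seed(41)
  for (i in 1:10) {
    a <- array(rbinom(3 * 4 * 2, 1, 0.4), c(3, 4, 2))
    b <- array(rbinom(3 * 4 * 2, 1, 0.4), c(3, 4, 2))
    expect_equal(dsc_class(a, b, 1), dsc_class(b, a, 1), tolerance = 1e-12)
  }
})

test_that("masked Dice loss honors the availability vector", {
  gt <- array(0, c(2, 2, 2))
  gt[1, 1, 1] <- 1; gt[1, 2, 1] <- 1
  pred <- array(0, c(2, 2, 2))
  pred[1, 1, 1] <- 1
  cfg <- loss_config()
  # only class 1 labeled: (1 - 2/3) / 1
  expect_equal(dice_loss(gt, pred, c(1, 0), cfg), 1 - (2 + 1e-7) / (3 + 1e-7),
               tolerance = 1e-9)
  # perfect prediction with all masks present
  expect_lt(dice_loss(gt, gt, c(1, 1), cfg), 1e-6)
  # appending unlabeled channels leaves the value unchanged
  gt2 <- array(0, c(2, 2, 4)); gt2[, , 1:2] <- gt
  pred2 <- array(runif(16), c(2, 2, 4)); pred2[, , 1:2] <- pred
  expect_equal(dice_loss(gt2, pred2, c(1, 0, 0, 0), cfg),
               dice_loss(gt, pred, c(1, 0), cfg), tolerance = 1e-12)
  expect_error(dice_loss(gt, pred, c(0, 0), cfg), "no labeled class")
})

test_that("class-asymmetric loss matches the hand-worked single-pixel case", {
  gt <- array(0, c(1, 1, 2)); gt[1, 1, 1] <- 1
  pred <- array(c(0.1, 0.9), c(1, 1, 2))
  m <- c(1, 0)
  expect_equal(cal_class(1, gt, pred, m), plogis(0.9), tolerance = 1e-9)
  expect_equal(cal_loss(gt, pred, m), plogis(0.9), tolerance = 1e-9)
  # outer ground truth of zero kills the contribution
  gt0 <- gt; gt0[1, 1, 1] <- 0
  expect_identical(cal_class(1, gt0, pred, m), 0)
  # fully labeled input: every inner weight vanishes
  expect_identical(cal_loss(gt, pred, c(1, 1)), 0)
})

test_that("CAL ignores labeled channels and pixels outside the class", {
  set.seed(42)
  cs <- random_case(4, 4, 4)
  cfg <- loss_config(alpha = 0.5)
  m <- c(1, 1, 0, 0)
  base <- cal_class(1, cs$gt, cs$pred, m, cfg)
  # perturb a labeled channel (z = 2): no effect
  p2 <- cs$pred; p2[, , 2] <- runif(16)
  expect_equal(cal_class(1, cs$gt, p2, m, cfg), base, tolerance = 1e-12)
  # perturb an unlabeled channel only at pixels where gt_1 = 0: no effect
  p3 <- cs$pred
  out <- cs$gt[, , 1] == 0
  ch <- p3[, , 3]; ch[out] <- runif(sum(out)); p3[, , 3] <- ch
  expect_equal(cal_class(1, cs$gt, p3, m, cfg), base, tolerance = 1e-12)
  # permuting the unlabeled channels leaves cal_loss unchanged
  p4 <- cs$pred[, , c(1, 2, 4, 3)]
  expect_equal(cal_loss(cs$gt, p4, m, cfg), cal_loss(cs$gt, cs$pred, m, cfg),
               tolerance = 1e-12)
})

test_that("combined loss reduces to its parts at the alpha limits", {
  set.seed(43)
  for (i in 1:5) {
    cs <- random_case(3, 5, 3)
    cfg0 <- loss_config(alpha = 0)
    expect_equal(combined_loss(cs$gt, cs$pred, cs$m, cfg0),
                 dice_loss(cs$gt, cs$pred, cs$m, cfg0), tolerance = 1e-12)
    cfg4 <- loss_config(alpha = 0.4)
    comps <- combined_loss_components(cs$gt, cs$pred, cs$m, cfg4)
    expect_equal(comps$total, 0.6 * comps$dsc + 0.4 * comps$cal,
                 tolerance = 1e-12)
  }
  expect_error(loss_config(alpha = 1), "cannot operate alone")
  expect_error(loss_config(alpha = -0.1), "alpha")
})

test_that("loss ranges hold on random inputs", {
  set.seed(44)
  for (i in 1:20) {
    cs <- random_case(sample(2:6, 1), sample(2:6, 1), sample(2:4, 1))
    cfg <- loss_config(alpha = runif(1, 0, 0.9))
    comps <- combined_loss_components(cs$gt, cs$pred, cs$m, cfg)
    expect_gte(comps$dsc, 0); expect_lt(comps$dsc, 1)
    expect_gte(comps$cal, 0)
    expect_gte(comps$total, 0)
    if (all(cs$m == 1)) expect_identical(comps$cal, 0)
  }
})

test_that("vectorized losses agree with the naive loop oracle", {
  set.seed(45)
  for (i in 1:25) {
    h <- sample(2:8, 1); w <- sample(2:8, 1); C <- sample(2:4, 1)
    cs <- random_case(h, w, C)
    cfg <- loss_config(alpha = runif(1, 0, 0.99),
                       background_index = if (runif(1) < 0.5) C else NULL,
                       cal_normalize = runif(1) < 0.5)
    expect_equal(dice_loss(cs$gt, cs$pred, cs$m, cfg),
                 naive_dice_loss(cs$gt, cs$pred, cs$m, cfg), tolerance = 1e-6)
    expect_equal(cal_loss(cs$gt, cs$pred, cs$m, cfg),
                 naive_cal_loss(cs$gt, cs$pred, cs$m, cfg), tolerance = 1e-6)
    expect_equal(combined_loss(cs$gt, cs$pred, cs$m, cfg),
                 naive_combined_loss(cs$gt, cs$pred, cs$m, cfg),
                 tolerance = 1e-6)
  }
})

test_that("analytic prediction gradient matches finite differences", {
  set.seed(46)
  cs <- random_case(3, 3, 3)
  cfg <- loss_config(alpha = 0.35, background_index = 3, cal_normalize = TRUE)
  g <- combined_loss_grad(cs$gt, cs$pred, cs$m, cfg)
  eps <- 1e-6
  for (k in sample(length(cs$pred), 12)) {
    up <- cs$pred; up[k] <- up[k] + eps
    dn <- cs$pred; dn[k] <- dn[k] - eps
    fd <- (combined_loss(cs$gt, up, cs$m, cfg) -
             combined_loss(cs$gt, dn, cs$m, cfg)) / (2 * eps)
    expect_equal(g[k], fd, tolerance = 1e-4)
  }
})

test_that("softmax produces a per-pixel simplex and a consistent backward", {
  set.seed(47)
  logits <- array(rnorm(4 * 5 * 3, sd = 3), c(4, 5, 3))
  p <- softmax_channels(logits)
  expect_true(all(p > 0))
  expect_equal(apply(p, c(1, 2), sum), matrix(1, 4, 5), tolerance = 1e-12)
  # a constant gradient over channels maps to zero logit gradient
  d0 <- softmax_backward(array(0.7, dim(p)), p)
  expect_lt(max(abs(d0)), 1e-12)
})

test_that("IoU follows the set-count definition", {
  gt <- array(0, c(4, 4, 1)); pred <- array(0, c(4, 4, 1))
  gt[1:2, 1:2, 1] <- 1            # area 4
  pred[2:3, 1:2, 1] <- 1          # area 4, overlap 2
  expect_equal(iou_class(gt, pred, 1), 2 / 6, tolerance = 1e-12)
  expect_identical(iou_class(gt, gt, 1), 1)
  disj <- array(0, c(4, 4, 1)); disj[4, 4, 1] <- 1
  expect_identical(iou_class(gt, disj, 1), 0)
  empty <- array(0, c(4, 4, 1))
  expect_identical(iou_class(empty, empty, 1), 1)
})

test_that("PFR divides the statistic by the available labels", {
  expect_equal(pfr(0.9, 110, 10), 0.009, tolerance = 1e-12)
  expect_equal(pfr(0.8, 100), 0.008, tolerance = 1e-12)
  expect_equal(pfr(0.5, 40, 20), 2 * pfr(0.5, 60, 20), tolerance = 1e-12)
  expect_error(pfr(0.9, 10, 10), "n = S - P")
})

test_that("hard_masks takes the per-pixel argmax with lowest-index ties", {
  pred <- array(c(0.5, 0.2, 0.5, 0.3, 0, 0.5), c(1, 2, 3))
  hm <- hard_masks(pred)
  expect_equal(hm[1, 1, ], c(1, 0, 0))   # tie between 1 and 2 -> class 1
  expect_equal(hm[1, 2, ], c(0, 0, 1))
  onehot <- array(0, c(2, 2, 3)); onehot[, , 2] <- 1
  expect_identical(hard_masks(onehot), onehot)
})

test_that("dataset evaluation aggregates per-class statistics correctly", {
  gt <- array(0, c(4, 4, 3)); gt[1:2, , 1] <- 1; gt[, , 3] <- 1 - gt[, , 1]
  perfect <- gt
  ev <- evaluate_dataset(list(gt, gt), list(perfect, perfect),
                         background_index = 3, n_available = 50)
  expect_equal(ev$mdsc, 1, tolerance = 1e-9)
  expect_equal(ev$miou, 1, tolerance = 1e-9)
  expect_equal(ev$mpfr_dsc, pfr(ev$mdsc, 50), tolerance = 1e-12)
  expect_equal(ev$mdsc, mean(ev$per_class$dsc[1:2]), tolerance = 1e-12)
  expect_error(evaluate_dataset(list(), list()), "empty")
})
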