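# Naive triple-loop reference implementations of the objective, independent
# of the package's vectorized code paths. Kept deliberately literal.

naive_dsc <- function(gt, pred, cls, eps = 1e-7) {
  num <- 0; dg <- 0; dp <- 0
  for (u in seq_len(dim(gt)[1])) {
    for (v in seq_len(dim(gt)[2])) {
      num <- num + gt[u, v, cls] * pred[u, v, cls]
      dg <- dg + gt[u, v, cls]
      dp <- dp + pred[u, v, cls]
    }
  }
  (2 * num + eps) / (dg + dp + eps)
}

naive_dice_loss <- function(gt, pred, m, cfg) {
  acc <- 0
  for (cls in seq_along(m))
    acc <- acc + m[cls] * (1 - naive_dsc(gt, pred, cls, cfg$epsilon))
  acc / sum(m)
}

naive_cal_class <- function(cls, gt, pred, m, cfg) {
  f <- if (cfg$activation == "sigmoid") function(x) 1 / (1 + exp(-x)) else identity
  C <- length(m)
  total <- 0
  for (u in seq_len(dim(gt)[1])) {
    for (v in seq_len(dim(gt)[2])) {
      inner <- 0
      for (z in seq_len(C)) {
        if (z == cls) next
        if (!is.null(cfg$background_index) && z == cfg$background_index) next
        inner <- inner + f(pred[u, v, z]) * (1 - m[z])
      }
      total <- total + gt[u, v, cls] * inner
    }
  }
  if (cfg$cal_normalize) total <- total / (dim(gt)[1] * dim(gt)[2])
  total
}

naive_cal_loss <- function(gt, pred, m, cfg) {
  acc <- 0
  for (cls in seq_along(m)) {
    if (!is.null(cfg$background_index) && cls == cfg$background_index) next
    acc <- acc + m[cls] * naive_cal_class(cls, gt, pred, m, cfg)
  }
  acc
}

naive_combined_loss <- function(gt, pred, m, cfg) {
  (1 - cfg$alpha) * naive_dice_loss(gt, pred, m, cfg) +
    cfg$alpha * naive_cal_loss(gt, pred, m, cfg)
}

# Random small test case: one-hot ground truth, random simplex prediction,
# random mask vector with at least one labeled class.
random_case <- function(h, w, C) {
  gt <- array(0, dim = c(h, w, C))
  win <- sample.int(C, h * w, replace = TRUE)
  gt[cbind(rep(seq_len(h), w), rep(seq_len(w), each = h), win)] <- 1
  pm <- matrix(rexp(h * w * C), h * w, C)
  pred <- array(pm / rowSums(pm), dim = c(h, w, C))
  m <- rbinom(C, 1, 0.6)
  if (sum(m) == 0) m[sample.int(C, 1)] <- 1
  list(gt = gt, pred = pred, m = m)
}
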