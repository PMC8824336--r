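## Loss functions and evaluation metrics for heterogeneously labeled
## multi-class segmentation.
##
## Arrays are (h, w, C): ground truths binary, predictions a per-pixel
## probability simplex over the C channels. The per-sample mask vector m
## (length C, values 0/1) flags which classes actually carry a ground-truth
## mask; all losses consult m and never infer absence from an all-zero
## channel.

#' Loss configuration
#'
#' Bundles the tunable parameters of the combined objective
#' \eqn{L = (1-\alpha) L_{DSC} + \alpha L_{CAL}}.
#'
#' @param alpha Weight of the class-asymmetric loss, in `[0, 1)`. `alpha = 1`
#'   is rejected: the CAL term only constrains unlabeled channels and cannot
#'   drive training on its own.
#' @param epsilon Small positive constant added to numerator and denominator
#'   of the Dice coefficient so empty-vs-empty channels score 1 and division
#'   by zero never occurs. Default `1e-7`.
#' @param activation Monotone map with range in `[0, 1]` applied to predicted
#'   probabilities inside the CAL term; `"sigmoid"` (default, the logistic
#'   function) or `"identity"`. Note `sigmoid(0) = 0.5`, so an unlabeled
#'   channel contributes 0.5 per labeled pixel even at probability 0.
#' @param background_index Index of the background channel, or `NULL`. When
#'   set, background is excluded from the CAL term entirely (outer and inner
#'   sums): a complement-defined background cannot be distinguished from
#'   unlabeled pixels.
#' @param cal_normalize If `TRUE`, divide the CAL term by the pixel count
#'   `w*h` so its scale is comparable with the Dice loss. Default `FALSE`
#'   (plain pixel-count sum).
#' @return An object of class `frugalseg_loss_config`.
#' @export
loss_config <- function(alpha = 0, epsilon = 1e-7,
                        activation = c("sigmoid", "identity"),
                        background_index = NULL, cal_normalize = FALSE) {
  activation <- match.arg(activation)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("'alpha' must be a single number in [0, 1); alpha = 1 is invalid ",
         "because the class-asymmetric loss only constrains unlabeled ",
         "channels and cannot operate alone", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("'epsilon' must be > 0", call. = FALSE)
  if (!is.null(background_index)) {
    background_index <- as.integer(background_index)
    stopifnot(length(background_index) == 1L, background_index >= 1L)
  }
  structure(list(alpha = alpha, epsilon = epsilon, activation = activation,
                 background_index = background_index,
                 cal_normalize = isTRUE(cal_normalize)),
            class = "frugalseg_loss_config")
}

cal_activation <- function(cfg) {
  switch(cfg$activation,
         sigmoid  = list(f = function(x) 1 / (1 + exp(-x)),
                         fprime = function(x) { s <- 1 / (1 + exp(-x)); s * (1 - s) }),
         identity = list(f = identity, fprime = function(x) rep(1, length(x))))
}

check_pair <- function(gt, pred) {
  if (!is.array(gt) || length(dim(gt)) != 3L)
    stop("ground truth must be a (h, w, C) array", call. = FALSE)
  if (!is.array(pred) || length(dim(pred)) != 3L)
    stop("prediction must be a (h, w, C) array", call. = FALSE)
  if (!identical(dim(gt), dim(pred)))
    stop("dimension mismatch: ground truth is ",
         paste(dim(gt), collapse = "x"), " but prediction is ",
         paste(dim(pred), collapse = "x"), call. = FALSE)
  invisible(dim(gt))
}

check_class <- function(class, C) {
  if (!is.numeric(class) || length(class) != 1L || class < 1 || class > C)
    stop("class index ", class, " out of range 1..", C, call. = FALSE)
  as.integer(class)
}

#' Soft Dice-Sørensen coefficient of one class channel
#'
#' \deqn{DSC_c = \frac{2 \sum_{u,v} \tilde y_{u,v,c}\, \hat y_{u,v,c} + \epsilon}
#'                    {\sum_{u,v} \tilde y_{u,v,c} + \sum_{u,v} \hat y_{u,v,c} + \epsilon}}
#'
#' `epsilon` guards the empty-vs-empty case, which scores exactly 1.
#'
#' @param gt Binary `(h, w, C)` ground-truth array.
#' @param pred Real `(h, w, C)` prediction array.
#' @param class 1-based channel index.
#' @param epsilon Stabilizer, default `1e-7`.
#' @return A number in `(0, 1]`.
#' @export
dsc_class <- function(gt, pred, class, epsilon = 1e-7) {
  d <- check_pair(gt, pred)
  class <- check_class(class, d[3L])
  g <- gt[, , class]
  p <- pred[, , class]
  (2 * sum(g * p) + epsilon) / (sum(g) + sum(p) + epsilon)
}

per_class_dsc <- function(gt, pred, epsilon) {
  inter <- colSums(gt * pred, dims = 2L)
  (2 * inter + epsilon) /
    (colSums(gt, dims = 2L) + colSums(pred, dims = 2L) + epsilon)
}

#' Mask-weighted Dice loss over labeled channels
#'
#' \deqn{L_{DSC} = \frac{\sum_c m_c (1 - DSC_c)}{\sum_c m_c}}
#'
#' Only channels with an available ground-truth mask (`m == 1`) contribute,
#' and the sum is normalized by the number of present masks so the loss scale
#' does not depend on how many classes happen to be labeled.
#'
#' @inheritParams dsc_class
#' @param m Binary availability vector of length `C`.
#' @param cfg A [loss_config()].
#' @return A number in `[0, 1)`.
#' @export
dice_loss <- function(gt, pred, m, cfg = loss_config()) {
  d <- check_pair(gt, pred)
  stopifnot(length(m) == d[3L], all(m %in% c(0, 1)))
  if (sum(m) < 1)
    stop("no labeled class: every entry of the mask vector m is 0, ",
         "so the Dice loss is undefined", call. = FALSE)
  dsc <- per_class_dsc(gt, pred, cfg$epsilon)
  sum(m * (1 - dsc)) / sum(m)
}

## Inner CAL weights: which channels z count as "unlabeled" targets.
cal_inner_weights <- function(m, cfg) {
  wz <- 1 - m
  if (!is.null(cfg$background_index)) wz[cfg$background_index] <- 0
  wz
}

## Outer CAL weights: which labeled channels c are scored.
cal_outer_weights <- function(m, cfg) {
  u <- m
  if (!is.null(cfg$background_index)) u[cfg$background_index] <- 0
  u
}

#' Class-asymmetric loss of one labeled class
#'
#' For a labeled class `c`, sums over all pixels belonging to `c` the
#' activated probability mass the prediction places in *unlabeled* channels:
#' \deqn{CAL_c = \sum_{u,v} \tilde y_{u,v,c} \sum_{z \ne c} f(\hat y_{u,v,z}) (1 - m_z).}
#' A pixel with known class `c` cannot belong to any other class (mutual
#' exclusivity), so confident predictions for channels lacking ground truth
#' are penalized there. The background channel, when declared in `cfg`, is
#' excluded from the inner sum. With `cfg$cal_normalize` the sum is divided
#' by the pixel count.
#'
#' @inheritParams dice_loss
#' @param class 1-based index of a labeled class (`m[class] == 1`).
#' @return A non-negative number.
#' @export
cal_class <- function(class, gt, pred, m, cfg = loss_config()) {
  d <- check_pair(gt, pred)
  class <- check_class(class, d[3L])
  stopifnot(length(m) == d[3L])
  act <- cal_activation(cfg)
  wz <- cal_inner_weights(m, cfg)
  wz[class] <- 0
  pm <- matrix(pred, nrow = d[1L] * d[2L], ncol = d[3L])
  inner <- as.vector(act$f(pm) %*% wz)
  v <- sum(as.vector(gt[, , class]) * inner)
  if (cfg$cal_normalize) v <- v / (d[1L] * d[2L])
  v
}

#' Class-asymmetric loss over all labeled classes
#'
#' \deqn{L_{CAL} = \sum_c m_c\, CAL_c,} with the background channel (when
#' declared) excluded from the outer sum as well. For a fully labeled sample
#' every inner weight `(1 - m_z)` vanishes and the loss is exactly 0.
#'
#' @inheritParams dice_loss
#' @return A non-negative number.
#' @export
cal_loss <- function(gt, pred, m, cfg = loss_config()) {
  d <- check_pair(gt, pred)
  stopifnot(length(m) == d[3L])
  u <- cal_outer_weights(m, cfg)
  wz <- cal_inner_weights(m, cfg)
  if (all(wz == 0) || all(u == 0)) return(0)
  act <- cal_activation(cfg)
  hw <- d[1L] * d[2L]
  pm <- matrix(pred, nrow = hw, ncol = d[3L])
  gm <- matrix(gt, nrow = hw, ncol = d[3L])
  ## for labeled c the inner weight wz[c] is already 0, so the exclusion
  ## z != c is automatic and the inner sum is shared across classes
  v <- sum(as.vector(act$f(pm) %*% wz) * as.vector(gm %*% u))
  if (cfg$cal_normalize) v <- v / hw
  v
}

#' Combined objective for heterogeneous labels
#'
#' \deqn{L = (1 - \alpha) L_{DSC} + \alpha L_{CAL}.}
#' `alpha` trades the channel-wise (horizontal) Dice optimization against the
#' per-pixel probability-distribution (vertical) optimization of the CAL
#' term.
#'
#' @inheritParams dice_loss
#' @return A non-negative number. `combined_loss_components()` returns the
#'   list `total`, `dsc`, `cal`.
#' @export
combined_loss <- function(gt, pred, m, cfg = loss_config()) {
  combined_loss_components(gt, pred, m, cfg)$total
}

#' @rdname combined_loss
#' @export
combined_loss_components <- function(gt, pred, m, cfg = loss_config()) {
  ld <- dice_loss(gt, pred, m, cfg)
  lc <- cal_loss(gt, pred, m, cfg)
  list(total = (1 - cfg$alpha) * ld + cfg$alpha * lc, dsc = ld, cal = lc)
}

#' Gradient of the combined objective with respect to the prediction
#'
#' Analytic derivative of [combined_loss()] in the prediction array, used by
#' the training loop (and checkable against finite differences). The Dice
#' part differentiates the softened coefficient; the CAL part routes through
#' the activation derivative at unlabeled channels.
#'
#' @inheritParams dice_loss
#' @return A `(h, w, C)` array `dL/dpred`.
#' @export
combined_loss_grad <- function(gt, pred, m, cfg = loss_config()) {
  d <- check_pair(gt, pred)
  h <- d[1L]; w <- d[2L]; C <- d[3L]
  if (sum(m) < 1) stop("no labeled class", call. = FALSE)
  eps <- cfg$epsilon
  inter <- colSums(gt * pred, dims = 2L)
  den <- colSums(gt, dims = 2L) + colSums(pred, dims = 2L) + eps
  num <- 2 * inter + eps
  grad <- array(0, dim = d)
  sm <- sum(m)
  for (c in seq_len(C)) {
    if (m[c] == 0) next
    ## d(1-DSC_c)/dp = -(2*gt*den - num)/den^2
    grad[, , c] <- grad[, , c] + (1 - cfg$alpha) / sm *
      (num[c] - 2 * gt[, , c] * den[c]) / den[c]^2
  }
  if (cfg$alpha > 0) {
    u <- cal_outer_weights(m, cfg)
    wz <- cal_inner_weights(m, cfg)
    if (any(wz > 0) && any(u > 0)) {
      act <- cal_activation(cfg)
      hw <- h * w
      gm <- matrix(gt, nrow = hw, ncol = C)
      lab <- as.vector(gm %*% u)         # labeled ground-truth mass per pixel
      scale <- cfg$alpha / (if (cfg$cal_normalize) hw else 1)
      pm <- matrix(pred, nrow = hw, ncol = C)
      gcal <- (lab * act$fprime(pm)) %*% diag(wz, nrow = C)
      grad <- grad + array(scale * gcal, dim = d)
    }
  }
  grad
}

#' Per-pixel softmax and its backward pass
#'
#' `softmax_channels()` maps logits to a per-pixel probability simplex over
#' the channel dimension; `softmax_backward()` pulls a gradient in the
#' probabilities back to the logits.
#'
#' @param logits,pred,dpred `(h, w, C)` arrays.
#' @return A `(h, w, C)` array.
#' @export
softmax_channels <- function(logits) {
  d <- dim(logits)
  lm <- matrix(logits, nrow = d[1L] * d[2L], ncol = d[3L])
  rowmax <- lm[, 1L]
  for (j in seq_len(d[3L])[-1L]) rowmax <- pmax(rowmax, lm[, j])
  lm <- exp(lm - rowmax)
  array(lm / rowSums(lm), dim = d)
}

#' @rdname softmax_channels
#' @export
softmax_backward <- function(dpred, pred) {
  d <- dim(pred)
  pm <- matrix(pred, nrow = d[1L] * d[2L], ncol = d[3L])
  dm <- matrix(dpred, nrow = d[1L] * d[2L], ncol = d[3L])
  array(pm * (dm - rowSums(dm * pm)), dim = d)
}

#' Intersection over union of one class channel
#'
#' Standard IoU on hard (binary) masks; both-empty counts as perfect overlap
#' (1.0).
#'
#' @param gt Binary `(h, w, C)` ground truth.
#' @param pred_binary Binary `(h, w, C)` array, e.g. from [hard_masks()].
#' @param class 1-based channel index.
#' @return A number in `[0, 1]`.
#' @export
iou_class <- function(gt, pred_binary, class) {
  d <- check_pair(gt, pred_binary)
  class <- check_class(class, d[3L])
  g <- gt[, , class] > 0.5
  p <- pred_binary[, , class] > 0.5
  uni <- sum(g | p)
  if (uni == 0) return(1)
  sum(g & p) / uni
}

#' Hard per-pixel class assignment
#'
#' Per-pixel argmax of a soft prediction, ties broken toward the lowest class
#' index, returned as a one-hot `(h, w, C)` array.
#'
#' @param pred Real `(h, w, C)` prediction array.
#' @return Binary `(h, w, C)` array.
#' @export
hard_masks <- function(pred) {
  d <- dim(pred)
  pm <- matrix(pred, nrow = d[1L] * d[2L], ncol = d[3L])
  win <- max.col(pm, ties.method = "first")
  out <- matrix(0, nrow = d[1L] * d[2L], ncol = d[3L])
  out[cbind(seq_along(win), win)] <- 1
  array(out, dim = d)
}

#' Performance Frugality Ratio
#'
#' Divides a performance statistic `M` (a DSC or IoU value, say) by the
#' number of available labels `n = S - P`, where `S` is the number of
#' sample-label pairs and `P` the number of dropped labels. Reaching the same
#' statistic with fewer labels yields a larger PFR.
#'
#' @param statistic The statistic value `M`.
#' @param total_samples Total sample-label pairs `S`.
#' @param dropped_labels Dropped label count `P` (default 0).
#' @return `statistic / (total_samples - dropped_labels)`.
#' @export
pfr <- function(statistic, total_samples, dropped_labels = 0) {
  stopifnot(is.numeric(statistic), length(statistic) == 1L)
  n <- total_samples - dropped_labels
  if (length(n) != 1L || n < 1)
    stop("number of available labels n = S - P must be >= 1 (got ", n, ")",
         call. = FALSE)
  statistic / n
}

#' Evaluate predictions against fully labeled ground truth
#'
#' Computes per-class DSC and IoU on hard (argmax) masks for a set of test
#' samples, their means over the foreground classes (mDSC, mIoU), and the
#' mean PFR given the training-set label availability.
#'
#' @param gts List of binary `(h, w, C)` ground-truth arrays (fully labeled).
#' @param preds List of `(h, w, C)` predictions, same length.
#' @param class_names Optional channel names (length `C`).
#' @param background_index Channel excluded from the foreground means and
#'   reported separately; `NULL` to average all channels.
#' @param n_available Number of available training labels `n = S - P` used
#'   for the PFR columns, or `NULL` to skip them.
#' @param epsilon Dice stabilizer.
#' @return A list of class `frugalseg_eval` with elements `per_class` (a
#'   data.frame of per-class mean DSC/IoU over samples), `mdsc`, `miou`,
#'   `mpfr_dsc`, `mpfr_iou` and `n_available`.
#' @export
evaluate_dataset <- function(gts, preds, class_names = NULL,
                             background_index = NULL, n_available = NULL,
                             epsilon = 1e-7) {
  if (length(gts) == 0L) stop("empty sample list", call. = FALSE)
  if (length(gts) != length(preds))
    stop("gts and preds must have the same length", call. = FALSE)
  C <- dim(gts[[1L]])[3L]
  dscs <- ious <- matrix(NA_real_, nrow = length(gts), ncol = C)
  for (i in seq_along(gts)) {
    hp <- hard_masks(preds[[i]])
    for (c in seq_len(C)) {
      dscs[i, c] <- dsc_class(gts[[i]], hp, c, epsilon)
      ious[i, c] <- iou_class(gts[[i]], hp, c)
    }
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(C))
  per_class <- data.frame(class = class_names,
                          dsc = colMeans(dscs), iou = colMeans(ious),
                          row.names = NULL)
  fg <- seq_len(C)
  if (!is.null(background_index)) fg <- setdiff(fg, background_index)
  res <- list(per_class = per_class,
              mdsc = mean(per_class$dsc[fg]),
              miou = mean(per_class$iou[fg]),
              n_available = n_available,
              mpfr_dsc = NULL, mpfr_iou = NULL)
  if (!is.null(n_available)) {
    res$mpfr_dsc <- pfr(res$mdsc, n_available)
    res$mpfr_iou <- pfr(res$miou, n_available)
  }
  class(res) <- "frugalseg_eval"
  res
}

#' @export
print.frugalseg_eval <- function(x, ...) {
  cat("Segmentation evaluation\n")
  print(x$per_class, digits = 4)
  cat(sprintf("foreground means: mDSC = %.4f, mIoU = %.4f\n", x$mdsc, x$miou))
  if (!is.null(x$mpfr_dsc))
    cat(sprintf("mPFR (n = %d available labels): DSC %.3g, IoU %.3g\n",
                x$n_available, x$mpfr_dsc, x$mpfr_iou))
  invisible(x)
}
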