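## Desk-scale experiment harness: four study designs (label ablation, class
## transfer, dataset merging, loss-weight sweep) run end-to-end on the
## synthetic benchmark, with per-run statistics aggregated into a result
## table, plus the label-budget calculator.

#' Label-budget arithmetic
#'
#' Total mask count and annotation time for homogeneously labeling a dataset:
#' `total_masks = n_samples * n_classes`, at `seconds_per_mask` each
#' (annotating one class mask for one image takes about 25 seconds with a
#' pixel-annotation tool).
#'
#' @param n_samples Number of images.
#' @param n_classes Number of annotated classes per image.
#' @param seconds_per_mask Annotation time per mask, seconds. Default 25.
#' @return `list(total_masks, total_hours)`.
#' @export
label_budget <- function(n_samples, n_classes, seconds_per_mask = 25) {
  stopifnot(n_samples >= 1, n_classes >= 1, seconds_per_mask > 0,
            n_samples == as.integer(n_samples),
            n_classes == as.integer(n_classes))
  total_masks <- n_samples * n_classes
  list(total_masks = total_masks,
       total_hours = total_masks * seconds_per_mask / 3600)
}

#' Experiment specification
#'
#' Bundles an experiment design with its sweep values, repeat count and base
#' configurations. Desk-scale defaults: a 200-image 64x64 synthetic benchmark
#' (three foreground classes for the ablation design, two for the
#' transfer/merge/alpha designs, mirroring the two-class reduction those
#' designs use), a tiny network, fixed-epoch Adam training and the combined
#' loss with `alpha = 0.4` and pixel-normalized CAL.
#'
#' @param kind One of `"ablation"`, `"transfer"`, `"merge"`, `"alpha_sweep"`.
#' @param values Sweep values: drop shares `rho` in `[0, 1]` (ablation,
#'   transfer), split proportions in `(0, 1)` (merge), or loss weights
#'   `alpha` in `[0, 1)` (alpha_sweep).
#' @param runs Repeats per configuration (fresh dataset, weights and drop
#'   plan per run). Default 3.
#' @param synth_cfg,net_cfg,train_cfg,loss_cfg Optional base configurations
#'   overriding the desk-scale defaults.
#' @param new_class Index of the partially labeled class in the transfer and
#'   alpha designs. Default 1.
#' @param seed Master seed; all per-run seeds derive from it.
#' @return An object of class `frugalseg_experiment_spec`.
#' @export
experiment_spec <- function(kind = c("ablation", "transfer", "merge", "alpha_sweep"),
                            values, runs = 3, synth_cfg = NULL, net_cfg = NULL,
                            train_cfg = NULL, loss_cfg = NULL, new_class = 1L,
                            seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(values) >= 1, runs >= 1)
  if (kind %in% c("ablation", "transfer") &&
      (any(values < 0) || any(values > 1)))
    stop("drop shares rho must lie in [0, 1]", call. = FALSE)
  if (kind == "ablation" && !any(values == 0))
    stop("the ablation sweep must include rho = 0 (the supervised baseline)",
         call. = FALSE)
  if (kind == "merge" && (any(values <= 0) || any(values >= 1)))
    stop("split proportions must lie strictly inside (0, 1)", call. = FALSE)
  if (kind == "alpha_sweep" && (any(values < 0) || any(values >= 1)))
    stop("alpha values must lie in [0, 1); alpha = 1 is invalid", call. = FALSE)
  nf <- if (kind == "ablation") 3L else 2L
  if (is.null(synth_cfg)) synth_cfg <- synth_config(n_foreground = nf)
  C <- synth_cfg$n_foreground + 1L
  if (is.null(net_cfg))
    net_cfg <- tiny_network_config(input_size = rep(synth_cfg$image_size, 2L),
                                   num_classes = C)
  if (is.null(train_cfg))
    train_cfg <- train_config(batch_size = 10, learning_rate = 5e-3,
                              max_epochs = 8, validation_fraction = 0)
  if (is.null(loss_cfg))
    loss_cfg <- loss_config(alpha = 0.4, background_index = C,
                            cal_normalize = TRUE)
  structure(list(kind = kind, values = values, runs = as.integer(runs),
                 synth_cfg = synth_cfg, net_cfg = net_cfg,
                 train_cfg = train_cfg, loss_cfg = loss_cfg,
                 new_class = as.integer(new_class), seed = as.integer(seed)),
            class = "frugalseg_experiment_spec")
}

## Train one model and evaluate it on the fully labeled test split.
## Returns per-class rows; n_available feeds the PFR columns.
train_and_eval <- function(spec, dataset, value, run, view = NULL,
                           sampler = NULL, loss_cfg = NULL, n_available) {
  run_seed <- derive_seed(spec$seed, run)
  net_cfg <- spec$net_cfg
  net_cfg$seed <- derive_seed(run_seed, 19L)
  tcfg <- spec$train_cfg
  tcfg$seed <- derive_seed(run_seed, 23L)
  if (is.null(loss_cfg)) loss_cfg <- spec$loss_cfg
  fit <- train_network(build_network(net_cfg), dataset, tcfg, loss_cfg,
                       view = view, sampler = sampler)
  test_ids <- dataset$ids[dataset$split == "test"]
  gts <- lapply(dataset$samples[test_ids], `[[`, "gt")
  preds <- predict_network(fit$net,
                           lapply(dataset$samples[test_ids], `[[`, "image"))
  ev <- evaluate_dataset(gts, preds,
                         class_names = c(dataset$class_names, "background"),
                         background_index = dataset$n_classes,
                         n_available = n_available)
  cbind(data.frame(kind = spec$kind, value = value, run = run,
                   seed = run_seed, stringsAsFactors = FALSE),
        rbind(ev$per_class,
              data.frame(class = "mean", dsc = ev$mdsc, iou = ev$miou)),
        n_available = n_available)
}

## Aggregate raw per-run rows into the result table:
## (configuration, class, statistic, mean, sd over runs, mPFR).
aggregate_results <- function(raw) {
  long <- rbind(
    data.frame(raw[c("kind", "value", "run", "class", "n_available")],
               statistic = "dsc", x = raw$dsc),
    data.frame(raw[c("kind", "value", "run", "class", "n_available")],
               statistic = "iou", x = raw$iou))
  agg <- do.call(rbind, lapply(
    split(long, list(long$value, long$class, long$statistic), drop = TRUE),
    function(g) data.frame(kind = g$kind[1L], configuration = g$value[1L],
                           class = g$class[1L], statistic = g$statistic[1L],
                           mean = mean(g$x), sd = sd(g$x),
                           mpfr = mean(g$x) / g$n_available[1L],
                           runs = nrow(g))))
  agg <- agg[order(agg$configuration, agg$class, agg$statistic), ]
  rownames(agg) <- NULL
  structure(agg, raw = raw, class = c("frugalseg_results", "data.frame"))
}

## Effective dropped-label count for PFR: mean per-class drop count over the
## classes that had labels dropped (0 when nothing was dropped).
effective_available <- function(S, dropped_per_class) {
  P <- if (length(dropped_per_class)) round(mean(dropped_per_class)) else 0
  S - P
}

#' Label-ablation experiment
#'
#' Drops labels from *all* foreground classes equally at each drop share in
#' `spec$values` (which must include the `rho = 0` supervised baseline),
#' trains one model per (rho, run) with a fixed (whole-training) drop plan,
#' and evaluates mDSC/mIoU/mPFR on the fully labeled test split.
#'
#' @param spec An [experiment_spec()] of kind `"ablation"`.
#' @param verbose Print progress.
#' @return A result table (`frugalseg_results`); attribute `"raw"` holds the
#'   per-run rows.
#' @export
run_ablation <- function(spec, verbose = FALSE) {
  stopifnot(spec$kind == "ablation")
  raw <- list()
  for (run in seq_len(spec$runs)) {
    scfg <- spec$synth_cfg
    scfg$seed <- derive_seed(spec$seed, 29L, run)
    ds <- synth_dataset(scfg)
    train_ids <- ds$ids[ds$split == "train"]
    S <- length(train_ids)
    for (v in spec$values) {
      dsp <- drop_spec(seq_len(scfg$n_foreground), rho = v,
                       seed = derive_seed(spec$seed, 31L, run),
                       persistence = "whole_training")
      view <- heterogeneous_view(train_ids, ds$n_classes, dsp,
                                 background_index = ds$n_classes)
      P <- attr(view$plan, "P")
      n_avail <- effective_available(S, if (v > 0) rep(P, scfg$n_foreground) else numeric(0))
      if (verbose) message(sprintf("ablation rho=%.2f run %d", v, run))
      raw[[length(raw) + 1L]] <-
        train_and_eval(spec, ds, v, run, view = view, n_available = n_avail)
    }
  }
  aggregate_results(do.call(rbind, raw))
}

#' Class-transfer experiment
#'
#' One class stays fully labeled while the "new" class (`spec$new_class`)
#' loses an increasing share of its labels; reports per-class curves across
#' the sweep.
#'
#' @inheritParams run_ablation
#' @param rho_values Optional override of the sweep (defaults to
#'   `spec$values`).
#' @export
run_transfer <- function(spec, rho_values = NULL, verbose = FALSE) {
  stopifnot(spec$kind %in% c("transfer", "alpha_sweep"))
  values <- if (is.null(rho_values)) spec$values else rho_values
  raw <- list()
  for (run in seq_len(spec$runs)) {
    scfg <- spec$synth_cfg
    scfg$seed <- derive_seed(spec$seed, 29L, run)
    ds <- synth_dataset(scfg)
    train_ids <- ds$ids[ds$split == "train"]
    S <- length(train_ids)
    for (v in values) {
      dsp <- drop_spec(spec$new_class, rho = v,
                       seed = derive_seed(spec$seed, 31L, run),
                       persistence = "whole_training")
      view <- heterogeneous_view(train_ids, ds$n_classes, dsp,
                                 background_index = ds$n_classes)
      P <- attr(view$plan, "P")
      n_avail <- effective_available(S, if (v > 0) P else numeric(0))
      if (verbose) message(sprintf("transfer rho=%.2f run %d", v, run))
      raw[[length(raw) + 1L]] <-
        train_and_eval(spec, ds, v, run, view = view, n_available = n_avail)
    }
  }
  aggregate_results(do.call(rbind, raw))
}

#' Equal-rate two-source sampler with oversampling
#'
#' Returns a sampler for [train_network()] that draws the two sides of a
#' merged dataset at equal rates each epoch: the larger side is shuffled, the
#' smaller side is oversampled (drawn with replacement up to the larger
#' side's size), and the two streams are interleaved so any batch contains
#' both sides within one sample. The environment of the returned function
#' carries an `audit` data.frame recording per-epoch draw counts per side.
#'
#' @param side_a,side_b Character vectors of sample ids.
#' @return `function(epoch, ids)` with an `audit` record in its environment.
#' @export
merge_sampler <- function(side_a, side_b) {
  audit <- data.frame(epoch = integer(), n_a = integer(), n_b = integer())
  f <- function(epoch, ids) {
    n <- max(length(side_a), length(side_b))
    draw <- function(s) if (length(s) >= n) sample(s, n) else
      sample(s, n, replace = TRUE)
    a <- draw(side_a); b <- draw(side_b)
    audit <<- rbind(audit, data.frame(epoch = epoch, n_a = n, n_b = n))
    as.vector(rbind(a, b))
  }
  f
}

#' Dataset-merging experiment
#'
#' Splits the training set into two single-class-labeled datasets at each
#' proportion in `spec$values` (side A keeps only class 1's masks, side B
#' only class 2's), trains on their union with equal-rate oversampling, and
#' evaluates both classes on the fully labeled test split.
#'
#' @inheritParams run_ablation
#' @export
run_merge <- function(spec, verbose = FALSE) {
  stopifnot(spec$kind == "merge")
  stopifnot(spec$synth_cfg$n_foreground == 2L)
  raw <- list()
  for (run in seq_len(spec$runs)) {
    scfg <- spec$synth_cfg
    scfg$seed <- derive_seed(spec$seed, 29L, run)
    ds <- synth_dataset(scfg)
    train_ids <- ds$ids[ds$split == "train"]
    S <- length(train_ids)
    for (v in spec$values) {
      n_a <- round(v * S)
      if (n_a < 1 || n_a >= S)
        stop("proportion ", v, " leaves one side empty (S = ", S, ")",
             call. = FALSE)
      shuffled <- with_isolated_seed(derive_seed(spec$seed, 37L, run),
                                     sample(train_ids))
      side_a <- shuffled[seq_len(n_a)]        # labeled with class 1 only
      side_b <- shuffled[(n_a + 1L):S]        # labeled with class 2 only
      plan <- matrix(1, nrow = S, ncol = ds$n_classes,
                     dimnames = list(shuffled, NULL))
      plan[side_a, 2L] <- 0
      plan[side_b, 1L] <- 0
      view <- fixed_view(shuffled, ds$n_classes, plan,
                         background_index = ds$n_classes)
      sampler <- merge_sampler(side_a, side_b)
      n_avail <- effective_available(S, c(S - n_a, n_a))
      if (verbose) message(sprintf("merge %.0f%%/%.0f%% run %d",
                                   100 * v, 100 * (1 - v), run))
      raw[[length(raw) + 1L]] <-
        train_and_eval(spec, ds, v, run, view = view, sampler = sampler,
                       n_available = n_avail)
      attr(raw[[length(raw)]], "audit") <- environment(sampler)$audit
    }
  }
  out <- aggregate_results(do.call(rbind, raw))
  attr(out, "audits") <- lapply(raw, attr, "audit")
  out
}

#' Loss-weight (alpha) sweep
#'
#' The transfer setup with the drop share fixed at `rho` (default 0.5),
#' sweeping the combined-objective weight `alpha` over `spec$values`; within
#' a run, every alpha sees the same dataset and the same drop plan, so the
#' comparison is paired.
#'
#' @inheritParams run_ablation
#' @param rho Fixed drop share for the new class. Default 0.5.
#' @export
run_alpha_sweep <- function(spec, rho = 0.5, verbose = FALSE) {
  stopifnot(spec$kind == "alpha_sweep")
  raw <- list()
  for (run in seq_len(spec$runs)) {
    scfg <- spec$synth_cfg
    scfg$seed <- derive_seed(spec$seed, 29L, run)
    ds <- synth_dataset(scfg)
    train_ids <- ds$ids[ds$split == "train"]
    S <- length(train_ids)
    dsp <- drop_spec(spec$new_class, rho = rho,
                     seed = derive_seed(spec$seed, 31L, run),
                     persistence = "whole_training")
    for (a in spec$values) {
      view <- heterogeneous_view(train_ids, ds$n_classes, dsp,
                                 background_index = ds$n_classes)
      P <- attr(view$plan, "P")
      lcfg <- spec$loss_cfg
      lcfg$alpha <- a
      if (verbose) message(sprintf("alpha=%.2f run %d", a, run))
      raw[[length(raw) + 1L]] <-
        train_and_eval(spec, ds, a, run, view = view, loss_cfg = lcfg,
                       n_available = effective_available(S, P))
    }
  }
  aggregate_results(do.call(rbind, raw))
}
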