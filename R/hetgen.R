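## Online heterogeneous-label generator: turns a homogeneously labeled
## dataset into a reproducible partially labeled one by dropping, for each
## eligible class, an exact share of the samples' masks. Labels are dropped
## on access; a per-iteration sample memory guarantees that repeated queries
## of the same sample within one iteration see identical labels. The source
## data is never modified.

## Run code under a derived seed without disturbing the caller's RNG stream.
with_isolated_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Mix a base seed with stream labels into a valid 32-bit seed.
derive_seed <- function(seed, ...) {
  v <- c(seed, ...)
  s <- 0
  for (x in v) s <- (s * 69069 + as.numeric(x) + 1) %% 2147483647
  as.integer(s)
}

## round half away from zero (P = round(rho * S))
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Label-dropping specification
#'
#' Defines which foreground classes are eligible for label dropping, the
#' relative drop share, and how long a realized plan persists.
#'
#' @param drop_classes Integer indices of the classes whose masks may be
#'   dropped (foreground classes only).
#' @param rho Relative drop share \eqn{\rho = P/S \in [0,1]}: for every
#'   eligible class, exactly `P = round(rho * S)` samples (half away from
#'   zero) lose that class's mask, drawn independently across classes.
#' @param seed Integer RNG seed; plans are deterministic given the seed.
#' @param persistence `"per_epoch"` redraws the plan each training iteration
#'   (epoch); `"whole_training"` fixes one plan for the entire training, so
#'   the heterogenized dataset behaves like a fixed partially labeled one.
#' @return An object of class `frugalseg_drop_spec`.
#' @export
drop_spec <- function(drop_classes, rho, seed = 1L,
                      persistence = c("per_epoch", "whole_training")) {
  persistence <- match.arg(persistence)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1)
    stop("'rho' must be a single number in [0, 1]", call. = FALSE)
  drop_classes <- sort(unique(as.integer(drop_classes)))
  structure(list(drop_classes = drop_classes, rho = rho,
                 seed = as.integer(seed), persistence = persistence),
            class = "frugalseg_drop_spec")
}

#' Draw a label-dropping plan
#'
#' For each eligible class, draws exactly `P = round(rho * S)` of the `S`
#' sample ids whose mask for that class is dropped. Draws are independent
#' across classes and deterministic given `spec$seed` (and the epoch, under
#' per-epoch persistence).
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param spec A [drop_spec()].
#' @param n_classes Total number of channels `C` of the mask vectors
#'   (including a background channel, if any).
#' @param epoch Training iteration counter; ignored under
#'   `"whole_training"` persistence.
#' @return A binary matrix (samples x classes, rownames = sample ids):
#'   `0` marks a dropped mask. Attribute `P` carries the per-class drop
#'   count.
#' @export
plan_drops <- function(sample_ids, spec, n_classes, epoch = 1L) {
  stopifnot(inherits(spec, "frugalseg_drop_spec"))
  if (length(sample_ids) == 0L) stop("no sample ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (any(spec$drop_classes > n_classes))
    stop("drop_classes index exceeds the number of classes", call. = FALSE)
  S <- length(sample_ids)
  P <- as.integer(round_half_away(spec$rho * S))
  ord <- order(sample_ids)   # plan independent of presentation order
  plan <- matrix(1, nrow = S, ncol = n_classes,
                 dimnames = list(sample_ids, NULL))
  e <- if (spec$persistence == "whole_training") 0L else as.integer(epoch)
  for (cls in spec$drop_classes) {
    dropped <- with_isolated_seed(derive_seed(spec$seed, cls, e),
                                  sample.int(S, P))
    plan[ord[dropped], cls] <- 0
  }
  attr(plan, "P") <- P
  plan
}

#' Heterogeneous view of a homogeneously labeled dataset
#'
#' Wraps a set of sample ids with a [drop_spec()] and a sample memory. Labels
#' are dropped online via [apply_drops()]; the memory records each sample's
#' realized mask vector at first access so repeated queries within one
#' iteration are bit-identical, and [reset_memory()] starts the next
#' iteration. The underlying dataset is never modified.
#'
#' @param sample_ids Character vector of sample ids in the source dataset.
#' @param n_classes Total channel count `C` (foreground + background).
#' @param spec A [drop_spec()].
#' @param background_index Index of the background channel to recompute as
#'   the complement of the *present* foreground masks, or `NULL`.
#' @param strict_background If `TRUE`, a sample with any missing foreground
#'   mask gets `m[background] = 0` (the complement background is then
#'   unreliable); default `FALSE` keeps background available, reproducing the
#'   common situation where background absorbs unlabeled structures.
#' @return An environment of class `frugalseg_het_view`.
#' @export
heterogeneous_view <- function(sample_ids, n_classes, spec,
                               background_index = NULL,
                               strict_background = FALSE) {
  stopifnot(inherits(spec, "frugalseg_drop_spec"))
  view <- new.env(parent = emptyenv())
  view$ids <- as.character(sample_ids)
  view$n_classes <- as.integer(n_classes)
  view$spec <- spec
  view$background_index <- background_index
  view$strict_background <- isTRUE(strict_background)
  view$epoch <- 1L
  view$plan <- plan_drops(view$ids, spec, n_classes, epoch = 1L)
  view$memory <- new.env(parent = emptyenv())
  class(view) <- "frugalseg_het_view"
  view
}

#' A view with an explicitly supplied, fixed dropping plan
#'
#' Like [heterogeneous_view()] but with a caller-provided availability plan
#' instead of a random draw; persistence is whole-training (resets are
#' no-ops). Used e.g. by the dataset-merging harness, where each side of the
#' merge keeps exactly one class's masks.
#'
#' @inheritParams heterogeneous_view
#' @param plan Binary matrix (samples x classes) with rownames `sample_ids`.
#' @return An environment of class `frugalseg_het_view`.
#' @export
fixed_view <- function(sample_ids, n_classes, plan, background_index = NULL,
                       strict_background = FALSE) {
  stopifnot(is.matrix(plan), nrow(plan) == length(sample_ids),
            ncol(plan) == n_classes, all(plan %in% c(0, 1)),
            !is.null(rownames(plan)),
            setequal(rownames(plan), sample_ids))
  view <- new.env(parent = emptyenv())
  view$ids <- as.character(sample_ids)
  view$n_classes <- as.integer(n_classes)
  view$spec <- drop_spec(integer(0), 0, persistence = "whole_training")
  view$background_index <- background_index
  view$strict_background <- isTRUE(strict_background)
  view$epoch <- 1L
  view$plan <- plan
  view$memory <- new.env(parent = emptyenv())
  class(view) <- "frugalseg_het_view"
  view
}

#' Apply online label dropping to one sample
#'
#' Looks the sample up in the view's current plan (recording it in the sample
#' memory on first access this iteration), zeroes the dropped channels, and
#' recomputes the background channel as the complement of the union of the
#' *present* foreground masks.
#'
#' @param view A [heterogeneous_view()].
#' @param sample_id Sample identifier.
#' @param gt The sample's full `(h, w, C)` ground truth.
#' @return `list(gt = modified ground truth, m = mask vector)`.
#' @export
apply_drops <- function(view, sample_id, gt) {
  stopifnot(inherits(view, "frugalseg_het_view"))
  sample_id <- as.character(sample_id)
  if (!sample_id %in% view$ids)
    stop("unknown sample id: ", sample_id, call. = FALSE)
  if (exists(sample_id, envir = view$memory, inherits = FALSE)) {
    m <- get(sample_id, envir = view$memory)
  } else {
    m <- view$plan[sample_id, ]
    assign(sample_id, m, envir = view$memory)
  }
  out <- gt
  bg <- view$background_index
  fg <- setdiff(seq_len(view$n_classes), bg)
  for (c in which(m == 0)) out[, , c] <- 0
  if (!is.null(bg)) {
    present <- fg[m[fg] == 1]
    occ <- matrix(0, nrow = dim(gt)[1L], ncol = dim(gt)[2L])
    for (k in present) occ <- pmax(occ, gt[, , k])
    out[, , bg] <- 1 - occ
    m[bg] <- if (view$strict_background && any(m[fg] == 0)) 0 else 1
    if (m[bg] == 0) out[, , bg] <- 0
  }
  list(gt = out, m = unname(m))
}

#' Reset the sample memory for the next training iteration
#'
#' Empties the memory; under per-epoch persistence the plan is redrawn (the
#' same drop share, new random subset), under whole-training persistence the
#' plan is unchanged and the reset is effectively a no-op.
#'
#' @param view A [heterogeneous_view()].
#' @return The view, invisibly.
#' @export
reset_memory <- function(view) {
  stopifnot(inherits(view, "frugalseg_het_view"))
  rm(list = ls(envir = view$memory), envir = view$memory)
  if (view$spec$persistence == "per_epoch") {
    view$epoch <- view$epoch + 1L
    view$plan <- plan_drops(view$ids, view$spec, view$n_classes,
                            epoch = view$epoch)
  }
  invisible(view)
}

#' @rdname reset_memory
#' @export
memory_size <- function(view) length(ls(envir = view$memory))

#' Heterogenize a manifest offline
#'
#' Applies a fixed (whole-training) dropping plan to a manifest's training
#' rows by blanking the mask-path cells of dropped labels; test rows are
#' never touched. The referenced image and mask files are not modified.
#'
#' @param manifest A manifest data.frame from [load_manifest()] or
#'   [generate_dataset()].
#' @param spec A [drop_spec()]; class indices refer to the manifest's
#'   foreground class order.
#' @return The heterogenized manifest.
#' @export
heterogenize_manifest <- function(manifest, spec) {
  cls <- manifest_classes(manifest)
  train <- manifest$split == "train"
  ids <- manifest$sample_id[train]
  fixed <- drop_spec(spec$drop_classes, spec$rho, spec$seed,
                     persistence = "whole_training")
  plan <- plan_drops(ids, fixed, length(cls))
  for (k in seq_along(cls)) {
    col <- paste0("mask_", cls[k])
    blank <- ids[plan[, k] == 0]
    manifest[[col]][match(blank, manifest$sample_id)] <- ""
  }
  manifest
}
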