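## Synthetic benchmark generator: desk-scale RGB images containing three
## adjacent, mutually exclusive elliptical regions on a dark background,
## mimicking the structure of a three-chamber cardiac segmentation task
## (atrium / ventricle / bulbus + background). Every generated sample is
## fully labeled; heterogenization is the label generator's job.

#' Synthetic dataset configuration
#'
#' @param n_samples Number of images. Default 200.
#' @param image_size Square image side in pixels. Default 64.
#' @param n_foreground Number of foreground classes (1-3). Default 3.
#' @param class_names Foreground class names; defaults to the cardiac-chamber
#'   names `atrium`, `ventricle`, `bulbus`.
#' @param base_colors 3-column RGB matrix (rows = classes) of per-class base
#'   colors; defaults are mutually distinct.
#' @param background_color RGB triple of the background.
#' @param area_scale Per-class relative area factors; the default makes the
#'   last class (`bulbus`) smaller and thinner, emulating a hardest-to-segment
#'   class.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (intensities are clipped back to `[0, 1]`). Default 0.12.
#' @param color_jitter Half-width of the uniform per-sample perturbation of
#'   each class's color (applied per RGB channel before noise), emulating
#'   between-sample appearance variation such as varying blood fill of a
#'   heart chamber. Default 0.12.
#' @param split_fraction Fraction of samples assigned to the test split.
#'   Default 0.2.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `frugalseg_synth_config`.
#' @export
synth_config <- function(n_samples = 200, image_size = 64, n_foreground = 3,
                         class_names = c("atrium", "ventricle", "bulbus")[seq_len(n_foreground)],
                         base_colors = NULL, background_color = c(0.08, 0.08, 0.12),
                         area_scale = c(1, 1, 0.55)[seq_len(n_foreground)],
                         noise_sd = 0.12, color_jitter = 0.12,
                         split_fraction = 0.2, seed = 1L) {
  stopifnot(n_foreground >= 1, n_foreground <= 3,
            length(class_names) == n_foreground,
            length(area_scale) == n_foreground,
            noise_sd >= 0, color_jitter >= 0,
            split_fraction >= 0, split_fraction < 1,
            image_size >= 16)
  if (is.null(base_colors))
    base_colors <- rbind(c(0.20, 0.75, 0.30),   # atrium: green
                         c(0.90, 0.55, 0.15),   # ventricle: orange
                         c(0.25, 0.45, 0.90))[seq_len(n_foreground), , drop = FALSE]
  stopifnot(nrow(base_colors) == n_foreground,
            anyDuplicated(base_colors) == 0)
  structure(list(n_samples = as.integer(n_samples),
                 image_size = as.integer(image_size),
                 n_foreground = as.integer(n_foreground),
                 class_names = class_names, base_colors = base_colors,
                 background_color = background_color, area_scale = area_scale,
                 noise_sd = noise_sd, color_jitter = color_jitter,
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "frugalseg_synth_config")
}

rasterize_ellipse <- function(size, cy, cx, ry, rx) {
  y <- matrix(seq_len(size), size, size)
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

#' Generate one synthetic sample
#'
#' Places one ellipse per foreground class side by side with positional and
#' size jitter (adjacent but pairwise disjoint; up to 100 placement
#' attempts), paints each region in its base color over the background color,
#' and adds clipped Gaussian noise. All classes are present and labeled.
#'
#' @param cfg A [synth_config()].
#' @param sample_seed Integer seed for this sample.
#' @return `list(image, gt, m, class_names)`; `gt` is `(size, size, C)` with
#'   the background channel last, `m` is all ones.
#' @export
generate_sample <- function(cfg, sample_seed) {
  s <- cfg$image_size
  nf <- cfg$n_foreground
  with_isolated_seed(sample_seed, {
    masks <- NULL
    for (attempt in seq_len(100)) {
      cand <- vector("list", nf)
      cx0 <- (seq_len(nf) - 0.5) / nf * s
      ok <- TRUE
      occupied <- matrix(FALSE, s, s)
      for (k in seq_len(nf)) {
        a <- cfg$area_scale[k]
        rx <- s * (0.45 / nf) * sqrt(a) * runif(1, 0.80, 1.10)
        ry <- s * 0.22 * sqrt(a) * runif(1, 0.80, 1.10) *
          (if (k == nf && nf == 3) 0.7 else 1)   # last class thinner
        cy <- s / 2 + runif(1, -0.08, 0.08) * s
        cx <- cx0[k] + runif(1, -0.05, 0.05) * s
        mk <- rasterize_ellipse(s, cy, cx, ry, rx)
        if (sum(mk) == 0 || any(mk & occupied)) { ok <- FALSE; break }
        occupied <- occupied | mk
        cand[[k]] <- mk
      }
      if (ok) { masks <- cand; break }
    }
    if (is.null(masks))
      stop("could not place ", nf, " disjoint shapes in 100 attempts; ",
           "reduce area_scale or increase image_size", call. = FALSE)
    img <- array(rep(cfg$background_color, each = s * s), dim = c(s, s, 3))
    gt <- array(0, dim = c(s, s, nf + 1L))
    for (k in seq_len(nf)) {
      gt[, , k] <- as.numeric(masks[[k]])
      col <- cfg$base_colors[k, ]
      if (cfg$color_jitter > 0)   # per-sample appearance variation
        col <- pmin(pmax(col + runif(3, -cfg$color_jitter, cfg$color_jitter), 0), 1)
      for (ch in 1:3)
        img[, , ch][masks[[k]]] <- col[ch]
    }
    gt[, , nf + 1L] <- as.numeric(!Reduce(`|`, masks))
    if (cfg$noise_sd > 0)
      img <- pmin(pmax(img + rnorm(length(img), 0, cfg$noise_sd), 0), 1)
    list(image = img, gt = gt, m = rep(1, nf + 1L),
         class_names = c(cfg$class_names, "background"))
  })
}

#' Generate a synthetic dataset in memory
#'
#' Generates `cfg$n_samples` fully labeled samples and a train/test split.
#'
#' @param cfg A [synth_config()].
#' @return An object of class `frugalseg_dataset`: list with `samples`
#'   (named list of `generate_sample()` outputs), `ids`, `split` (character
#'   vector), `class_names` (foreground), `n_classes` (foreground +
#'   background) and `cfg`.
#' @export
synth_dataset <- function(cfg) {
  ids <- sprintf("s%04d", seq_len(cfg$n_samples))
  samples <- lapply(seq_along(ids), function(i)
    generate_sample(cfg, derive_seed(cfg$seed, 7L, i)))
  names(samples) <- ids
  n_test <- floor(cfg$split_fraction * cfg$n_samples)
  test_idx <- with_isolated_seed(derive_seed(cfg$seed, 11L),
                                 sample.int(cfg$n_samples, n_test))
  split <- rep("train", cfg$n_samples)
  split[test_idx] <- "test"
  structure(list(samples = samples, ids = ids, split = split,
                 class_names = cfg$class_names,
                 n_classes = cfg$n_foreground + 1L, cfg = cfg),
            class = "frugalseg_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes one RGB PNG per sample plus one binary mask PNG per foreground
#' class (values exactly 0/255), and a `manifest.csv` indexing them with the
#' train/test split. The dataset is fully labeled.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory.
#' @param force Overwrite into a non-empty directory.
#' @return The manifest data.frame (invisibly), with attribute `"dir"`.
#' @export
generate_dataset <- function(cfg, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("output directory ", dir, " is not empty (use force = TRUE)",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- synth_dataset(cfg)
  man <- data.frame(sample_id = ds$ids,
                    image = paste0(ds$ids, ".png"),
                    stringsAsFactors = FALSE)
  for (k in seq_along(cfg$class_names))
    man[[paste0("mask_", cfg$class_names[k])]] <-
      paste0(ds$ids, "_", cfg$class_names[k], ".png")
  man$split <- ds$split
  for (i in seq_along(ds$ids)) {
    smp <- ds$samples[[i]]
    png::writePNG(smp$image, file.path(dir, man$image[i]))
    for (k in seq_along(cfg$class_names))
      png::writePNG(smp$gt[, , k],
                    file.path(dir, man[[paste0("mask_", cfg$class_names[k])]][i]))
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  attr(man, "dir") <- normalizePath(dir)
  invisible(man)
}

#' Load a manifest-indexed dataset into memory
#'
#' Reads every sample of a manifest via [read_sample()] into the in-memory
#' dataset structure used by the training and experiment functions.
#'
#' @param manifest A manifest from [load_manifest()] or [generate_dataset()].
#' @return A `frugalseg_dataset`.
#' @export
as_dataset <- function(manifest) {
  ids <- manifest$sample_id
  samples <- lapply(ids, function(id) read_sample(manifest, id))
  names(samples) <- ids
  cls <- manifest_classes(manifest)
  structure(list(samples = samples, ids = ids, split = manifest$split,
                 class_names = cls, n_classes = length(cls) + 1L,
                 cfg = NULL),
            class = "frugalseg_dataset")
}

#' Nearest-base-color reference segmenter
#'
#' Assigns each pixel to the class (or background) whose configured base
#' color is nearest in RGB. A sanity reference for the synthetic benchmark:
#' on noise-free data it is essentially perfect, so the evaluation pipeline
#' can be validated independently of any trained network.
#'
#' @param image `(h, w, 3)` array.
#' @param cfg The [synth_config()] that produced the data.
#' @return A soft-looking one-hot `(h, w, C)` prediction array.
#' @export
color_threshold_predict <- function(image, cfg) {
  centers <- rbind(cfg$base_colors, cfg$background_color)
  hw <- prod(dim(image)[1:2])
  px <- matrix(image, nrow = hw, ncol = 3)
  d2 <- sapply(seq_len(nrow(centers)), function(k)
    rowSums(sweep(px, 2, centers[k, ])^2))
  win <- max.col(-d2, ties.method = "first")
  out <- matrix(0, hw, nrow(centers))
  out[cbind(seq_len(hw), win)] <- 1
  array(out, dim = c(dim(image)[1:2], nrow(centers)))
}
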