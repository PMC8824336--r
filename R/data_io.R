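## Dataset I/O: CSV manifests binding RGB PNG images to per-class binary
## mask PNGs (a blank mask cell = missing label), plus the preprocessing and
## augmentation recipe (shared geometric transform for an image and all its
## masks, rescaling to a target size, intensities in [0, 1]).

#' Foreground class names encoded in a manifest
#'
#' @param manifest A manifest data.frame.
#' @return Character vector of class names, in column order.
#' @export
manifest_classes <- function(manifest) {
  cols <- grep("^mask_", names(manifest), value = TRUE)
  sub("^mask_", "", cols)
}

#' Load a dataset manifest
#'
#' A manifest is a CSV with header columns `sample_id,image,mask_<class1>,
#' ...,mask_<classC>,split`; a blank mask cell means the label for that class
#' is absent for that sample. Paths are resolved relative to the manifest's
#' directory.
#'
#' @param path Path to the CSV file.
#' @param check_files Verify that every referenced file exists (default
#'   `TRUE`).
#' @param quiet Suppress the per-class availability report.
#' @return A data.frame with attribute `"dir"` (the manifest directory).
#' @export
load_manifest <- function(path, check_files = TRUE, quiet = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- read.csv(path, colClasses = "character")
  required <- c("sample_id", "image", "split")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols))
    stop("manifest lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(man), c(required, grep("^mask_", names(man), value = TRUE)))
  if (length(unknown))
    stop("unknown manifest column(s): ", paste(unknown, collapse = ", "),
         "; expected sample_id, image, mask_<class>..., split", call. = FALSE)
  if (anyDuplicated(man$sample_id))
    stop("duplicate sample_id values in manifest", call. = FALSE)
  bad_split <- setdiff(unique(man$split), c("train", "test"))
  if (length(bad_split))
    stop("unknown split tag(s): ", paste(bad_split, collapse = ", "),
         call. = FALSE)
  dir <- dirname(normalizePath(path))
  attr(man, "dir") <- dir
  cls <- manifest_classes(man)
  if (!length(cls)) stop("manifest has no mask_<class> columns", call. = FALSE)
  if (check_files) {
    refs <- c(man$image, unlist(lapply(cls, function(k) {
      v <- man[[paste0("mask_", k)]]
      v[nzchar(v)]
    })))
    ok <- file.exists(file.path(dir, refs))
    if (!all(ok))
      stop("manifest references missing file(s): ",
           paste(utils::head(refs[!ok], 5), collapse = ", "), call. = FALSE)
  }
  if (!quiet) {
    for (s in c("train", "test")) {
      rows <- man$split == s
      avail <- vapply(cls, function(k) sum(nzchar(man[[paste0("mask_", k)]][rows])),
                      integer(1))
      message(sprintf("%s: %d samples; labels available: %s", s, sum(rows),
                      paste(sprintf("%s=%d", cls, avail), collapse = ", ")))
    }
  }
  man
}

#' Write a manifest
#'
#' @param manifest A manifest data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_png_gray <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a
}

read_png_rgb <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Read one manifest sample into memory
#'
#' Loads the RGB image (intensities in `[0, 1]`) and the per-class masks,
#' binarized at half intensity (threshold 128 on 8-bit files). Absent masks
#' yield all-zero channels with `m = 0`. A background channel is appended as
#' the complement of the union of the *present* foreground masks. Overlapping
#' foreground masks violate mutual exclusivity and trigger a warning.
#'
#' @param manifest A manifest from [load_manifest()].
#' @param sample_id Sample identifier.
#' @return `list(image, gt, m, class_names)` where `gt` is `(h, w, C)` with
#'   background last and `class_names` includes `"background"`.
#' @export
read_sample <- function(manifest, sample_id) {
  row <- match(as.character(sample_id), manifest$sample_id)
  if (is.na(row)) stop("unknown sample id: ", sample_id, call. = FALSE)
  dir <- attr(manifest, "dir")
  resolve <- function(p) if (is.null(dir)) p else file.path(dir, p)
  img <- read_png_rgb(resolve(manifest$image[row]))
  cls <- manifest_classes(manifest)
  C <- length(cls) + 1L
  gt <- array(0, dim = c(dim(img)[1L], dim(img)[2L], C))
  m <- c(rep(0, length(cls)), 1)
  for (k in seq_along(cls)) {
    cell <- manifest[[paste0("mask_", cls[k])]][row]
    if (!nzchar(cell)) next
    mk <- read_png_gray(resolve(cell))
    if (!identical(dim(mk), dim(img)[1:2]))
      stop("size mismatch between image and mask '", cls[k], "' for sample ",
           sample_id, call. = FALSE)
    gt[, , k] <- as.numeric(mk >= 128 / 255)
    m[k] <- 1
  }
  present <- which(m[seq_along(cls)] == 1)
  occ <- if (length(present))
    apply(gt[, , present, drop = FALSE], c(1, 2), max)
  else matrix(0, dim(img)[1L], dim(img)[2L])
  if (length(present) > 1L) {
    tot <- apply(gt[, , present, drop = FALSE], c(1, 2), sum)
    if (any(tot > 1))
      warning("sample ", sample_id, ": foreground masks overlap at ",
              sum(tot > 1), " pixel(s); mutual exclusivity violated",
              call. = FALSE)
  }
  gt[, , C] <- 1 - occ
  list(image = img, gt = gt, m = m, class_names = c(cls, "background"))
}

#' Augmentation configuration
#'
#' Geometric augmentation recipe applied identically to an image and all its
#' mask channels: small rotations and shears, relative shifts, zoom,
#' horizontal flips, nearest (edge-replicating) fill for uncovered borders,
#' followed by rescaling to `target_size` with intensities kept in `[0, 1]`.
#'
#' @param rotation_range Maximum rotation in degrees; drawn uniformly from
#'   `[0, rotation_range]`. Default 0.3.
#' @param width_shift,height_shift Maximum relative shift; drawn uniformly
#'   from `[-s, s]`. Default 0.05.
#' @param shear_range Maximum counter-clockwise shear angle in degrees; drawn
#'   uniformly from `[0, shear_range]`. Default 0.05.
#' @param zoom_range Zoom amplitude `z`; the zoom factor is drawn uniformly
#'   from `[1 - z, 1 + z]`. Default 0.5.
#' @param horizontal_flip_prob Probability of a horizontal flip. Default 0.5.
#' @param target_size Output `(h, w)`. Default `c(256, 256)`.
#' @param seed Optional seed making single draws reproducible.
#' @return An object of class `frugalseg_augment_config`.
#' @export
augment_config <- function(rotation_range = 0.3, width_shift = 0.05,
                           height_shift = 0.05, shear_range = 0.05,
                           zoom_range = 0.5, horizontal_flip_prob = 0.5,
                           target_size = c(256, 256), seed = NULL) {
  stopifnot(rotation_range >= 0, shear_range >= 0, zoom_range >= 0,
            zoom_range < 1, width_shift >= 0, height_shift >= 0,
            horizontal_flip_prob >= 0, horizontal_flip_prob <= 1,
            length(target_size) == 2L)
  structure(list(rotation_range = rotation_range, width_shift = width_shift,
                 height_shift = height_shift, shear_range = shear_range,
                 zoom_range = zoom_range,
                 horizontal_flip_prob = horizontal_flip_prob,
                 target_size = as.integer(target_size), seed = seed),
            class = "frugalseg_augment_config")
}

## Sample a 2D array at fractional (row, col) coordinates, clamping to the
## border (edge-replicating fill). Bilinear for images, nearest for masks.
sample_grid <- function(a, rr, cc, bilinear = TRUE) {
  h <- nrow(a); w <- ncol(a)
  if (bilinear) {
    r0 <- pmin(pmax(floor(rr), 1), h); r1 <- pmin(r0 + 1, h)
    c0 <- pmin(pmax(floor(cc), 1), w); c1 <- pmin(c0 + 1, w)
    fr <- pmin(pmax(rr - r0, 0), 1); fc <- pmin(pmax(cc - c0, 0), 1)
    a[cbind(r0, c0)] * (1 - fr) * (1 - fc) + a[cbind(r1, c0)] * fr * (1 - fc) +
      a[cbind(r0, c1)] * (1 - fr) * fc + a[cbind(r1, c1)] * fr * fc
  } else {
    a[cbind(pmin(pmax(round(rr), 1), h), pmin(pmax(round(cc), 1), w))]
  }
}

## Inverse-map output pixel centers through an affine transform about the
## image center and resample every channel of image and ground truth.
apply_affine <- function(image, gt, A, target_size) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  th <- target_size[1L]; tw <- target_size[2L]
  sy <- h / th; sx <- w / tw
  out_r <- rep(seq_len(th), times = tw); out_c <- rep(seq_len(tw), each = th)
  ## map output pixel -> source pixel of the (unaugmented) input
  y <- (out_r - 0.5) * sy + 0.5 - (h + 1) / 2
  x <- (out_c - 0.5) * sx + 0.5 - (w + 1) / 2
  rr <- A[1, 1] * y + A[1, 2] * x + A[1, 3] + (h + 1) / 2
  cc <- A[2, 1] * y + A[2, 2] * x + A[2, 3] + (w + 1) / 2
  img_out <- array(0, dim = c(th, tw, dim(image)[3L]))
  for (k in seq_len(dim(image)[3L]))
    img_out[, , k] <- matrix(pmin(pmax(
      sample_grid(image[, , k], rr, cc, bilinear = TRUE), 0), 1), th, tw)
  gt_out <- array(0, dim = c(th, tw, dim(gt)[3L]))
  for (k in seq_len(dim(gt)[3L]))
    gt_out[, , k] <- matrix(as.numeric(
      sample_grid(gt[, , k], rr, cc, bilinear = FALSE) > 0.5), th, tw)
  list(image = img_out, gt = gt_out)
}

#' Augment an image and its ground truth with one shared transform
#'
#' Draws one geometric transform from `cfg` and applies it identically to the
#' image and every mask channel; masks are resampled with nearest
#' interpolation (so they stay binary and mutually exclusive) while the image
#' is resampled bilinearly. Uncovered border pixels replicate the nearest
#' edge. The output is rescaled to `cfg$target_size`. With all ranges zero,
#' flip probability zero and matching target size, the output equals the
#' input exactly.
#'
#' @param image `(h, w, 3)` array with intensities in `[0, 1]`.
#' @param gt Binary `(h, w, C)` ground-truth array.
#' @param cfg An [augment_config()].
#' @return `list(image, gt)` at `cfg$target_size`.
#' @export
augment <- function(image, gt, cfg = augment_config()) {
  stopifnot(identical(dim(image)[1:2], dim(gt)[1:2]))
  draw <- function() {
    list(theta = runif(1, 0, cfg$rotation_range) * pi / 180,
         shear = runif(1, 0, cfg$shear_range) * pi / 180,
         ty = runif(1, -cfg$height_shift, cfg$height_shift) * dim(image)[1L],
         tx = runif(1, -cfg$width_shift, cfg$width_shift) * dim(image)[2L],
         zoom = runif(1, 1 - cfg$zoom_range, 1 + cfg$zoom_range),
         flip = runif(1) < cfg$horizontal_flip_prob)
  }
  p <- if (is.null(cfg$seed)) draw() else with_isolated_seed(cfg$seed, draw())
  ## forward transform in centered (row, col) coordinates:
  ## flip . translate . rotate . shear . zoom ; inverse-mapped for resampling
  rot <- matrix(c(cos(p$theta), sin(p$theta), -sin(p$theta), cos(p$theta)), 2)
  shr <- matrix(c(1, 0, -sin(p$shear), cos(p$shear)), 2)
  zm <- diag(c(1 / p$zoom, 1 / p$zoom))
  flip <- diag(c(1, if (p$flip) -1 else 1))
  fwd <- flip %*% rot %*% shr %*% zm
  Ainv <- solve(fwd)
  t_inv <- -Ainv %*% (flip %*% c(p$ty, p$tx))
  A <- cbind(Ainv, t_inv)
  apply_affine(image, gt, A, cfg$target_size)
}

#' Resize an image/ground-truth pair without augmentation
#'
#' @inheritParams augment
#' @param target_size Output `(h, w)`.
#' @return `list(image, gt)`.
#' @export
resize_sample <- function(image, gt, target_size) {
  apply_affine(image, gt, cbind(diag(2), c(0, 0)), target_size)
}
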