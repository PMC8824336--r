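## Compact symmetric encoder-decoder segmentation network (U-Net style):
## 3x3 'same' convolutions + ReLU, 2x2 max pooling on the encoder path,
## nearest-neighbor upsampling with skip-connection concatenation on the
## decoder path, and a 1x1 convolution + per-pixel softmax head. Trained
## with Adam on the combined heterogeneous-label objective. The conv/pool
## kernels live in compiled code; everything else is plain R.

#' Network configuration
#'
#' @param input_size Input `(h, w)`; both must be divisible by `2^depth`.
#' @param num_classes Output channels `C`, including the background class.
#' @param depth Number of encoder stages (poolings).
#' @param base_filters Channel width of the first stage; stage `i` uses
#'   `base_filters * 2^(i-1)`.
#' @param convs_per_stage Convolutions per stage (classic U-Net uses 2).
#' @param normalize Apply per-channel instance normalization after each
#'   convolution (before the ReLU). Without normalization the activation
#'   scale grows across stages and the softmax saturates irreversibly, which
#'   is fatal when heterogeneous labels provide conflicting supervision.
#'   Default `TRUE`.
#' @param seed Seed for weight initialization.
#' @return An object of class `frugalseg_net_config`.
#' @export
network_config <- function(input_size = c(256, 256), num_classes = 4,
                           depth = 4, base_filters = 64, convs_per_stage = 2,
                           normalize = TRUE, seed = NULL) {
  input_size <- as.integer(input_size)
  if (any(input_size %% 2^depth != 0))
    stop("input dimensions ", paste(input_size, collapse = "x"),
         " are not divisible by 2^depth = ", 2^depth, call. = FALSE)
  stopifnot(num_classes >= 2, depth >= 1, base_filters >= 1,
            convs_per_stage >= 1)
  structure(list(input_size = input_size, num_classes = as.integer(num_classes),
                 depth = as.integer(depth), base_filters = as.integer(base_filters),
                 convs_per_stage = as.integer(convs_per_stage),
                 normalize = isTRUE(normalize), seed = seed),
            class = "frugalseg_net_config")
}

#' @rdname network_config
#' @param ... Overrides passed to [network_config()].
#' @export
tiny_network_config <- function(input_size = c(64, 64), num_classes = 4, ...) {
  network_config(input_size = input_size, num_classes = num_classes,
                 depth = 2, base_filters = 8, convs_per_stage = 1, ...)
}

## Conv layer shapes implied by a config: list of (name, in_ch, out_ch).
conv_specs <- function(cfg) {
  F <- cfg$base_filters * 2^(seq_len(cfg$depth) - 1L)
  Fb <- cfg$base_filters * 2^cfg$depth
  specs <- list()
  in_ch <- 3L
  for (i in seq_len(cfg$depth)) {
    for (j in seq_len(cfg$convs_per_stage)) {
      specs[[length(specs) + 1L]] <- list(name = sprintf("enc%d_c%d", i, j),
                                          in_ch = in_ch, out_ch = F[i])
      in_ch <- F[i]
    }
  }
  for (j in seq_len(cfg$convs_per_stage)) {
    specs[[length(specs) + 1L]] <- list(name = sprintf("bot_c%d", j),
                                        in_ch = in_ch, out_ch = Fb)
    in_ch <- Fb
  }
  for (i in rev(seq_len(cfg$depth))) {
    ch_concat <- in_ch + F[i]
    for (j in seq_len(cfg$convs_per_stage)) {
      specs[[length(specs) + 1L]] <- list(name = sprintf("dec%d_c%d", i, j),
                                          in_ch = if (j == 1L) ch_concat else F[i],
                                          out_ch = F[i])
    }
    in_ch <- F[i]
  }
  list(convs = specs, head_in = in_ch)
}

#' Parameter count of a network configuration
#'
#' @param cfg A [network_config()].
#' @return Total number of trainable parameters.
#' @export
count_params <- function(cfg) {
  sp <- conv_specs(cfg)
  n <- sum(vapply(sp$convs, function(s) 9 * s$in_ch * s$out_ch + s$out_ch,
                  numeric(1)))
  n + sp$head_in * cfg$num_classes + cfg$num_classes
}

#' Build a segmentation network
#'
#' Allocates He-initialized weights for the encoder-decoder defined by `cfg`.
#' The model maps `(h, w, 3)` inputs to `(h, w, C)` per-pixel softmax
#' predictions.
#'
#' @param cfg A [network_config()].
#' @return An object of class `frugalseg_net`.
#' @export
build_network <- function(cfg) {
  sp <- conv_specs(cfg)
  init <- function() {
    params <- list()
    for (s in sp$convs) {
      fan_in <- 9 * s$in_ch
      params[[paste0(s$name, "_W")]] <-
        matrix(rnorm(fan_in * s$out_ch, 0, sqrt(2 / fan_in)), fan_in, s$out_ch)
      params[[paste0(s$name, "_b")]] <- rep(0, s$out_ch)
    }
    ## near-zero head scale: initial logits ~ 0 keep the softmax close to
    ## uniform, so no class channel starts saturated-dead (small structures
    ## otherwise lose their gradient through the softmax and never recover)
    params$head_W <- matrix(rnorm(sp$head_in * cfg$num_classes, 0, 0.01),
                            sp$head_in, cfg$num_classes)
    params$head_b <- rep(0, cfg$num_classes)
    params
  }
  params <- if (is.null(cfg$seed)) init() else
    with_isolated_seed(derive_seed(cfg$seed, 13L), init())
  structure(list(cfg = cfg, params = params), class = "frugalseg_net")
}

#' @export
print.frugalseg_net <- function(x, ...) {
  cat(sprintf("frugalseg encoder-decoder: depth %d, base %d filters, %d conv(s)/stage\n",
              x$cfg$depth, x$cfg$base_filters, x$cfg$convs_per_stage))
  cat(sprintf("input (%s, 3) -> output (%s, %d); %s parameters\n",
              paste(x$cfg$input_size, collapse = ", "),
              paste(x$cfg$input_size, collapse = ", "), x$cfg$num_classes,
              format(count_params(x$cfg), big.mark = ",")))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

## Instance normalization: per sample, per channel, zero mean / unit sd.
instnorm_forward <- function(x, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  mu <- colMeans(xm)
  xm <- sweep(xm, 2L, mu)
  sd_ <- sqrt(colMeans(xm^2) + eps)
  y <- sweep(xm, 2L, sd_, `/`)
  list(y = array(y, dim = d), sd = sd_, ymat = y)
}

instnorm_backward <- function(dy, fw) {
  d <- dim(dy)
  dm <- matrix(dy, d[1L] * d[2L], d[3L])
  y <- fw$ymat
  dm <- dm - matrix(colMeans(dm), nrow(dm), ncol(dm), byrow = TRUE) -
    y * matrix(colMeans(dm * y), nrow(dm), ncol(dm), byrow = TRUE)
  array(sweep(dm, 2L, fw$sd, `/`), dim = d)
}

concat_channels <- function(a, b) {
  d <- dim(a)
  array(c(a, b), dim = c(d[1L], d[2L], d[3L] + dim(b)[3L]))
}

## Forward pass. With cache = TRUE also returns every conv input, post-ReLU
## output, pool argmax and concat geometry needed for the backward pass.
net_forward <- function(net, x, cache = FALSE) {
  cfg <- net$cfg
  p <- net$params
  cc <- if (cache) new.env(parent = emptyenv()) else NULL
  run_conv <- function(a, name) {
    if (cache) {
      fwd <- conv3_forward_ws(a, p[[paste0(name, "_W")]],
                              p[[paste0(name, "_b")]])
      z <- fwd$y
      cc[[paste0(name, "_P")]] <- fwd$P
      cc[[paste0(name, "_cin")]] <- dim(a)[3L]
    } else {
      z <- conv3_forward(a, p[[paste0(name, "_W")]], p[[paste0(name, "_b")]])
    }
    if (cfg$normalize) {
      nf <- instnorm_forward(z)
      if (cache) cc[[paste0(name, "_norm")]] <- nf
      z <- nf$y
    }
    out <- relu(z)
    if (cache) cc[[paste0(name, "_out")]] <- out
    out
  }
  a <- x
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    for (j in seq_len(cfg$convs_per_stage))
      a <- run_conv(a, sprintf("enc%d_c%d", i, j))
    skips[[i]] <- a
    pl <- maxpool2_forward(a)
    if (cache) cc[[sprintf("pool%d_idx", i)]] <- pl$idx
    a <- pl$y
  }
  for (j in seq_len(cfg$convs_per_stage))
    a <- run_conv(a, sprintf("bot_c%d", j))
  for (i in rev(seq_len(cfg$depth))) {
    below <- dim(a)[3L]
    a <- concat_channels(upsample2(a), skips[[i]])
    if (cache) cc[[sprintf("dec%d_below", i)]] <- below
    for (j in seq_len(cfg$convs_per_stage))
      a <- run_conv(a, sprintf("dec%d_c%d", i, j))
  }
  d <- dim(a)
  if (cache) cc$head_in <- a
  lm <- matrix(a, d[1L] * d[2L], d[3L]) %*% p$head_W
  lm <- sweep(lm, 2L, p$head_b, `+`)
  logits <- array(lm, dim = c(d[1L], d[2L], cfg$num_classes))
  pred <- softmax_channels(logits)
  if (cache) list(pred = pred, logits = logits, cache = cc)
  else list(pred = pred, logits = logits)
}

## Backward pass: gradient of the loss in every parameter, given dL/dlogits.
net_backward <- function(net, cc, dlogits) {
  cfg <- net$cfg
  p <- net$params
  grads <- list()
  back_conv <- function(da, name) {
    da <- da * (cc[[paste0(name, "_out")]] > 0)
    if (cfg$normalize)
      da <- instnorm_backward(da, cc[[paste0(name, "_norm")]])
    bw <- conv3_backward_ws(cc[[paste0(name, "_P")]], p[[paste0(name, "_W")]],
                            da, cc[[paste0(name, "_cin")]])
    grads[[paste0(name, "_W")]] <<- bw$dW
    grads[[paste0(name, "_b")]] <<- as.vector(bw$db)
    bw$dx
  }
  d <- dim(cc$head_in)
  dm <- matrix(dlogits, d[1L] * d[2L], cfg$num_classes)
  am <- matrix(cc$head_in, d[1L] * d[2L], d[3L])
  grads$head_W <- crossprod(am, dm)
  grads$head_b <- colSums(dm)
  da <- array(dm %*% t(p$head_W), dim = d)
  dskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {      # decoder stages, innermost first
    for (j in rev(seq_len(cfg$convs_per_stage)))
      da <- back_conv(da, sprintf("dec%d_c%d", i, j))
    below <- cc[[sprintf("dec%d_below", i)]]
    dskips[[i]] <- da[, , (below + 1L):dim(da)[3L], drop = FALSE]
    da <- upsample2_backward(da[, , seq_len(below), drop = FALSE])
  }
  for (j in rev(seq_len(cfg$convs_per_stage)))
    da <- back_conv(da, sprintf("bot_c%d", j))
  for (i in rev(seq_len(cfg$depth))) {
    da <- maxpool2_backward(cc[[sprintf("pool%d_idx", i)]], da) + dskips[[i]]
    for (j in rev(seq_len(cfg$convs_per_stage)))
      da <- back_conv(da, sprintf("enc%d_c%d", i, j))
  }
  grads
}

#' Training configuration
#'
#' Defaults follow a standard supervised protocol for this problem family:
#' Adam at learning rate `1e-3`, batch size 11, early stopping on the
#' validation Dice loss with best-weight restoration.
#'
#' @param batch_size Samples per weight update. Default 11.
#' @param learning_rate Adam step size. Default `1e-3`.
#' @param max_epochs Upper bound on epochs. Default 50.
#' @param patience Early-stopping patience in epochs on the validation Dice
#'   loss; `Inf` disables early stopping. Default 5.
#' @param validation_fraction Fraction of training samples held out for
#'   validation; 0 disables validation (and early stopping). Default 0.1.
#' @param weight_decay Decoupled (AdamW-style) weight decay. Soft Dice
#'   through a softmax has absorbing saturated states: once a class's
#'   probability reaches 0 at a set of pixels its gradient there vanishes and
#'   the class can never recover. A small weight decay bounds the logits and
#'   removes the absorbing states. Default `1e-3`.
#' @param seed Seed controlling shuffling, the validation split and any
#'   augmentation draws during training.
#' @return An object of class `frugalseg_train_config`.
#' @export
train_config <- function(batch_size = 11, learning_rate = 1e-3,
                         max_epochs = 50, patience = 5,
                         validation_fraction = 0.1, weight_decay = 1e-3,
                         seed = NULL) {
  stopifnot(batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            patience >= 1, validation_fraction >= 0, validation_fraction < 1,
            weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), patience = patience,
                 validation_fraction = validation_fraction,
                 weight_decay = weight_decay, seed = seed),
            class = "frugalseg_train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && grepl("_W$", nm))
      params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

#' Train a segmentation network on (possibly heterogeneous) labels
#'
#' Runs mini-batch Adam on the combined objective. The per-sample loss uses
#' that sample's mask vector, and the batch loss is the mean of the
#' per-sample losses, so the per-sample normalization by the number of
#' present masks stays correct when availability varies within a batch. When
#' a [heterogeneous_view()] is supplied, labels are dropped online through it
#' ([apply_drops()]), and its sample memory is reset after every epoch.
#' Validation (when enabled) monitors the Dice loss on held-out training
#' samples with their full labels, and early stopping restores the best
#' weights.
#'
#' @param net A [build_network()] model.
#' @param dataset A `frugalseg_dataset` (only its `split == "train"` samples
#'   are used unless `ids` is given).
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param view Optional [heterogeneous_view()] for online label dropping.
#' @param sampler Optional `function(epoch, ids)` returning the (possibly
#'   oversampled) sequence of sample ids to visit that epoch; defaults to a
#'   random shuffle.
#' @param ids Optional explicit training ids.
#' @param augment_cfg Optional [augment_config()] applied online per access.
#' @param verbose Print per-epoch losses.
#' @return `list(net, history)`; `history` is a data.frame with per-epoch
#'   training `loss`, `dsc_loss`, `cal_loss` and `val_dsc_loss`.
#' @export
train_network <- function(net, dataset, train_cfg = train_config(),
                          loss_cfg = loss_config(), view = NULL,
                          sampler = NULL, ids = NULL, augment_cfg = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(net, "frugalseg_net"))
  if (is.null(ids)) ids <- dataset$ids[dataset$split == "train"]
  if (length(ids) == 0L) stop("no training samples", call. = FALSE)
  run <- function() {
    val_ids <- character(0)
    if (train_cfg$validation_fraction > 0) {
      n_val <- max(1L, floor(train_cfg$validation_fraction * length(ids)))
      val_ids <- sample(ids, n_val)
    }
    fit_ids <- setdiff(ids, val_ids)
    if (length(fit_ids) < train_cfg$batch_size)
      stop("training stream shorter than one batch (", length(fit_ids),
           " samples, batch size ", train_cfg$batch_size, ")", call. = FALSE)
    params <- net$params
    state <- adam_init(params)
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       dsc_loss = numeric(), cal_loss = numeric(),
                       val_dsc_loss = numeric())
    best <- list(val = Inf, params = params, since = 0L)
    fetch <- function(id) {
      smp <- dataset$samples[[id]]
      gt <- smp$gt; m <- smp$m
      if (!is.null(view)) {
        dr <- apply_drops(view, id, gt)
        gt <- dr$gt; m <- dr$m
      }
      img <- smp$image
      if (!is.null(augment_cfg)) {
        au <- augment(img, gt, augment_cfg)
        img <- au$image; gt <- au$gt
      }
      list(image = img, gt = gt, m = m)
    }
    for (epoch in seq_len(train_cfg$max_epochs)) {
      order_ids <- if (is.null(sampler)) sample(fit_ids) else sampler(epoch, fit_ids)
      sums <- c(loss = 0, dsc = 0, cal = 0)
      n_seen <- 0L
      for (start in seq(1L, length(order_ids), by = train_cfg$batch_size)) {
        batch <- order_ids[start:min(start + train_cfg$batch_size - 1L,
                                     length(order_ids))]
        gacc <- NULL
        for (id in batch) {
          smp <- fetch(id)
          net$params <- params
          fw <- net_forward(net, smp$image, cache = TRUE)
          comps <- combined_loss_components(smp$gt, fw$pred, smp$m, loss_cfg)
          dpred <- combined_loss_grad(smp$gt, fw$pred, smp$m, loss_cfg)
          g <- net_backward(net, fw$cache, softmax_backward(dpred, fw$pred))
          gacc <- if (is.null(gacc)) g else
            Map(`+`, gacc, g)
          sums <- sums + c(comps$total, comps$dsc, comps$cal)
          n_seen <- n_seen + 1L
        }
        gacc <- lapply(gacc, `/`, length(batch))
        st <- adam_step(params, gacc, state, train_cfg$learning_rate,
                        train_cfg$weight_decay)
        params <- st$params; state <- st$state
      }
      net$params <- params
      val_dsc <- NA_real_
      if (length(val_ids)) {
        val_dsc <- mean(vapply(val_ids, function(id) {
          smp <- dataset$samples[[id]]
          dice_loss(smp$gt, net_forward(net, smp$image)$pred, smp$m, loss_cfg)
        }, 0))
        if (val_dsc < best$val - 1e-6) {
          best$val <- val_dsc; best$params <- params; best$since <- 0L
        } else best$since <- best$since + 1L
      }
      hist <- rbind(hist, data.frame(epoch = epoch, loss = sums[1] / n_seen,
                                     dsc_loss = sums[2] / n_seen,
                                     cal_loss = sums[3] / n_seen,
                                     val_dsc_loss = val_dsc))
      if (verbose)
        message(sprintf("epoch %d: L=%.4f L_DSC=%.4f L_CAL=%.4f val=%.4f",
                        epoch, sums[1] / n_seen, sums[2] / n_seen,
                        sums[3] / n_seen, val_dsc))
      if (!is.null(view)) reset_memory(view)
      if (length(val_ids) && best$since >= train_cfg$patience) break
    }
    if (length(val_ids) && is.finite(best$val)) net$params <- best$params
    rownames(hist) <- NULL
    list(net = net, history = hist)
  }
  if (is.null(train_cfg$seed)) run()
  else with_isolated_seed(derive_seed(train_cfg$seed, 17L), run())
}

#' Predict soft segmentations
#'
#' @param net A trained [build_network()] model.
#' @param images A single `(h, w, 3)` array or a list of them.
#' @return A `(h, w, C)` prediction (or list of predictions); per-pixel
#'   channel sums are 1. Use [hard_masks()] for argmax labelings.
#' @export
predict_network <- function(net, images) {
  one <- function(x) {
    if (!identical(dim(x)[1:2], net$cfg$input_size))
      stop("input size ", paste(dim(x)[1:2], collapse = "x"),
           " does not match the network input ",
           paste(net$cfg$input_size, collapse = "x"), call. = FALSE)
    net_forward(net, x)$pred
  }
  if (is.list(images)) lapply(images, one) else one(images)
}
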