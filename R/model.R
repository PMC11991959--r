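#' Model configuration for the multi-task TCN
#'
#' The network is a temporal convolutional network: a two-stage strided
#' encoder downsamples the 25 Hz two-belt input by a factor of 25 to a
#' 1 Hz feature sequence, followed by a chain of residual blocks with
#' exponentially increasing dilation (non-causal, centred convolutions:
#' the four future context epochs are inputs by design). Two heads share
#' the trunk: a 3-way softmax over the center epoch's sleep state
#' (Wake/NREM/REM) pooled over the center 30 steps, and a per-second
#' sigmoid arousal probability for each of the center epoch's 30
#' seconds.
#'
#' @param n_blocks number of residual blocks.
#' @param kernel_size odd convolution kernel length (in trunk samples).
#' @param dilations per-block dilation factors (length `n_blocks`).
#' @param channels trunk feature channels.
#' @param enc_channels channels after the first encoder stage.
#' @param spatial_dropout_rate channel-dropout probability in blocks.
#' @param use_batch_norm logical.
#' @param context_epochs context epochs each side of the center (4).
#' @param sample_rate input rate, Hz.
#' @return list of class `nbs_config`. Construction fails if the
#'   receptive field induced by the dilations does not cover the full
#'   9-epoch window.
#' @export
model_config <- function(n_blocks = 6, kernel_size = 7,
                         dilations = c(1, 2, 4, 8, 16, 32),
                         channels = 16, enc_channels = 12,
                         spatial_dropout_rate = 0.1,
                         use_batch_norm = TRUE,
                         context_epochs = 4L, sample_rate = 25) {
  stopifnot(length(dilations) == n_blocks, kernel_size %% 2 == 1)
  cfg <- structure(
    list(n_blocks = as.integer(n_blocks), kernel_size = as.integer(kernel_size),
         dilations = as.integer(dilations), channels = as.integer(channels),
         enc_channels = as.integer(enc_channels),
         spatial_dropout_rate = spatial_dropout_rate,
         use_batch_norm = isTRUE(use_batch_norm),
         context_epochs = as.integer(context_epochs),
         sample_rate = sample_rate),
    class = "nbs_config")
  win <- window_samples(cfg)
  rf <- receptive_field(cfg)
  if (rf < win) {
    abort(sprintf(
      "receptive field (%d samples) smaller than the %d-sample window; increase dilations",
      rf, win))
  }
  cfg
}

window_samples <- function(cfg) {
  as.integer((2L * cfg$context_epochs + 1L) * 30 * cfg$sample_rate)
}

#' Receptive field of the configured network, in input samples
#'
#' Computed with the standard recursion `rf <- rf + (k - 1) * d * jump`
#' over all convolutions (two strided encoder convolutions, then two
#' dilated convolutions per residual block).
#'
#' @param cfg an `nbs_config` (or `nbs_model`).
#' @return integer number of input samples.
#' @export
receptive_field <- function(cfg) {
  if (inherits(cfg, "nbs_model")) cfg <- cfg$config
  k <- cfg$kernel_size
  rf <- 1L; jump <- 1L
  for (s in c(5L, 5L)) {        # encoder stages
    rf <- rf + (k - 1L) * jump
    jump <- jump * s
  }
  for (d in cfg$dilations) {    # two convs per residual block
    rf <- rf + 2L * (k - 1L) * d * jump
  }
  as.integer(rf)
}

init_w <- function(c_out, c_in, k) {
  # He initialization for ReLU networks
  array(rnorm(c_out * c_in * k, 0, sqrt(2 / (c_in * k))),
        dim = c(c_out, c_in, k))
}

#' Build a multi-task TCN model
#'
#' Instantiates parameters (He-initialized, deterministic under `seed`)
#' for the shared trunk and the two task heads.
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed for initialization.
#' @return object of class `nbs_model` with elements `config`, `params`
#'   (flat named list of arrays) and `bn` (running statistics).
#' @export
build_model <- function(cfg = model_config(), seed = 0L) {
  stopifnot(inherits(cfg, "nbs_config"))
  k <- cfg$kernel_size; ch <- cfg$channels; ec <- cfg$enc_channels
  with_seed(seed, {
    params <- list()
    params[["enc1.W"]] <- init_w(ec, 2L, k); params[["enc1.b"]] <- rep(0, ec)
    params[["enc2.W"]] <- init_w(ch, ec, k); params[["enc2.b"]] <- rep(0, ch)
    bn <- list()
    add_bn <- function(nm, c) {
      params[[paste0(nm, ".gamma")]] <<- rep(1, c)
      params[[paste0(nm, ".beta")]] <<- rep(0, c)
      bn[[nm]] <<- list(mean = rep(0, c), var = rep(1, c))
    }
    add_bn("enc1.bn", ec); add_bn("enc2.bn", ch)
    for (i in seq_len(cfg$n_blocks)) {
      p <- sprintf("blk%d", i)
      params[[paste0(p, ".W1")]] <- init_w(ch, ch, k)
      params[[paste0(p, ".b1")]] <- rep(0, ch)
      params[[paste0(p, ".W2")]] <- init_w(ch, ch, k)
      params[[paste0(p, ".b2")]] <- rep(0, ch)
      add_bn(paste0(p, ".bn1"), ch); add_bn(paste0(p, ".bn2"), ch)
    }
    params[["state.W"]] <- matrix(rnorm(3 * ch, 0, sqrt(1 / ch)), 3, ch)
    params[["state.b"]] <- rep(0, 3)
    params[["ar.W"]] <- matrix(rnorm(ch, 0, sqrt(1 / ch)), 1, ch)
    params[["ar.b"]] <- 0
    structure(list(config = cfg, params = params, bn = bn),
              class = "nbs_model")
  })
}

#' @export
print.nbs_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<nbs_model: %d residual blocks, %d channels, %s parameters, receptive field %d samples>\n",
    x$config$n_blocks, x$config$channels, format(np, big.mark = ","),
    receptive_field(x$config)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `nbs_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

center_steps <- function(cfg) {
  ctx <- cfg$context_epochs
  (ctx * 30L + 1L):((ctx + 1L) * 30L)
}

run_bn <- function(model, nm, x, training, cache, grads_env = NULL) {
  if (!model$config$use_batch_norm) {
    return(list(out = x, cache = NULL, model = model))
  }
  r <- bn_fwd(x, model$params[[paste0(nm, ".gamma")]],
              model$params[[paste0(nm, ".beta")]],
              model$bn[[nm]]$mean, model$bn[[nm]]$var, training)
  if (training) {
    model$bn[[nm]]$mean <- r$run_mean
    model$bn[[nm]]$var <- r$run_var
  }
  list(out = r$out, cache = r$cache, model = model)
}

# Full forward pass. x: array (2, window_samples, batch).
# Returns logits plus (optionally) the cache needed for backprop.
nbs_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernel_size
  hpad <- (k - 1L) %/% 2L
  cache <- list()

  st <- conv1d_fwd(x, p[["enc1.W"]], p[["enc1.b"]], 5L, 1L, hpad)
  cache$enc1 <- st$cache
  b <- run_bn(model, "enc1.bn", st$out, training, cache)
  model <- b$model; cache$enc1.bn <- b$cache
  r <- relu_fwd(b$out); cache$enc1.relu <- r$cache
  h <- r$out

  st <- conv1d_fwd(h, p[["enc2.W"]], p[["enc2.b"]], 5L, 1L, hpad)
  cache$enc2 <- st$cache
  b <- run_bn(model, "enc2.bn", st$out, training, cache)
  model <- b$model; cache$enc2.bn <- b$cache
  r <- relu_fwd(b$out); cache$enc2.relu <- r$cache
  h <- r$out

  for (i in seq_len(cfg$n_blocks)) {
    nm <- sprintf("blk%d", i)
    d <- cfg$dilations[i]
    skip <- h
    c1 <- conv1d_fwd(h, p[[paste0(nm, ".W1")]], p[[paste0(nm, ".b1")]],
                     1L, d, hpad * d)
    b1 <- run_bn(model, paste0(nm, ".bn1"), c1$out, training, cache)
    model <- b1$model
    r1 <- relu_fwd(b1$out)
    dr <- sdrop_fwd(r1$out, cfg$spatial_dropout_rate, training)
    c2 <- conv1d_fwd(dr$out, p[[paste0(nm, ".W2")]], p[[paste0(nm, ".b2")]],
                     1L, d, hpad * d)
    b2 <- run_bn(model, paste0(nm, ".bn2"), c2$out, training, cache)
    model <- b2$model
    r2 <- relu_fwd(b2$out + skip)
    cache[[nm]] <- list(c1 = c1$cache, bn1 = b1$cache, r1 = r1$cache,
                        dr = dr$cache, c2 = c2$cache, bn2 = b2$cache,
                        r2 = r2$cache)
    h <- r2$out
  }

  ctr <- center_steps(cfg)
  feat_c <- h[, ctr, , drop = FALSE]                 # (F, 30, B)
  nb <- dim(feat_c)[3]; fch <- dim(feat_c)[1]
  pooled <- apply(feat_c, 3, rowMeans)
  pooled <- matrix(pooled, nrow = fch, ncol = nb)
  state_logits <- p[["state.W"]] %*% pooled + p[["state.b"]]
  af <- matrix(feat_c, nrow = fch)                   # (F, 30*B)
  ar_logits <- matrix(p[["ar.W"]] %*% af + p[["ar.b"]], nrow = 30)

  out <- list(state_logits = state_logits, ar_logits = ar_logits,
              model = model)
  if (keep_cache) {
    cache$feat_c <- feat_c; cache$pooled <- pooled; cache$af <- af
    cache$h_dim <- dim(h)
    out$cache <- cache
  }
  out
}

# Backward pass from head-logit gradients to parameter gradients.
nbs_backward <- function(model, cache, d_state_logits, d_ar_logits) {
  cfg <- model$config
  p <- model$params
  g <- list()
  fch <- dim(cache$feat_c)[1]; nb <- dim(cache$feat_c)[3]

  g[["state.W"]] <- d_state_logits %*% t(cache$pooled)
  g[["state.b"]] <- rowSums(d_state_logits)
  dpooled <- crossprod(p[["state.W"]], d_state_logits)   # (F, B)

  darf <- matrix(d_ar_logits, nrow = 1)                  # (1, 30*B)
  g[["ar.W"]] <- darf %*% t(cache$af)
  g[["ar.b"]] <- sum(darf)
  daf <- crossprod(p[["ar.W"]], darf)                    # (F, 30*B)

  dfeat_c <- array(daf, dim = c(fch, 30L, nb))
  for (b in seq_len(nb)) {
    dfeat_c[, , b] <- dfeat_c[, , b] + dpooled[, b] / 30
  }
  dh <- array(0, dim = cache$h_dim)
  dh[, center_steps(cfg), ] <- dfeat_c

  bn_b <- function(nm, dy, bcache) {
    if (!cfg$use_batch_norm) return(dy)
    r <- bn_bwd(dy, bcache)
    g[[paste0(nm, ".gamma")]] <<- r$dgamma
    g[[paste0(nm, ".beta")]] <<- r$dbeta
    r$dx
  }

  for (i in rev(seq_len(cfg$n_blocks))) {
    nm <- sprintf("blk%d", i)
    cc <- cache[[nm]]
    dy <- relu_bwd(dh, cc$r2)
    dskip <- dy
    dy <- bn_b(paste0(nm, ".bn2"), dy, cc$bn2)
    cb <- conv1d_bwd(dy, cc$c2)
    g[[paste0(nm, ".W2")]] <- cb$dW; g[[paste0(nm, ".b2")]] <- cb$db
    dy <- sdrop_bwd(cb$dx, cc$dr)
    dy <- relu_bwd(dy, cc$r1)
    dy <- bn_b(paste0(nm, ".bn1"), dy, cc$bn1)
    cb <- conv1d_bwd(dy, cc$c1)
    g[[paste0(nm, ".W1")]] <- cb$dW; g[[paste0(nm, ".b1")]] <- cb$db
    dh <- cb$dx + dskip
  }

  dy <- relu_bwd(dh, cache$enc2.relu)
  dy <- bn_b("enc2.bn", dy, cache$enc2.bn)
  cb <- conv1d_bwd(dy, cache$enc2)
  g[["enc2.W"]] <- cb$dW; g[["enc2.b"]] <- cb$db

  dy <- relu_bwd(cb$dx, cache$enc1.relu)
  dy <- bn_b("enc1.bn", dy, cache$enc1.bn)
  cb <- conv1d_bwd(dy, cache$enc1)
  g[["enc1.W"]] <- cb$dW; g[["enc1.b"]] <- cb$db
  g
}

#' Forward pass for one context window
#'
#' Maps a 9-epoch context window to the center epoch's sleep-state
#' probability triplet (softmax over Wake/NREM/REM) and 30 per-second
#' arousal probabilities (sigmoid).
#'
#' @param model a built (or trained) `nbs_model`.
#' @param window a `context_window` or a 2 x 6750 numeric matrix.
#' @return list: `state_probs` (named 3-vector summing to 1),
#'   `arousal_probs` (length-30 vector in `[0, 1]`).
#' @export
predict_window <- function(model, window) {
  x <- if (inherits(window, "context_window")) window$signal else window
  if (!is.matrix(x) || nrow(x) != 2 ||
      ncol(x) != window_samples(model$config)) {
    abort(sprintf("window must be a 2 x %d signal matrix",
                  window_samples(model$config)))
  }
  fw <- nbs_forward(model, array(x, dim = c(2, ncol(x), 1)),
                    training = FALSE)
  sp <- drop(softmax_cols(fw$state_logits))
  list(state_probs = setNames(sp, sleep_states),
       arousal_probs = as.numeric(sigmoid(fw$ar_logits)))
}

#' Predict hypnodensity and arousal probabilities for a recording
#'
#' Slides the 9-epoch context window one epoch at a time across the
#' preprocessed recording and concatenates the center-epoch outputs:
#' one probability triplet per epoch (the hypnodensity) and one
#' arousal probability per second.
#'
#' @param model a trained `nbs_model`.
#' @param rec a preprocessed [rip_recording()] (or a `rip_windows`).
#' @param chunk windows evaluated per forward pass.
#' @return list of class `nbs_prediction`: `hypnodensity` (tibble with
#'   epoch, WAKE, NREM, REM; rows sum to 1), `arousal_probs` (numeric,
#'   `30 * n_epochs`).
#' @export
predict_recording <- function(model, rec, chunk = 64L) {
  ws <- if (inherits(rec, "rip_windows")) rec else assemble_windows(rec)
  if (ws$n_epochs < 1) abort("recording shorter than one epoch")
  n_ep <- ws$n_epochs
  wlen <- window_samples(model$config)
  probs <- matrix(0, nrow = n_ep, ncol = 3)
  arp <- numeric(n_ep * 30L)
  for (start in seq(1L, n_ep, by = chunk)) {
    eps <- start:min(start + chunk - 1L, n_ep)
    x <- array(0, dim = c(2L, wlen, length(eps)))
    for (j in seq_along(eps)) x[, , j] <- window_signal(ws, eps[j] - 1L)
    fw <- nbs_forward(model, x, training = FALSE)
    probs[eps, ] <- t(softmax_cols(fw$state_logits))
    arp[rep((eps - 1L) * 30L, each = 30L) + 1:30] <-
      as.numeric(fw$ar_logits |> sigmoid())
  }
  hd <- tibble(epoch = seq_len(n_ep) - 1L,
               WAKE = probs[, 1], NREM = probs[, 2], REM = probs[, 3])
  structure(list(hypnodensity = hd, arousal_probs = arp),
            class = "nbs_prediction")
}

#' @export
print.nbs_prediction <- function(x, ...) {
  cat(sprintf("<nbs_prediction: %d epochs, %d arousal seconds>\n",
              nrow(x$hypnodensity), length(x$arousal_probs)))
  invisible(x)
}

#' Save / load a model checkpoint as JSON
#'
#' Checkpoints carry the config, all parameters, batch-norm running
#' statistics and the training seed, in a plain-text JSON container.
#'
#' @param model an `nbs_model`; @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  ser <- list(
    config = unclass(model$config),
    params = lapply(model$params, function(p)
      list(dim = dim(as.array(p)), data = as.numeric(p))),
    bn = model$bn,
    seed = model$seed %||% NA
  )
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, ser$config[c(
    "n_blocks", "kernel_size", "dilations", "channels", "enc_channels",
    "spatial_dropout_rate", "use_batch_norm", "context_epochs",
    "sample_rate")])
  params <- lapply(ser$params, function(p) {
    if (length(p$dim) > 1) array(p$data, dim = p$dim) else as.numeric(p$data)
  })
  bn <- lapply(ser$bn, function(b) list(mean = as.numeric(b$mean),
                                        var = as.numeric(b$var)))
  structure(list(config = cfg, params = params, bn = bn,
                 seed = ser$seed),
            class = "nbs_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
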