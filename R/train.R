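#' Training configuration
#'
#' @param steps optimizer steps.
#' @param batch_size windows per step.
#' @param lr AdamW learning rate.
#' @param weight_decay decoupled weight decay (weights only).
#' @param lambda weight of the per-second arousal cross-entropy in the
#'   total loss (state cross-entropy has weight 1).
#' @param eval_every steps between tuning-split evaluations.
#' @param patience evaluations without tune improvement before stopping.
#' @param seed seed controlling sampling, augmentation and dropout.
#' @param augment list(scale_range, max_shift_s) or NULL to disable.
#' @param tune_cap maximum tuning windows used per evaluation.
#' @return list of class `train_config`.
#' @export
train_config <- function(steps = 1500, batch_size = 32, lr = 3e-3,
                         weight_decay = 1e-4, lambda = 1,
                         eval_every = 100, patience = 10, seed = 0L,
                         augment = list(scale_range = c(0.8, 1.25),
                                        max_shift_s = 4L),
                         tune_cap = 256L) {
  structure(as.list(environment()), class = "train_config")
}

# Cross-entropy losses and head-logit gradients for one batch.
batch_loss <- function(model, x, state, arousal, lambda, training,
                       want_grads = TRUE) {
  nb <- dim(x)[3]
  fw <- nbs_forward(model, x, training = training, keep_cache = want_grads)
  model <- fw$model
  probs <- softmax_cols(fw$state_logits)
  eps <- 1e-12
  l_state <- -mean(log(pmax(probs[cbind(state, seq_len(nb))], eps)))
  q <- sigmoid(fw$ar_logits)                     # (30, B)
  y <- t(arousal)
  l_ar <- -mean(y * log(pmax(q, eps)) + (1 - y) * log(pmax(1 - q, eps)))
  out <- list(loss = l_state + lambda * l_ar, state_loss = l_state,
              ar_loss = l_ar, model = model)
  if (want_grads) {
    onehot <- matrix(0, 3, nb)
    onehot[cbind(state, seq_len(nb))] <- 1
    d_state <- (probs - onehot) / nb
    d_ar <- lambda * (q - y) / (30 * nb)
    out$grads <- nbs_backward(model, fw$cache, d_state, d_ar)
  }
  out
}

# fast pooled balanced sampler used inside the training loop
make_pool <- function(wsets) {
  pool <- purrr::map_dfr(seq_along(wsets), function(i) {
    tibble(set = i, epoch = wsets[[i]]$index$epoch,
           pos = wsets[[i]]$index$any_arousal)
  })
  list(pos = which(pool$pos), neg = which(!pool$pos), pool = pool)
}

draw_batch <- function(wsets, pl, bs, augment_cfg) {
  want_pos <- runif(bs) < 0.5
  rows <- integer(bs)
  rows[want_pos] <- pl$pos[sample.int(length(pl$pos), sum(want_pos),
                                      replace = TRUE)]
  rows[!want_pos] <- pl$neg[sample.int(length(pl$neg), sum(!want_pos),
                                       replace = TRUE)]
  spe <- samples_per_epoch(wsets[[1]]$sample_rate)
  wlen <- spe * (2L * wsets[[1]]$context_epochs + 1L)
  x <- array(0, dim = c(2L, wlen, bs))
  state <- integer(bs)
  ar <- matrix(0L, bs, 30)
  for (b in seq_len(bs)) {
    ws <- wsets[[pl$pool$set[rows[b]]]]
    ep <- pl$pool$epoch[rows[b]]
    shift <- 0L; fac <- c(1, 1)
    if (!is.null(augment_cfg)) {
      fac <- runif(2, augment_cfg$scale_range[1], augment_cfg$scale_range[2])
      ms <- augment_cfg$max_shift_s
      if (ms > 0) shift <- sample.int(2L * ms + 1L, 1L) - ms - 1L
    }
    x[, , b] <- window_signal(ws, ep, shift_s = shift) * fac
    state[b] <- match(ws$index$state[ep + 1L], sleep_states)
    ar[b, ] <- window_targets(ws, ep, shift_s = shift)
  }
  list(x = x, state = state, arousal = ar, positive = pl$pool$pos[rows])
}

tune_loss <- function(model, tune_sets, lambda, cap, chunk = 64L) {
  # fixed, deterministic evaluation subset: evenly spaced windows
  pool <- purrr::map_dfr(seq_along(tune_sets), function(i) {
    tibble(set = i, epoch = tune_sets[[i]]$index$epoch)
  })
  if (nrow(pool) > cap) {
    pool <- pool[round(seq(1, nrow(pool), length.out = cap)), ]
  }
  tot <- 0; n <- 0L
  for (start in seq(1L, nrow(pool), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(pool))
    spe <- samples_per_epoch(tune_sets[[1]]$sample_rate)
    wlen <- spe * (2L * tune_sets[[1]]$context_epochs + 1L)
    x <- array(0, dim = c(2L, wlen, length(rows)))
    state <- integer(length(rows))
    ar <- matrix(0L, length(rows), 30)
    for (j in seq_along(rows)) {
      ws <- tune_sets[[pool$set[rows[j]]]]
      ep <- pool$epoch[rows[j]]
      x[, , j] <- window_signal(ws, ep)
      state[j] <- match(ws$index$state[ep + 1L], sleep_states)
      ar[j, ] <- window_targets(ws, ep)
    }
    bl <- batch_loss(model, x, state, ar, lambda, training = FALSE,
                     want_grads = FALSE)
    tot <- tot + bl$loss * length(rows)
    n <- n + length(rows)
  }
  tot / n
}

#' Train the multi-task TCN
#'
#' Optimizes the summed loss `state cross-entropy + lambda * per-second
#' arousal cross-entropy` with AdamW, drawing class-balanced batches
#' (each drawn window contains a scored arousal with probability 0.5)
#' with scale/shift augmentation. Batch normalization uses batch
#' statistics during training and running statistics at evaluation;
#' spatial dropout is active only during training. The tuning split is
#' evaluated every `eval_every` steps and the best-on-tune parameters
#' are returned. Training aborts with a diagnostic if the loss becomes
#' non-finite. With a fixed seed the run is reproducible on one device.
#'
#' @param model a built `nbs_model`.
#' @param train_sets,tune_sets annotated `rip_windows` (or lists).
#' @param tc a [train_config()].
#' @param verbose print progress.
#' @return list of class `nbs_fit`: `model` (best-on-tune), `history`
#'   tibble (step, train_loss, state_loss, ar_loss, pos_fraction,
#'   tune_loss), `config`.
#' @export
train_nbs <- function(model, train_sets, tune_sets, tc = train_config(),
                      verbose = FALSE) {
  if (inherits(train_sets, "rip_windows")) train_sets <- list(train_sets)
  if (inherits(tune_sets, "rip_windows")) tune_sets <- list(tune_sets)
  if (length(train_sets) == 0 || length(tune_sets) == 0) {
    abort("both training and tuning splits must be non-empty")
  }
  pl <- make_pool(train_sets)
  if (length(pl$pos) == 0L || length(pl$neg) == 0L) {
    warn("one arousal stratum is empty; uniform sampling used")
    if (length(pl$pos) == 0L) pl$pos <- pl$neg
    if (length(pl$neg) == 0L) pl$neg <- pl$pos
  }
  opt <- adamw_init(model$params, lr = tc$lr, weight_decay = tc$weight_decay)
  hist <- list()
  best <- list(loss = Inf, params = model$params, bn = model$bn)
  since_best <- 0L
  with_seed(tc$seed, {
    for (step in seq_len(tc$steps)) {
      batch <- draw_batch(train_sets, pl, tc$batch_size, tc$augment)
      bl <- batch_loss(model, batch$x, batch$state, batch$arousal,
                       tc$lambda, training = TRUE)
      model <- bl$model
      if (!is.finite(bl$loss)) {
        abort(sprintf(
          "training diverged at step %d (loss %s); lower the learning rate",
          step, format(bl$loss)))
      }
      up <- adamw_step(model$params, bl$grads, opt)
      model$params <- up$params; opt <- up$opt
      rec <- tibble(step = step, train_loss = bl$loss,
                    state_loss = bl$state_loss, ar_loss = bl$ar_loss,
                    pos_fraction = mean(batch$positive),
                    tune_loss = NA_real_)
      if (step %% tc$eval_every == 0L || step == tc$steps) {
        tl <- tune_loss(model, tune_sets, tc$lambda, tc$tune_cap)
        rec$tune_loss <- tl
        if (tl < best$loss) {
          best <- list(loss = tl, params = model$params, bn = model$bn)
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
        }
        if (verbose) {
          message(sprintf("step %5d  train %.4f  tune %.4f", step,
                          bl$loss, tl))
        }
        if (since_best >= tc$patience) {
          hist[[length(hist) + 1L]] <- rec
          break
        }
      }
      hist[[length(hist) + 1L]] <- rec
    }
  })
  model$params <- best$params
  model$bn <- best$bn
  model$seed <- tc$seed
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 config = tc),
            class = "nbs_fit")
}

#' @export
print.nbs_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<nbs_fit: %d steps, final train loss %.4f, best tune loss %.4f>\n",
              n, x$history$train_loss[n],
              min(x$history$tune_loss, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.nbs_fit <- function(x, ...) x$history

#' @export
glance.nbs_fit <- function(x, ...) {
  tibble(steps = nrow(x$history),
         final_train_loss = x$history$train_loss[nrow(x$history)],
         best_tune_loss = min(x$history$tune_loss, na.rm = TRUE),
         mean_pos_fraction = mean(x$history$pos_fraction),
         n_parameters = n_parameters(x$model))
}
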