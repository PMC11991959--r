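#' Score sleep states from a hypnodensity track
#'
#' Takes the per-epoch state probabilities to a hypnogram: per-epoch
#' argmax followed by a smoothing pass that regularizes the state
#' sequence (a sliding mode filter; ties keep the center epoch's
#' argmax). Smoothing never introduces a state absent from the local
#' window. With `smooth_window = 1` (or 0) the raw argmax is returned.
#'
#' @param track hypnodensity: an `nbs_prediction`, or a tibble/matrix
#'   with columns/cols WAKE, NREM, REM (rows on the probability
#'   simplex).
#' @param smooth_window odd mode-filter width in epochs (default 5).
#' @return a [hypnogram()].
#' @export
score_sleep_states <- function(track, smooth_window = 5L) {
  m <- hypnodensity_matrix(track)
  if (nrow(m) == 0) abort("empty hypnodensity track")
  if (any(!is.finite(m)) || any(m < 0) ||
      any(abs(rowSums(m) - 1) > 1e-4)) {
    abort("hypnodensity rows must be probability triplets summing to 1")
  }
  raw <- max.col(m, ties.method = "first")
  sm <- mode_filter(raw, smooth_window)
  hypnogram(sleep_states[sm])
}

hypnodensity_matrix <- function(track) {
  if (inherits(track, "nbs_prediction")) track <- track$hypnodensity
  if (is.data.frame(track)) {
    as.matrix(track[, c("WAKE", "NREM", "REM")])
  } else {
    as.matrix(track)
  }
}

# sliding mode filter; ties resolved in favour of the center element
mode_filter <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) abort("smooth_window must be odd")
  h <- w %/% 2L
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    win <- x[max(1L, i - h):min(n, i + h)]
    tab <- tabulate(win, nbins = max(x))
    best <- which(tab == max(tab))
    out[i] <- if (x[i] %in% best) x[i] else best[1]
  }
  out
}

#' Detect arousal events from a per-second probability track
#'
#' Implements the rule-based post-processing step: maximal runs of
#' consecutive seconds whose arousal probability strictly exceeds the
#' threshold become events if the run lasts at least 3 s; 1-2 s runs
#' are discarded. Event onset is the run start and duration the run
#' length; runs separated by at least one sub-threshold second remain
#' distinct events (no gap merging).
#'
#' @param probs numeric vector of per-second probabilities (an
#'   `nbs_prediction` is also accepted).
#' @param threshold detection threshold in (0, 1); default 0.5.
#' @param min_duration minimum run length in seconds (default 3).
#' @return [events_table()] of arousals.
#' @export
detect_arousals <- function(probs, threshold = 0.5, min_duration = 3L) {
  if (inherits(probs, "nbs_prediction")) probs <- probs$arousal_probs
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  above <- probs > threshold
  if (!any(above)) return(events_table(type = "arousal"))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  events_table(onset = starts[keep] - 1L, duration = r$lengths[keep],
               type = "arousal")
}

#' Total sleep time from a hypnogram
#'
#' TST in minutes: 0.5 minutes per NREM or REM epoch. ARTIFACT epochs
#' contribute to neither sleep nor wake.
#'
#' @param hyp a hypnogram.
#' @return minutes (numeric).
#' @export
compute_tst <- function(hyp) {
  st <- hypnogram_states_chr(hyp)
  0.5 * sum(st %in% c("NREM", "REM"))
}

#' Arousal index
#'
#' Arousals per hour of sleep: `60 * n_events / tst_minutes`.
#'
#' @param events arousal [events_table()] (or a count).
#' @param tst total sleep time in minutes (> 0).
#' @return events/hour.
#' @export
compute_ari <- function(events, tst) {
  n <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  if (!is.numeric(tst) || tst <= 0) {
    abort("arousal index undefined: total sleep time must be positive")
  }
  60 * n / tst
}

#' Score a recording end to end
#'
#' Runs the trained model over a preprocessed recording and applies the
#' rule-based scoring: hypnogram via argmax + mode smoothing, arousal
#' events via the 3-s threshold rule, then summary indices.
#'
#' @param model trained `nbs_model`.
#' @param rec preprocessed [rip_recording()] (or `rip_windows`).
#' @param threshold arousal detection threshold.
#' @param smooth_window mode-filter width (epochs).
#' @return list of class `nbs_scoring`: `hypnogram`, `arousals`,
#'   `prediction`, `summary` (tibble: tst_min, ari, n_arousals).
#' @export
score_recording <- function(model, rec, threshold = 0.5,
                            smooth_window = 5L) {
  pred <- predict_recording(model, rec)
  hyp <- score_sleep_states(pred, smooth_window)
  ev <- detect_arousals(pred, threshold)
  # arousals scored during predicted wake are not sleep arousals
  if (nrow(ev) > 0) {
    st <- hypnogram_states_chr(hyp)
    keep <- st[pmin(epoch_of(ev$onset) + 1L, length(st))] %in%
      c("NREM", "REM")
    ev <- ev[keep, ]
  }
  tst <- compute_tst(hyp)
  structure(list(
    hypnogram = hyp, arousals = ev, prediction = pred,
    summary = tibble(tst_min = tst,
                     ari = if (tst > 0) compute_ari(ev, tst) else NA_real_,
                     n_arousals = nrow(ev))
  ), class = "nbs_scoring")
}

#' @export
print.nbs_scoring <- function(x, ...) {
  cat(sprintf("<nbs_scoring: TST %.1f min, %d arousals, ArI %.1f /h>\n",
              x$summary$tst_min, x$summary$n_arousals, x$summary$ari))
  invisible(x)
}

#' Event-level F1 between two arousal scorings
#'
#' Greedy one-to-one matching of predicted to reference events by
#' temporal overlap; F1 = 2 * matches / (n_pred + n_ref).
#'
#' @param ref,pred arousal [events_table()]s.
#' @return list: f1, precision, recall, n_matched.
#' @export
event_f1 <- function(ref, pred) {
  n_r <- nrow(ref); n_p <- nrow(pred)
  if (n_r == 0 && n_p == 0) return(list(f1 = NA_real_, precision = NA_real_,
                                        recall = NA_real_, n_matched = 0L))
  used <- rep(FALSE, n_r)
  matched <- 0L
  if (n_p > 0 && n_r > 0) {
    for (i in seq_len(n_p)) {
      p0 <- pred$onset[i]; p1 <- p0 + pred$duration[i]
      ov <- which(!used & ref$onset < p1 & (ref$onset + ref$duration) > p0)
      if (length(ov) > 0) {
        used[ov[1]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  list(f1 = 2 * matched / (n_p + n_r),
       precision = if (n_p > 0) matched / n_p else NA_real_,
       recall = if (n_r > 0) matched / n_r else NA_real_,
       n_matched = matched)
}

#' Calibrate the arousal threshold on a tuning split
#'
#' Scans a threshold grid and returns the value maximizing the mean
#' event-level F1 against ground truth across the tuning nights. The
#' detection threshold is a free parameter of the scoring rule; it is
#' chosen once on tuning data, never on test data.
#'
#' @param model trained model.
#' @param nights list of `rip_night` objects (tuning split).
#' @param grid candidate thresholds.
#' @param windows optional precomputed list of `rip_windows` matching
#'   `nights` (avoids re-preprocessing).
#' @return list: threshold, grid results tibble.
#' @export
calibrate_threshold <- function(model, nights, grid = seq(0.2, 0.8, 0.05),
                                windows = NULL) {
  preds <- lapply(seq_along(nights), function(i) {
    src <- if (!is.null(windows)) windows[[i]] else
      preprocess_recording(nights[[i]]$recording)
    predict_recording(model, src)
  })
  res <- purrr::map_dfr(grid, function(th) {
    f1 <- vapply(seq_along(nights), function(i) {
      ev <- detect_arousals(preds[[i]], th)
      event_f1(nights[[i]]$truth$arousals, ev)$f1
    }, numeric(1))
    tibble(threshold = th, mean_f1 = mean(f1, na.rm = TRUE))
  })
  list(threshold = res$threshold[which.max(res$mean_f1)], results = res)
}
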