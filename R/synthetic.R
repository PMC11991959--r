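#' Configuration for the synthetic overnight RIP generator
#'
#' Defines the study conditions for simulated two-belt respiratory
#' inductance plethysmography (RIP) nights: sleep macro-structure,
#' event rates, breathing variability per state, the REM "paradoxical
#' breathing" contrast between thorax and abdomen, the ventilatory
#' response to arousal (VRA), baseline drift, and sensor noise.
#'
#' Defaults emulate an adult clinical population: a target
#' apnea-hypopnea index (AHI) of 15 events/hour sits mid-range of the
#' severity spectrum seen in sleep clinics (cohort means near 27 +/- 25
#' events/hour), an arousal index of 20 events/hour, and roughly half
#' of arousals linked to a preceding respiratory event.
#'
#' @param duration_hours recording length in hours.
#' @param sample_rate output sampling rate, Hz.
#' @param seed integer; together with the config it fully determines
#'   every generated sample (bit-identical reruns).
#' @param target_ahi respiratory events per hour of sleep.
#' @param arousal_rate arousals per hour of sleep.
#' @param linked_arousal_fraction fraction of arousals whose onset
#'   falls within 15 s after a respiratory event's end.
#' @param state_dwell per-state list of `c(mean, min)` bout durations in
#'   seconds; dwell is `min` plus an exponential with mean `mean - min`
#'   (a semi-Markov process producing bouts rather than epoch-wise noise).
#' @param transition embedded-chain transition matrix (rows WAKE, NREM,
#'   REM; zero diagonal).
#' @param amp_cv per-state coefficient of variation of breath amplitude:
#'   low in NREM (monotonous metabolic breathing), elevated in REM,
#'   highest in WAKE (volitional overwrite: sighs, movements).
#' @param rem_paradox_factor in `[0, 1]`; scales the REM thorax gain as
#'   `1 - 2 * factor`, so 0 leaves thorax in phase with abdomen and 1
#'   fully phase-opposes it (chest wall caving in during inspiration).
#' @param vra_gain multiplicative breath-amplitude increase (> 1) during
#'   the ~10 s following an arousal onset, with shortened inspiratory
#'   time: the gasp-like ventilatory response to arousal.
#' @param noise_sd Gaussian sensor noise SD as a fraction of unit breath
#'   amplitude.
#' @param drift_amplitude slow (< 0.02 Hz) baseline-drift amplitude as a
#'   fraction of unit breath amplitude.
#' @param hypopnea_reduction fractional amplitude reduction during
#'   hypopneas (apneas are near-total).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(duration_hours = 8, sample_rate = 25, seed = 1L,
                         target_ahi = 15, arousal_rate = 20,
                         linked_arousal_fraction = 0.5,
                         state_dwell = list(
                           WAKE = c(mean = 180, min = 30),
                           NREM = c(mean = 1140, min = 300),
                           REM  = c(mean = 600, min = 120)
                         ),
                         transition = rbind(
                           WAKE = c(0, 0.95, 0.05),
                           NREM = c(0.45, 0, 0.55),
                           REM  = c(0.30, 0.70, 0)
                         ),
                         amp_cv = c(WAKE = 0.35, NREM = 0.04, REM = 0.20),
                         rem_paradox_factor = 0.7,
                         vra_gain = 1.8,
                         noise_sd = 0.05,
                         drift_amplitude = 0.3,
                         hypopnea_reduction = 0.7) {
  if (!is.numeric(duration_hours) || duration_hours <= 0) {
    abort("duration_hours must be positive")
  }
  if (sample_rate <= 0) abort("sample_rate must be positive")
  if (target_ahi < 0) abort("target_ahi must be non-negative")
  if (arousal_rate < 0) abort("arousal_rate must be non-negative")
  if (rem_paradox_factor < 0 || rem_paradox_factor > 1) {
    abort("rem_paradox_factor must lie in [0, 1]")
  }
  if (vra_gain <= 1) abort("vra_gain must exceed 1")
  stopifnot(all(dim(transition) == c(3, 3)), all(diag(transition) == 0),
            all(abs(rowSums(transition) - 1) < 1e-9))
  structure(
    list(duration_hours = duration_hours, sample_rate = sample_rate,
         seed = as.integer(seed), target_ahi = target_ahi,
         arousal_rate = arousal_rate,
         linked_arousal_fraction = linked_arousal_fraction,
         state_dwell = state_dwell, transition = transition,
         amp_cv = amp_cv, rem_paradox_factor = rem_paradox_factor,
         vra_gain = vra_gain, noise_sd = noise_sd,
         drift_amplitude = drift_amplitude,
         hypopnea_reduction = hypopnea_reduction),
    class = "synth_config"
  )
}

# Sample one semi-Markov bout duration, in whole epochs (>= 1).
sample_dwell_epochs <- function(dwell) {
  secs <- dwell[["min"]] + rexp(1, 1 / max(dwell[["mean"]] - dwell[["min"]], 1))
  max(1L, as.integer(round(secs / 30)))
}

#' Generate a synthetic hypnogram
#'
#' Simulates overnight sleep macro-structure as a semi-Markov process
#' over WAKE/NREM/REM: state bouts with exponential-above-minimum dwell
#' and an embedded transition chain with no self-transitions. The night
#' begins with a WAKE bout (sleep latency) and is forced to end in WAKE.
#'
#' @param config a [synth_config()].
#' @return a [hypnogram()] with `duration_hours * 120` epochs.
#' @export
generate_hypnogram <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_epochs <- as.integer(round(config$duration_hours * 3600 / 30))
  if (n_epochs < 1) abort("duration too short for a single epoch")
  with_seed(config$seed, {
    states <- integer(0)
    cur <- 1L  # begin in WAKE
    while (length(states) < n_epochs) {
      d <- sample_dwell_epochs(config$state_dwell[[sleep_states[cur]]])
      states <- c(states, rep(cur, d))
      cur <- sample.int(3L, 1L, prob = config$transition[cur, ])
    }
    states <- states[seq_len(n_epochs)]
    # force a terminal WAKE epoch pair (lights-on)
    tail_n <- min(2L, n_epochs)
    states[(n_epochs - tail_n + 1L):n_epochs] <- 1L
    hypnogram(sleep_states[states])
  })
}

# Maximal runs of sleep (NREM/REM) epochs as second intervals [start, end).
sleep_runs <- function(hyp) {
  st <- hypnogram_states_chr(hyp)
  asleep <- st %in% c("NREM", "REM")
  r <- rle(asleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = (starts[keep] - 1L) * 30, end = ends[keep] * 30)
}

epoch_of <- function(t) as.integer(floor(t / 30))

#' Plant arousal and respiratory events on a hypnogram
#'
#' Places apnea/hypopnea events (durations 10-25 s) only within sleep
#' spans at a rate targeting `config$target_ahi`, then places arousals
#' at `config$arousal_rate`: a configurable fraction with onset within
#' 15 s after a respiratory event's end (respiratory-linked), the rest
#' spontaneous (no respiratory event in the 15 s look-back window).
#' Arousal onsets never fall in WAKE epochs; no events overlap.
#'
#' @param hyp a hypnogram.
#' @param config a [synth_config()].
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return list with `arousals` and `respiratory_events` tibbles plus a
#'   `best_effort` flag set when the target AHI could not be met in the
#'   available sleep time (a warning is also emitted).
#' @export
plant_events <- function(hyp, config, seed = config$seed + 1L) {
  hyp <- as_hypnogram(hyp)
  runs <- sleep_runs(hyp)
  total_s <- nrow(hyp) * 30
  sleep_s <- sum(runs$end - runs$start)
  sleep_h <- sleep_s / 3600
  with_seed(seed, {
    resp <- events_table()
    best_effort <- FALSE
    n_resp <- round(config$target_ahi * sleep_h)
    if (n_resp > 0 && sleep_s > 0) {
      onsets <- durs <- numeric(0)
      attempts <- 0L
      while (length(onsets) < n_resp && attempts < 80L * n_resp) {
        attempts <- attempts + 1L
        run <- runs[sample.int(nrow(runs), 1L,
                               prob = runs$end - runs$start), ]
        dur <- runif(1, 10, 25)
        if (run$end - run$start < dur + 2) next
        on <- runif(1, run$start, run$end - dur)
        # keep a >= 5 s gap between respiratory events
        if (any(on < onsets + durs + 5 & onsets < on + dur + 5)) next
        onsets <- c(onsets, on); durs <- c(durs, dur)
      }
      if (length(onsets) < n_resp) {
        warn(sprintf(
          "target AHI %.1f unattainable in %.2f h of sleep; planted %d/%d events",
          config$target_ahi, sleep_h, length(onsets), n_resp))
        best_effort <- TRUE
      }
      type <- ifelse(runif(length(onsets)) < 0.3, "apnea", "hypopnea")
      resp <- events_table(onsets, durs, type)
    }

    n_ar <- round(config$arousal_rate * sleep_h)
    ar_on <- ar_dur <- numeric(0); ar_link <- logical(0)
    if (n_ar > 0 && sleep_s > 0) {
      n_linked <- round(config$linked_arousal_fraction * n_ar)
      st <- hypnogram_states_chr(hyp)
      ok_onset <- function(on, dur) {
        if (on < 0 || on + dur > total_s) return(FALSE)
        if (!st[epoch_of(on) + 1L] %in% c("NREM", "REM")) return(FALSE)
        !any(on < ar_on + ar_dur + 1 & ar_on < on + dur + 1)
      }
      resp_ends <- resp$onset + resp$duration
      # linked arousals: onset shortly after a respiratory event's end
      attempts <- 0L
      while (sum(ar_link) < n_linked && nrow(resp) > 0 &&
             attempts < 80L * n_linked) {
        attempts <- attempts + 1L
        e <- sample.int(nrow(resp), 1L)
        on <- resp_ends[e] + runif(1, 0.5, 10)
        dur <- runif(1, 3, 12)
        if (!ok_onset(on, dur)) next
        ar_on <- c(ar_on, on); ar_dur <- c(ar_dur, dur)
        ar_link <- c(ar_link, TRUE)
      }
      # spontaneous arousals: nothing respiratory in the 15-s look-back
      attempts <- 0L
      while (length(ar_on) < n_ar && attempts < 200L * n_ar) {
        attempts <- attempts + 1L
        run <- runs[sample.int(nrow(runs), 1L,
                               prob = runs$end - runs$start), ]
        on <- runif(1, run$start, run$end)
        dur <- runif(1, 3, 12)
        if (!ok_onset(on, dur)) next
        if (nrow(resp) > 0 &&
            any(resp$onset < on & resp_ends > on - 15)) next
        ar_on <- c(ar_on, on); ar_dur <- c(ar_dur, dur)
        ar_link <- c(ar_link, FALSE)
      }
    }
    ord <- order(ar_on)
    list(
      arousals = events_table(ar_on[ord], ar_dur[ord], "arousal",
                              ar_link[ord]),
      respiratory_events = resp,
      best_effort = best_effort
    )
  })
}

# State-dependent per-breath parameter draws for one contiguous segment.
draw_breaths <- function(state, seg_start, seg_end, cfg) {
  len <- seg_end - seg_start
  base_period <- switch(state, WAKE = 4.2, NREM = 4.0, REM = 3.8)
  period_sd <- switch(state, WAKE = 0.9, NREM = 0.15, REM = 0.55)
  n_max <- ceiling(len / 1.8) + 3L
  periods <- pmax(1.8, rnorm(n_max, base_period, period_sd))
  amp <- pmax(0.1, 1 + rnorm(n_max, 0, cfg$amp_cv[[state]]))
  if (state == "WAKE") {
    sigh <- runif(n_max) < 0.04
    amp[sigh] <- amp[sigh] * 2.5
    hold <- runif(n_max) < 0.03
    periods[hold] <- runif(sum(hold), 8, 12)
    amp[hold] <- amp[hold] * 0.2
  }
  insp <- pmin(0.55, pmax(0.28,
    rnorm(n_max, 0.42, switch(state, WAKE = 0.06, NREM = 0.02, REM = 0.05))))
  starts <- seg_start + c(0, cumsum(periods[-n_max]))
  keep <- starts < seg_end
  tibble(start = starts[keep], period = periods[keep], amp = amp[keep],
         insp = insp[keep], state = state)
}

#' Synthesize a two-belt RIP signal from ground truth
#'
#' Renders breathing from a hypnogram plus planted events: regular
#' breathing in NREM (low breath-to-breath amplitude variability),
#' variable amplitude/timing in REM with the thorax gain scaled by
#' `1 - 2 * rem_paradox_factor` (paradoxical chest motion), irregular
#' breathing with sighs, breath-holds and movement bursts in WAKE. Each
#' arousal imprints a ventilatory response (amplitude times `vra_gain`
#' for ~10 s, decaying over the next 10 s, with shortened inspiration);
#' respiratory events attenuate both belts (hypopnea by
#' `hypopnea_reduction`, apnea near-totally). Slow sinusoidal baseline
#' drift and white sensor noise are added per channel.
#'
#' @param hyp hypnogram; @param arousals,resp_events event tibbles;
#' @param config a [synth_config()]; @param seed RNG seed (default
#'   `config$seed + 2`).
#' @return a [rip_recording()] at `config$sample_rate`.
#' @export
synthesize_breathing <- function(hyp, arousals, resp_events, config,
                                 seed = config$seed + 2L) {
  hyp <- as_hypnogram(hyp)
  check_no_overlap(resp_events, "respiratory events")
  total_s <- nrow(hyp) * 30
  ev_all <- dplyr::bind_rows(arousals, resp_events)
  if (nrow(ev_all) > 0 &&
      any(ev_all$onset < 0 | ev_all$onset + ev_all$duration > total_s)) {
    abort("events must lie within the recording span")
  }
  fs <- config$sample_rate
  n <- as.integer(round(total_s * fs))
  st <- hypnogram_states_chr(hyp)

  with_seed(seed, {
    # breath train per contiguous state segment
    r <- rle(st)
    seg_end_ep <- cumsum(r$lengths)
    seg_start_ep <- seg_end_ep - r$lengths
    breaths <- vector("list", length(r$values))
    t0 <- 0
    for (i in seq_along(r$values)) {
      seg_end <- seg_end_ep[i] * 30
      if (t0 >= seg_end) { breaths[[i]] <- NULL; next }
      b <- draw_breaths(r$values[i], t0, seg_end, config)
      breaths[[i]] <- b
      if (nrow(b) > 0) t0 <- b$start[nrow(b)] + b$period[nrow(b)]
    }
    br <- dplyr::bind_rows(breaths)

    # ventilatory response to arousal: boost then linear decay
    if (nrow(arousals) > 0) {
      for (j in seq_len(nrow(arousals))) {
        on <- arousals$onset[j]
        dt <- br$start - on
        boost <- dt >= 0 & dt < 10
        decay <- dt >= 10 & dt < 20
        g <- config$vra_gain
        br$amp[boost] <- br$amp[boost] * g
        br$amp[decay] <- br$amp[decay] * (1 + (g - 1) * (20 - dt[decay]) / 10)
        br$insp[boost] <- br$insp[boost] * 0.7
      }
    }
    # respiratory events attenuate breaths they cover
    if (nrow(resp_events) > 0) {
      for (j in seq_len(nrow(resp_events))) {
        on <- resp_events$onset[j]; en <- on + resp_events$duration[j]
        hit <- br$start >= on - 1 & br$start < en
        fac <- if (resp_events$type[j] == "apnea") 0.05 else
          (1 - config$hypopnea_reduction)
        br$amp[hit] <- br$amp[hit] * fac
      }
    }

    # per-breath thorax gain: REM paradox, mild jitter elsewhere
    g_th <- ifelse(br$state == "REM",
                   (1 - 2 * config$rem_paradox_factor),
                   0.95) * (1 + rnorm(nrow(br), 0, 0.05))
    ph2 <- runif(nrow(br), 0, 2 * pi)   # second-harmonic phase per breath
    a2 <- runif(nrow(br), 0.03, 0.10)

    # render: piecewise-cosine breath template plus a small 2nd harmonic
    tt <- (seq_len(n) - 1) / fs
    bi <- findInterval(tt, br$start)
    bi[bi == 0L] <- 1L
    u <- (tt - br$start[bi]) / br$period[bi]
    u <- pmin(pmax(u, 0), 1)
    insp <- br$insp[bi]
    v <- ifelse(u <= insp,
                0.5 - 0.5 * cos(pi * u / insp),
                0.5 + 0.5 * cos(pi * (u - insp) / (1 - insp)))
    v <- v - 0.5 + a2[bi] * sin(4 * pi * u + ph2[bi])
    abdomen <- br$amp[bi] * v
    thorax <- g_th[bi] * br$amp[bi] * v

    # WAKE movement bursts: band-limited high-amplitude transients
    wake_segs <- which(r$values == "WAKE")
    for (i in wake_segs) {
      s0 <- seg_start_ep[i] * 30; s1 <- seg_end_ep[i] * 30
      n_burst <- rpois(1, (s1 - s0) / 120)
      if (n_burst == 0) next
      for (b in seq_len(n_burst)) {
        dur <- runif(1, 2, 6)
        c0 <- runif(1, s0, max(s0, s1 - dur))
        i0 <- max(1L, as.integer(c0 * fs)); i1 <- min(n, as.integer((c0 + dur) * fs))
        if (i1 <= i0 + 4) next
        m <- i1 - i0 + 1L
        smooth_noise <- function(m) {
          x <- as.numeric(stats::filter(rnorm(m), rep(1 / 5, 5), sides = 2))
          x[is.na(x)] <- 0
          x
        }
        burst <- smooth_noise(m)
        w <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / m)
        amp_b <- runif(1, 3, 6)
        abdomen[i0:i1] <- abdomen[i0:i1] + amp_b * w * burst
        thorax[i0:i1] <- thorax[i0:i1] +
          amp_b * w * (0.7 * burst + 0.3 * smooth_noise(m))
      }
    }

    # slow drift + sensor noise, independent per channel
    drift1 <- config$drift_amplitude *
      (sin(2 * pi * runif(1, 0.004, 0.012) * tt + runif(1, 0, 2 * pi)) +
         0.6 * sin(2 * pi * runif(1, 0.012, 0.02) * tt + runif(1, 0, 2 * pi)))
    drift2 <- config$drift_amplitude *
      (sin(2 * pi * runif(1, 0.004, 0.012) * tt + runif(1, 0, 2 * pi)) +
         0.6 * sin(2 * pi * runif(1, 0.012, 0.02) * tt + runif(1, 0, 2 * pi)))
    scale <- runif(1, 8, 12)  # arbitrary inductance units
    thorax <- scale * (thorax + drift1 + rnorm(n, 0, config$noise_sd))
    abdomen <- scale * (abdomen + drift2 + rnorm(n, 0, config$noise_sd))
    rip_recording(thorax, abdomen, sample_rate = fs)
  })
}

#' Simulate one full synthetic night
#'
#' Chains [generate_hypnogram()], [plant_events()] and
#' [synthesize_breathing()] under one seed.
#'
#' @param config a [synth_config()].
#' @return list of class `rip_night`: `recording`, `truth` (hypnogram,
#'   arousals, respiratory_events, ahi, ari, plmsi, best_effort).
#' @export
generate_night <- function(config) {
  hyp <- generate_hypnogram(config)
  ev <- plant_events(hyp, config)
  rec <- synthesize_breathing(hyp, ev$arousals, ev$respiratory_events, config)
  tst_h <- compute_tst(hyp) / 60
  structure(list(
    recording = rec,
    truth = list(
      hypnogram = hyp,
      arousals = ev$arousals,
      respiratory_events = ev$respiratory_events,
      ahi = if (tst_h > 0) nrow(ev$respiratory_events) / tst_h else 0,
      ari = if (tst_h > 0) nrow(ev$arousals) / tst_h else 0,
      plmsi = 0,
      best_effort = ev$best_effort
    ),
    config = config
  ), class = "rip_night")
}

#' Generate a synthetic cohort spanning all AHI severity bins
#'
#' Produces `n` independently seeded nights. The default config sampler
#' cycles target AHI through the four severity bins (normal < 5, mild
#' 5-15, moderate 15-30, severe >= 30) so stratified evaluation has
#' non-empty groups.
#'
#' @param n number of subjects (>= 1).
#' @param master_seed base seed; subject `i` uses `master_seed + 1000*i`.
#' @param config_sampler function(i, seed) returning a [synth_config()];
#'   defaults to the severity-cycling sampler.
#' @return list of `rip_night` objects.
#' @export
generate_cohort <- function(n, master_seed = 1L, config_sampler = NULL) {
  if (!is.numeric(n) || n < 1) abort("cohort size n must be >= 1")
  n <- as.integer(n)
  if (is.null(config_sampler)) {
    bins <- c(2, 10, 22, 45)
    config_sampler <- function(i, seed) {
      ahi <- with_seed(seed, bins[(i - 1L) %% 4L + 1L] * runif(1, 0.7, 1.3))
      synth_config(duration_hours = 8, seed = seed, target_ahi = ahi,
                   arousal_rate = with_seed(seed + 1L, runif(1, 10, 35)))
    }
  }
  lapply(seq_len(n), function(i) {
    generate_night(config_sampler(i, as.integer(master_seed + 1000L * i)))
  })
}

#' Per-epoch descriptive breathing features
#'
#' Simple features used for sanity checks of the generated physiology:
#' per-epoch breath-amplitude coefficient of variation (via peak
#' detection on the abdomen belt), thorax-abdomen correlation, and
#' signal RMS. These are the hand-crafted quantities a rule-based
#' discriminant would use to separate states.
#'
#' @param rec a [rip_recording()] (baseline-removed or raw).
#' @return tibble: epoch, amp_cv, cor_ta, rms.
#' @export
epoch_features <- function(rec) {
  fs <- rec$sample_rate
  spe <- as.integer(30 * fs)
  n_ep <- floor(length(rec$abdomen) / spe)
  purrr::map_dfr(seq_len(n_ep), function(e) {
    idx <- ((e - 1L) * spe + 1L):(e * spe)
    a <- rec$abdomen[idx]; t <- rec$thorax[idx]
    pk <- find_breath_peaks(a, fs)
    amps <- a[pk]
    tibble(
      epoch = e - 1L,
      amp_cv = if (length(amps) >= 3 && mean(abs(amps)) > 0)
        sd(amps) / max(mean(abs(amps)), 1e-12) else NA_real_,
      cor_ta = suppressWarnings(cor(t, a)),
      rms = sqrt(mean(a^2))
    )
  })
}

# Local-maximum breath-peak finder with a minimum 1.8-s spacing.
find_breath_peaks <- function(x, fs, min_dist_s = 1.8) {
  n <- length(x)
  if (n < 5) return(integer(0))
  is_pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(is_pk) == 0) return(integer(0))
  # keep inspiratory crests only: noise bumps in the troughs sit far
  # below a fraction of the typical crest height
  thr <- 0.25 * stats::quantile(x[is_pk], 0.95)
  is_pk <- is_pk[x[is_pk] > thr]
  # greedy non-maximum suppression: keep strongest peaks >= min_dist apart
  out <- integer(0)
  for (p in is_pk[order(x[is_pk], decreasing = TRUE)]) {
    if (length(out) == 0 || all(abs(out - p) >= min_dist_s * fs)) {
      out <- c(out, p)
    }
  }
  sort(out)
}
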