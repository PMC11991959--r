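# Independent oracle implementations used to verify package operations.
# These are written naively (loops, direct formulas) on purpose: they
# share no code with the implementation paths they check.

# FFT amplitude of a tone at frequency f in a signal sampled at fs
fft_amplitude <- function(x, f, fs) {
  n <- length(x)
  2 * abs(stats::fft(x)[round(f * n / fs) + 1]) / n
}

# brute-force enumeration of maximal supra-threshold runs >= min_dur
oracle_detect_runs <- function(probs, threshold, min_dur = 3) {
  onsets <- durs <- integer(0)
  i <- 1
  n <- length(probs)
  while (i <= n) {
    if (probs[i] > threshold) {
      j <- i
      while (j < n && probs[j + 1] > threshold) j <- j + 1
      if (j - i + 1 >= min_dur) {
        onsets <- c(onsets, i - 1L)
        durs <- c(durs, j - i + 1L)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  data.frame(onset = onsets, duration = durs)
}

# naive semi-Markov night simulator: independent re-implementation of
# the generative process (embedded chain + exponential-above-minimum
# dwell, WAKE start, forced WAKE tail)
oracle_semi_markov_night <- function(n_epochs, dwell, trans) {
  states <- integer(0)
  cur <- 1L
  while (length(states) < n_epochs) {
    d <- dwell[[cur]]
    secs <- d[["min"]] + rexp(1, 1 / max(d[["mean"]] - d[["min"]], 1))
    states <- c(states, rep(cur, max(1L, as.integer(round(secs / 30)))))
    cur <- sample.int(3L, 1L, prob = trans[cur, ])
  }
  states <- states[seq_len(n_epochs)]
  states[max(1, n_epochs - 1):n_epochs] <- 1L
  states
}

# analytic stationary time fractions of the semi-Markov process
oracle_stationary_fractions <- function(dwell, trans) {
  ev <- eigen(t(trans))
  p <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  p <- p / sum(p)
  means <- vapply(dwell, function(d) d[["mean"]], numeric(1))
  tf <- p * means
  tf / sum(tf)
}

# direct-formula Cohen's kappa (longhand)
oracle_kappa <- function(cm) {
  n <- sum(cm)
  po <- 0
  for (i in seq_len(nrow(cm))) po <- po + cm[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(cm))) pe <- pe + sum(cm[i, ]) * sum(cm[, i])
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

# ICC(2,1) from a textbook two-way ANOVA table via stats::aov
oracle_icc_aov <- function(ref, pred) {
  n <- length(ref)
  df <- data.frame(
    y = c(ref, pred),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("ref", "pred"), each = n))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# make a tiny deterministic annotated window set for model tests
tiny_window_set <- function(seed = 7, hours = 0.5, ahi = 20,
                            arousal_rate = 25) {
  night <- generate_night(synth_config(duration_hours = hours, seed = seed,
                                       target_ahi = ahi,
                                       arousal_rate = arousal_rate))
  rec <- preprocess_recording(night$recording)
  list(night = night,
       ws = assemble_windows(rec, night$truth$hypnogram,
                             night$truth$arousals))
}
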