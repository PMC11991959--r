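test_that("generation is deterministic and epoch counts are exact", {
  cfg <- synth_config(duration_hours = 8, seed = 11)
  h1 <- generate_hypnogram(cfg)
  h2 <- generate_hypnogram(cfg)
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 960)  # 8 * 3600 / 30
  expect_equal(as.character(h1$state[1]), "WAKE")
  expect_equal(as.character(h1$state[nrow(h1)]), "WAKE")

  cfg_s <- synth_config(duration_hours = 0.5, seed = 11)
  n1 <- generate_night(cfg_s)
  n2 <- generate_night(cfg_s)
  expect_identical(n1$recording$thorax, n2$recording$thorax)
  expect_identical(n1$truth$arousals, n2$truth$arousals)
  n3 <- generate_night(synth_config(duration_hours = 0.5, seed = 12))
  expect_false(identical(n1$recording$thorax, n3$recording$thorax))
})

test_that("invalid generator configs are rejected", {
  expect_error(synth_config(duration_hours = 0), "positive")
  expect_error(synth_config(duration_hours = -1), "positive")
  expect_error(synth_config(target_ahi = -2), "non-negative")
  expect_error(synth_config(vra_gain = 0.9), "exceed 1")
  expect_error(synth_config(rem_paradox_factor = 1.5), "0, 1")
})

test_that("REM fraction matches an independent semi-Markov simulation", {
  cfg <- synth_config(duration_hours = 8, seed = 1)
  n_nights <- 1000
  frac_pkg <- vapply(seq_len(n_nights), function(i) {
    h <- generate_hypnogram(synth_config(duration_hours = 8, seed = 5000 + i))
    mean(h$state == "REM")
  }, numeric(1))
  set.seed(99)
  frac_orc <- vapply(seq_len(n_nights), function(i) {
    mean(oracle_semi_markov_night(960, cfg$state_dwell, cfg$transition) == 3L)
  }, numeric(1))
  se <- sqrt(var(frac_pkg) / n_nights + var(frac_orc) / n_nights)
  expect_lt(abs(mean(frac_pkg) - mean(frac_orc)), 3 * se)
  # and the analytic stationary fraction is in the right neighbourhood
  # (finite-night truncation and the forced WAKE edges bias it slightly)
  target <- oracle_stationary_fractions(cfg$state_dwell, cfg$transition)[3]
  expect_lt(abs(mean(frac_pkg) - target), 0.03)
})

test_that("event planting respects rates, placement and the 15-s linkage", {
  cfg0 <- synth_config(duration_hours = 2, seed = 5, target_ahi = 0)
  hyp <- generate_hypnogram(cfg0)
  ev0 <- plant_events(hyp, cfg0)
  expect_equal(nrow(ev0$respiratory_events), 0)

  cfg1 <- synth_config(duration_hours = 8, seed = 6, target_ahi = 30,
                       arousal_rate = 20, linked_arousal_fraction = 1)
  hyp1 <- generate_hypnogram(cfg1)
  ev1 <- plant_events(hyp1, cfg1)
  sleep_h <- compute_tst(hyp1) / 60
  n_target <- 30 * sleep_h
  expect_lt(abs(nrow(ev1$respiratory_events) - n_target) / n_target, 0.10)
  # every arousal linked under linked fraction 1 (15-s look-back rule)
  cls <- classify_respiratory_arousals(ev1$arousals, ev1$respiratory_events)
  expect_equal(cls$linked_fraction, 1)

  # no arousal onsets in WAKE epochs; all events in bounds; durations valid
  st <- as.character(hyp1$state)
  on_ep <- floor(ev1$arousals$onset / 30) + 1
  expect_true(all(st[on_ep] %in% c("NREM", "REM")))
  expect_true(all(ev1$arousals$duration >= 3))
  expect_true(all(ev1$respiratory_events$duration >= 10))
  all_ev <- rbind(ev1$arousals, ev1$respiratory_events)
  expect_true(all(all_ev$onset >= 0 &
                    all_ev$onset + all_ev$duration <= nrow(hyp1) * 30))

  # arousal bookkeeping: ground-truth ArI within 10% of the planted rate
  ari <- 60 * nrow(ev1$arousals) / compute_tst(hyp1)
  expect_lt(abs(ari - 20) / 20, 0.10)
})

test_that("unattainable AHI warns and flags best effort", {
  cfg <- synth_config(duration_hours = 0.5, seed = 2, target_ahi = 300)
  hyp <- generate_hypnogram(cfg)
  expect_warning(ev <- plant_events(hyp, cfg), "unattainable")
  expect_true(ev$best_effort)
})

test_that("NREM breathing is monotonous: low per-breath amplitude CV", {
  cfg <- synth_config(duration_hours = 1, seed = 3, noise_sd = 0.03)
  hyp <- hypnogram(rep("NREM", 120))
  rec <- synthesize_breathing(hyp, events_table(), events_table(), cfg)
  rec <- remove_baseline(rec)
  pk <- ripsleep:::find_breath_peaks(rec$abdomen, rec$sample_rate)
  amps <- rec$abdomen[pk]
  # generated with 4% amplitude jitter; 15% allows peak-measurement noise
  expect_lt(sd(amps) / mean(amps), 0.15)
})

test_that("arousals imprint a ventilatory response (VRA)", {
  cfg <- synth_config(duration_hours = 0.25, seed = 8, noise_sd = 0.03)
  hyp <- hypnogram(rep("NREM", 30))
  ar <- events_table(600, 8, "arousal")
  rec <- synthesize_breathing(hyp, ar, events_table(), cfg)
  x <- remove_baseline(rec)$abdomen
  fs <- cfg$sample_rate
  pk <- find_breath_peaks(x, fs)
  t_pk <- pk / fs
  amp_post <- mean(x[pk[t_pk > 600 & t_pk < 615]])
  amp_pre <- mean(x[pk[t_pk > 570 & t_pk < 600]])
  expect_gte(amp_post / amp_pre, cfg$vra_gain * 0.8)
})

test_that("full REM paradox phase-opposes the belts", {
  cfg <- synth_config(duration_hours = 0.25, seed = 9,
                      rem_paradox_factor = 1)
  hyp <- hypnogram(rep("REM", 30))
  rec <- synthesize_breathing(hyp, events_table(), events_table(), cfg)
  expect_lt(cor(rec$thorax, rec$abdomen), 0)
})

test_that("overlapping respiratory events are rejected", {
  cfg <- synth_config(duration_hours = 0.25, seed = 1)
  hyp <- hypnogram(rep("NREM", 30))
  bad <- events_table(c(100, 105), c(15, 15), "apnea")
  expect_error(
    synthesize_breathing(hyp, events_table(), bad, cfg), "overlap")
  outside <- events_table(890, 20, "apnea")
  expect_error(
    synthesize_breathing(hyp, events_table(), outside, cfg), "within")
})

test_that("cohorts span all four AHI severity bins deterministically", {
  co <- generate_cohort(4, master_seed = 3,
                        config_sampler = function(i, seed) {
                          synth_config(duration_hours = 1, seed = seed,
                                       target_ahi = c(2, 10, 22, 45)[i])
                        })
  sev <- ahi_severity(vapply(co, function(n) n$truth$ahi, numeric(1)))
  expect_setequal(as.character(sev),
                  c("normal", "mild", "moderate", "severe"))
  expect_error(generate_cohort(0), ">= 1")
  co2 <- generate_cohort(2, master_seed = 3,
                         config_sampler = function(i, seed) {
                           synth_config(duration_hours = 0.5, seed = seed)
                         })
  co3 <- generate_cohort(2, master_seed = 3,
                         config_sampler = function(i, seed) {
                           synth_config(duration_hours = 0.5, seed = seed)
                         })
  expect_identical(co2[[1]]$recording$abdomen, co3[[1]]$recording$abdomen)
})

test_that("a hand-coded discriminant separates the three states", {
  # breath-amplitude CV + thorax/abdomen correlation per epoch must be
  # enough to stage generated data well above chance: the learning task
  # is solvable by construction
  nights <- lapply(c(21, 22, 23), function(s) {
    generate_night(synth_config(duration_hours = 2, seed = s))
  })
  acc <- vapply(nights, function(n) {
    rec <- remove_baseline(n$recording)
    f <- epoch_features(rec)
    truth <- as.character(n$truth$hypnogram$state)[seq_len(nrow(f))]
    rms_med <- median(f$rms, na.rm = TRUE)
    # wake: erratic amplitudes at normal-or-high drive, or movement
    # bursts; REM: paradoxical (negative) belt correlation
    pred <- ifelse(
      is.na(f$amp_cv) | (f$amp_cv > 0.28 & f$rms > 1.1 * rms_med) |
        f$rms > 2 * rms_med, "WAKE",
      ifelse(f$cor_ta < 0.25, "REM", "NREM"))
    mean(pred == truth)
  }, numeric(1))
  expect_gt(mean(acc), 0.80)
})
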