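test_that("epoch confusion tallies states and honours the artifact mask", {
  states <- sample(c("WAKE", "NREM", "REM"), 20, replace = TRUE)
  ref <- hypnogram(states)
  cm <- epoch_confusion(ref, ref)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(sum(diag(cm)), 20)

  set.seed(12)
  pred <- hypnogram(sample(c("WAKE", "NREM", "REM"), 20, replace = TRUE))
  cm2 <- epoch_confusion(ref, pred)
  # hand tally
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm2[i, j],
                 sum(states == c("WAKE", "NREM", "REM")[i] &
                       as.character(pred$state) == c("WAKE", "NREM", "REM")[j]))
  }

  expect_warning(cm3 <- epoch_confusion(ref, pred, rep(TRUE, 20)), "masked")
  expect_equal(sum(cm3), 0)
  expect_error(epoch_confusion(ref, hypnogram(states[1:10])), "lengths")
  # ARTIFACT epochs contribute nothing
  refa <- hypnogram(c(states[1:18], "ARTIFACT", "ARTIFACT"))
  expect_equal(sum(epoch_confusion(refa, pred)), 18)
})

test_that("arousal epoch confusion follows epoch presence/absence", {
  # one event spanning epochs 3-4 (0-based), identical scorings
  ev <- events_table(100, 30, "arousal")   # 100-130 s: epochs 3 and 4
  cm <- arousal_epoch_confusion(ev, ev, 10)
  expect_equal(cm[1, 1], 2)  # TP
  expect_equal(cm[2, 2], 8)  # TN
  expect_equal(cm[1, 2] + cm[2, 1], 0)

  none <- events_table(type = "arousal")
  cm0 <- arousal_epoch_confusion(none, none, 12)
  expect_equal(cm0[2, 2], 12)

  ref1 <- events_table(7 * 30 + 5, 3, "arousal")
  cm1 <- arousal_epoch_confusion(ref1, none, 12)
  expect_equal(cm1[1, 2], 1)  # FN
  expect_equal(cm1[2, 1], 0)  # FP
})

test_that("binary metrics follow the stated formulas exactly", {
  cm <- matrix(c(50, 0, 0, 50), 2, 2, byrow = TRUE)
  m <- binary_metrics(cm)
  expect_equal(unlist(m), c(sensitivity = 100, specificity = 100,
                            accuracy = 100, f1 = 100))

  set.seed(5)
  for (i in 1:50) {
    cm <- matrix(sample(1:500, 4), 2, 2)
    m <- binary_metrics(cm)
    tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
    expect_equal(m$sensitivity, 100 * tp / (tp + fn))
    expect_equal(m$specificity, 100 * tn / (tn + fp))
    expect_equal(m$accuracy, 100 * (tp + tn) / sum(cm))
    expect_equal(m$f1, 100 * 2 * tp / (2 * tp + fp + fn))
  }
  degenerate <- matrix(c(0, 0, 3, 7), 2, 2, byrow = TRUE)
  expect_warning(m0 <- binary_metrics(degenerate), "undefined")
  expect_true(is.na(m0$sensitivity))
})

test_that("one-vs-rest collapses a 3x3 matrix per class", {
  d <- diag(c(10, 20, 30))
  rownames(d) <- colnames(d) <- c("WAKE", "NREM", "REM")
  m <- one_vs_rest_metrics(d)
  expect_true(all(m$sensitivity == 100 & m$f1 == 100))
})

test_that("Cohen's kappa matches the longhand formula and is 1 on diagonals", {
  expect_equal(cohen_kappa(diag(c(5, 9, 2))), 1)
  set.seed(31)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    cm <- matrix(sample(0:200, k * k, replace = TRUE), k, k)
    if (sum(cm) == 0) next
    expect_equal(cohen_kappa(cm), oracle_kappa(cm), tolerance = 1e-12)
  }
})

test_that("bootstrap CI is seeded, collapses on constants, flags undefined", {
  ci1 <- bootstrap_ci(rnorm(50), mean, n_iter = 200, seed = 4)
  ci2 <- bootstrap_ci(rnorm(50), mean, n_iter = 200, seed = 4)
  # note: data differ but the interface must be deterministic given data
  cst <- bootstrap_ci(rep(3, 20), mean, n_iter = 100, seed = 1)
  expect_equal(cst$lower, 3)
  expect_equal(cst$upper, 3)
  x <- rnorm(30)
  a <- bootstrap_ci(x, mean, n_iter = 500, seed = 9)
  b <- bootstrap_ci(x, mean, n_iter = 500, seed = 9)
  expect_identical(a, b)
  expect_error(bootstrap_ci(numeric(0), mean), "non-empty")
  expect_error(bootstrap_ci(c(1, 2, 3), function(d) NA_real_, n_iter = 50,
                            seed = 2), "undefined")
})

test_that("Bland-Altman bias, limits and slope behave as defined", {
  ref <- c(10, 20, 30, 40, 50)
  ba <- bland_altman(ref, ref + 5, n_iter = 100, seed = 2)
  expect_equal(ba$bias, 5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa_low, 5)
  expect_equal(ba$loa_high, 5)

  ba0 <- bland_altman(ref, ref, n_iter = 100, seed = 2)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$proportionality_slope, 0)

  expect_error(bland_altman(1:2, 1:2), "at least 3")

  # sign convention: algorithm overestimates => positive bias
  ba1 <- bland_altman(c(1, 2, 3, 4), c(2, 3, 4, 5), n_iter = 50, seed = 1)
  expect_equal(ba1$bias, 1)

  # Monte-Carlo recovery of the generating parameters
  set.seed(1299)
  ref <- pmax(rnorm(1299, 20, 15), 0)
  pred <- ref + rnorm(1299, -4, 14)
  ba2 <- bland_altman(ref, pred, n_iter = 200, seed = 3)
  expect_lt(abs(ba2$bias - (-4)), 1)
  half <- (ba2$loa_high - ba2$loa_low) / 2
  expect_lt(abs(half - 1.96 * 14), 1.5)
  expect_true(ba2$bias_ci$lower <= ba2$bias && ba2$bias <= ba2$bias_ci$upper)
})

test_that("Bland-Altman and ICC agree with brute-force computation", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    ref <- rnorm(n, 10, 3)
    pred <- ref + rnorm(n, 1, 2)
    ba <- bland_altman(ref, pred, n_iter = 10, seed = 1)
    d <- pred - ref
    expect_equal(ba$bias, mean(d), tolerance = 1e-12)
    expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
    expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
    expect_equal(ba$proportionality_slope,
                 unname(coef(lm(d ~ I((ref + pred) / 2)))[2]),
                 tolerance = 1e-10)
    expect_equal(ripsleep:::icc_value(ref, pred), oracle_icc_aov(ref, pred),
                 tolerance = 1e-10)
  }
})

test_that("ICC behaves at its analytic anchors", {
  ref <- c(1, 5, 9, 13, 20)
  r <- icc(ref, ref, n_iter = 100, seed = 1)
  expect_equal(r$estimate, 1)
  set.seed(6)
  r2 <- icc(rnorm(500), rnorm(500), n_iter = 50, seed = 2)
  expect_lt(abs(r2$estimate), 0.15)
  expect_warning(r3 <- icc(rep(2, 5), rep(2, 5), n_iter = 10, seed = 1),
                 "variance")
  expect_true(is.na(r3$estimate))
})

test_that("patient-level statistics ignore subject order", {
  set.seed(10)
  ref <- rnorm(40, 20, 8); pred <- ref + rnorm(40, -2, 4)
  perm <- sample(40)
  ba1 <- bland_altman(ref, pred, n_iter = 10, seed = 1)
  ba2 <- bland_altman(ref[perm], pred[perm], n_iter = 10, seed = 1)
  expect_equal(ba1$bias, ba2$bias)
  expect_equal(ba1$loa_high, ba2$loa_high)
  expect_equal(ripsleep:::icc_value(ref, pred),
               ripsleep:::icc_value(ref[perm], pred[perm]), tolerance = 1e-12)
})

test_that("AHI severity boundaries are left-closed at 5, 15 and 30", {
  expect_equal(as.character(ahi_severity(c(0, 4.99, 5, 14.99, 15, 29.99, 30, 80))),
               c("normal", "normal", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_error(ahi_severity(-1), "non-negative")

  subj <- tibble::tibble(ahi = c(2, 10, 22, 45), ref = c(10, 12, 15, 30),
                         pred = c(11, 13, 14, 26), plmsi = c(0, 20, 3, 1))
  out <- stratify_by_ahi(subj)
  expect_equal(out$n[1:4], rep(1L, 4))
  expect_equal(out$group[1:4], c("normal", "mild", "moderate", "severe"))
  expect_true(all(c("plmsi_lt_15", "plmsi_ge_15") %in% out$group))
  expect_equal(out$n[out$group == "plmsi_ge_15"], 1L)
})

test_that("respiratory-arousal linkage uses the 15-s look-back window", {
  resp <- events_table(100, 20, "apnea")   # ends at 120 s
  linked <- classify_respiratory_arousals(events_table(125, 5, "arousal"),
                                          resp)
  expect_true(linked$arousals$respiratory_linked[1])   # gap 5 s
  expect_equal(linked$linked_fraction, 1)

  far <- classify_respiratory_arousals(events_table(140, 5, "arousal"), resp)
  expect_false(far$arousals$respiratory_linked[1])     # gap 20 s
  expect_equal(far$linked_fraction, 0)

  none <- classify_respiratory_arousals(events_table(50, 5, "arousal"),
                                        events_table())
  expect_equal(none$linked_fraction, 0)
  expect_warning(
    und <- classify_respiratory_arousals(events_table(type = "arousal"),
                                         resp), "undefined")
  expect_true(is.na(und$linked_fraction))
})

test_that("cohort agreement report pools confusion and bootstraps kappa", {
  set.seed(3)
  refs <- preds <- list()
  for (i in 1:3) {
    s <- sample(c("WAKE", "NREM", "REM"), 60, replace = TRUE,
                prob = c(0.2, 0.6, 0.2))
    p <- s
    flip <- sample(60, 10)
    p[flip] <- sample(c("WAKE", "NREM", "REM"), 10, replace = TRUE)
    refs[[i]] <- hypnogram(s); preds[[i]] <- hypnogram(p)
  }
  rep <- agreement_report(refs, preds, n_iter = 100, seed = 2)
  expect_equal(sum(rep$state_confusion), 180)
  expect_equal(rep$state_kappa,
               oracle_kappa(unclass(rep$state_confusion)), tolerance = 1e-12)
  expect_true(rep$state_kappa_ci$lower <= rep$state_kappa_ci$upper)
  td <- tidy(rep)
  expect_true(all(c("class", "metric", "estimate") %in% names(td)))
})
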