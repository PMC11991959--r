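#' Epoch-level sleep-state confusion matrix
#'
#' Tallies reference (rows) against predicted (columns) epoch states
#' over WAKE/NREM/REM. Epochs flagged in `artifact_mask`, or labeled
#' ARTIFACT in either scoring, contribute nothing (they are excluded
#' from analysis).
#'
#' @param ref,pred hypnograms of equal length.
#' @param artifact_mask optional logical vector (TRUE = exclude).
#' @return 3x3 integer matrix of class `confusion_matrix`.
#' @export
epoch_confusion <- function(ref, pred, artifact_mask = NULL) {
  r <- hypnogram_states_chr(ref)
  p <- hypnogram_states_chr(pred)
  if (length(r) != length(p)) abort("hypnogram lengths differ")
  keep <- r %in% sleep_states & p %in% sleep_states
  if (!is.null(artifact_mask)) {
    stopifnot(length(artifact_mask) == length(r))
    keep <- keep & !artifact_mask
  }
  if (!any(keep)) warn("all epochs masked; confusion matrix is empty")
  m <- table(factor(r[keep], levels = sleep_states),
             factor(p[keep], levels = sleep_states))
  cm <- matrix(as.integer(m), 3, 3,
               dimnames = list(reference = sleep_states,
                               prediction = sleep_states))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Epoch-level arousal confusion matrix
#'
#' An epoch is arousal-positive for a scoring if any arousal of that
#' scoring overlaps it. Tallies a 2x2 matrix (rows: reference
#' Positive/Negative; columns: prediction).
#'
#' @param ref_events,pred_events arousal [events_table()]s.
#' @param n_epochs total scored epochs.
#' @param artifact_mask optional logical exclusion vector.
#' @return 2x2 `confusion_matrix`.
#' @export
arousal_epoch_confusion <- function(ref_events, pred_events, n_epochs,
                                    artifact_mask = NULL) {
  rp <- epochs_with_events(ref_events, n_epochs)
  pp <- epochs_with_events(pred_events, n_epochs)
  keep <- rep(TRUE, n_epochs)
  if (!is.null(artifact_mask)) keep <- !artifact_mask
  m <- table(factor(rp[keep], levels = c(TRUE, FALSE)),
             factor(pp[keep], levels = c(TRUE, FALSE)))
  cm <- matrix(as.integer(m), 2, 2,
               dimnames = list(reference = c("Positive", "Negative"),
                               prediction = c("Positive", "Negative")))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(matrix(as.vector(x), nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}

# logical vector: does any event overlap epoch e = [30e, 30e+30)?
epochs_with_events <- function(events, n_epochs) {
  out <- rep(FALSE, n_epochs)
  if (is.null(events) || nrow(events) == 0) return(out)
  for (j in seq_len(nrow(events))) {
    e0 <- max(0L, epoch_of(events$onset[j]))
    e1 <- min(n_epochs - 1L,
              epoch_of(events$onset[j] + events$duration[j] - 1e-9))
    if (e1 >= e0) out[(e0 + 1L):(e1 + 1L)] <- TRUE
  }
  out
}

#' Reconstruct a 2x2 confusion matrix from printed rates
#'
#' Given sensitivity and specificity (percent) and the class totals,
#' rebuilds the TP/FN/FP/TN counts (rounded to whole epochs). Used to
#' recompute accuracy, F1 and kappa from published summary tables.
#'
#' @param sensitivity,specificity percent values.
#' @param n_pos,n_neg reference positive/negative totals.
#' @return 2x2 `confusion_matrix`.
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  tp <- round(sensitivity / 100 * n_pos)
  tn <- round(specificity / 100 * n_neg)
  cm <- matrix(as.numeric(c(tp, n_pos - tp, n_neg - tn, tn)), 2, 2,
               dimnames = list(reference = c("Positive", "Negative"),
                               prediction = c("Positive", "Negative")))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Binary agreement metrics from a 2x2 confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and F1 `2TP/(2TP+FP+FN)`, reported in percent.
#' A zero denominator yields `NA` with a warning, never a silent 0.
#'
#' @param cm 2x2 matrix: rows reference (Positive, Negative), columns
#'   prediction.
#' @return tibble: sensitivity, specificity, accuracy, f1 (percent).
#' @export
binary_metrics <- function(cm) {
  stopifnot(all(dim(cm) == c(2, 2)))
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  safe <- function(num, den, what) {
    if (den <= 0) {
      warn(paste0(what, " undefined: zero denominator"))
      return(NA_real_)
    }
    100 * num / den
  }
  tibble(
    sensitivity = safe(tp, tp + fn, "sensitivity"),
    specificity = safe(tn, tn + fp, "specificity"),
    accuracy = safe(tp + tn, tp + tn + fp + fn, "accuracy"),
    f1 = safe(2 * tp, 2 * tp + fp + fn, "F1")
  )
}

#' One-vs-rest metrics for a multi-class confusion matrix
#'
#' Collapses each class to a 2x2 (class vs rest) matrix and applies
#' [binary_metrics()].
#'
#' @param cm a KxK `confusion_matrix` (reference rows).
#' @return tibble with one row per class.
#' @export
one_vs_rest_metrics <- function(cm) {
  k <- nrow(cm)
  labs <- rownames(cm) %||% as.character(seq_len(k))
  purrr::map_dfr(seq_len(k), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- sum(cm[-i, -i])
    m2 <- matrix(as.numeric(c(tp, fn, fp, tn)), 2, 2, byrow = TRUE)
    dplyr::bind_cols(tibble(class = labs[i]), binary_metrics(m2))
  })
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the row/column marginals.
#'
#' @param cm KxK `confusion_matrix` with positive total.
#' @return numeric kappa.
#' @export
cohen_kappa <- function(cm) {
  cm <- unclass(cm)
  n <- sum(cm)
  if (n <= 0) abort("confusion matrix total must be positive")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warn("kappa undefined: expected agreement is 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples observation units with replacement (vector elements, or
#' data-frame rows — so subject-level resampling respects within-subject
#' pairing) and returns the percentile interval of the statistic.
#' Seeded and reproducible.
#'
#' @param data numeric vector or data frame.
#' @param statistic function of a resampled `data` returning a scalar.
#' @param n_iter bootstrap iterations (10,000 for reported CIs).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list: lower, upper, point, n_iter.
#' @export
bootstrap_ci <- function(data, statistic, n_iter = 10000, seed = 1L,
                         conf = 0.95) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n == 0) abort("bootstrap data must be non-empty")
  point <- statistic(data)
  stats <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
      as.numeric(statistic(d))[1]
    }, numeric(1))
  })
  ok <- is.finite(stats)
  if (mean(ok) < 0.5) {
    abort("statistic undefined in more than half of bootstrap resamples")
  }
  a <- (1 - conf) / 2
  q <- stats::quantile(stats[ok], c(a, 1 - a), names = FALSE)
  list(lower = q[1], upper = q[2], point = point, n_iter = n_iter)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `pred - ref` (algorithm minus manual), so a
#' positive bias means the algorithm over-estimates. Reports the mean
#' difference (bias), the 95% limits of agreement `bias +/- 1.96 * SD`,
#' bootstrap CIs for each, a proportionality slope (least squares of
#' difference on pair mean, with its p-value), and the intraclass
#' correlation of the pairs. `log = TRUE` analyses log-transformed
#' values.
#'
#' @param ref,pred paired numeric vectors (n >= 3).
#' @param n_iter bootstrap iterations for the CIs.
#' @param seed bootstrap seed.
#' @param log analyse on the log scale (values must be positive).
#' @return object of class `bland_altman`.
#' @export
bland_altman <- function(ref, pred, n_iter = 2000, seed = 1L, log = FALSE) {
  stopifnot(length(ref) == length(pred))
  n <- length(ref)
  if (n < 3) abort("Bland-Altman requires at least 3 pairs")
  if (log) {
    if (any(ref <= 0 | pred <= 0)) abort("log mode requires positive values")
    ref <- base::log(ref); pred <- base::log(pred)
  }
  d <- pred - ref
  m <- (pred + ref) / 2
  bias <- mean(d)
  s <- sd(d)
  df <- data.frame(ref = ref, pred = pred)
  ci_of <- function(f, sd_off) {
    bootstrap_ci(df, function(dd) {
      di <- dd$pred - dd$ref
      mean(di) + sd_off * sd(di)
    }, n_iter = n_iter, seed = seed)
  }
  fit <- stats::lm(d ~ m)
  slope <- unname(coef(fit)[2])
  # perfect fits (zero residual) are legitimate degenerate inputs here;
  # lm's reliability warning is expected and not informative
  slope_p <- if (n > 3 && sd(m) > 0) {
    suppressWarnings(summary(fit)$coefficients[2, 4])
  } else NA_real_
  structure(list(
    n = n, bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    bias_ci = ci_of("bias", 0),
    loa_low_ci = ci_of("loa_low", -1.96),
    loa_high_ci = ci_of("loa_high", 1.96),
    proportionality_slope = slope, slope_p = slope_p,
    icc = icc_value(ref, pred),
    log = log, data = tibble(ref = ref, pred = pred, diff = d, mean = m)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (pred - ref), n = %d%s\n  bias %.2f [%.2f, %.2f]\n  LoA  %.2f [%.2f, %.2f] to %.2f [%.2f, %.2f]\n  proportionality slope %.3f (p = %.3g), ICC %.3f\n",
    x$n, if (x$log) " (log scale)" else "",
    x$bias, x$bias_ci$lower, x$bias_ci$upper,
    x$loa_low, x$loa_low_ci$lower, x$loa_low_ci$upper,
    x$loa_high, x$loa_high_ci$lower, x$loa_high_ci$upper,
    x$proportionality_slope, x$slope_p, x$icc))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(
    term = c("bias", "loa_low", "loa_high", "proportionality_slope"),
    estimate = c(x$bias, x$loa_low, x$loa_high, x$proportionality_slope),
    conf.low = c(x$bias_ci$lower, x$loa_low_ci$lower,
                 x$loa_high_ci$lower, NA),
    conf.high = c(x$bias_ci$upper, x$loa_low_ci$upper,
                  x$loa_high_ci$upper, NA)
  )
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         proportionality_slope = x$proportionality_slope,
         slope_p = x$slope_p, icc = x$icc)
}

# ICC(2,1): two-way random effects, absolute agreement, single measure,
# computed from the two-way ANOVA sums of squares.
icc_value <- function(ref, pred) {
  x <- cbind(ref, pred)
  n <- nrow(x); k <- 2
  if (n < 2) return(NA_real_)
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  sst <- sum((x - grand)^2)
  sse <- sst - k * sum((rowMeans(x) - grand)^2) -
    n * sum((colMeans(x) - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (abs(den) < 1e-15) return(NA_real_)
  (msr - mse) / den
}

#' Intraclass correlation coefficient (two-way random, absolute
#' agreement, single measure)
#'
#' The standard method-comparison form ICC(2,1), with a percentile
#' bootstrap confidence interval over subjects.
#'
#' @param ref,pred paired numeric vectors (n >= 3).
#' @param n_iter,seed bootstrap settings.
#' @return list of class `icc_result`: estimate, lower, upper, n.
#' @export
icc <- function(ref, pred, n_iter = 2000, seed = 1L) {
  stopifnot(length(ref) == length(pred))
  if (length(ref) < 3) abort("ICC requires at least 3 pairs")
  if (sd(rowMeans(cbind(ref, pred))) < 1e-15) {
    warn("ICC undefined: no between-subject variance")
    est <- NA_real_
    return(structure(list(estimate = est, lower = NA_real_,
                          upper = NA_real_, n = length(ref)),
                     class = "icc_result"))
  }
  est <- icc_value(ref, pred)
  ci <- bootstrap_ci(data.frame(ref = ref, pred = pred),
                     function(d) icc_value(d$ref, d$pred),
                     n_iter = n_iter, seed = seed)
  structure(list(estimate = est, lower = ci$lower, upper = ci$upper,
                 n = length(ref)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f [%.3f, %.3f], n = %d\n",
              x$estimate, x$lower, x$upper, x$n))
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble(term = "icc", estimate = x$estimate,
         conf.low = x$lower, conf.high = x$upper)
}

#' Assign AHI severity groups
#'
#' Standard boundaries, left-closed at 5, 15 and 30: normal (AHI < 5),
#' mild (5 <= AHI < 15), moderate (15 <= AHI < 30), severe (AHI >= 30).
#'
#' @param ahi numeric vector (>= 0).
#' @return factor with levels normal/mild/moderate/severe.
#' @export
ahi_severity <- function(ahi) {
  if (any(ahi < 0, na.rm = TRUE)) abort("AHI must be non-negative")
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Stratified patient-level agreement by AHI severity (and PLMSI)
#'
#' Bins subjects by AHI severity and reports per-bin n, bias, limits of
#' agreement (1.96 SD of the differences) and ICC for a paired index
#' (e.g. arousal index, reference vs algorithm). If a `plmsi` column is
#' present the PLMSI < 15 / >= 15 split is reported as well.
#'
#' @param subjects data frame with columns `ahi`, `ref`, `pred` (and
#'   optionally `plmsi`).
#' @return tibble: group, n, bias, loa, icc.
#' @export
stratify_by_ahi <- function(subjects) {
  stopifnot(all(c("ahi", "ref", "pred") %in% names(subjects)))
  subjects$group <- ahi_severity(subjects$ahi)
  one <- function(d, label) {
    di <- d$pred - d$ref
    tibble(group = label, n = nrow(d),
           bias = if (nrow(d) > 0) mean(di) else NA_real_,
           loa = if (nrow(d) > 1) 1.96 * sd(di) else NA_real_,
           icc = if (nrow(d) >= 3) icc_value(d$ref, d$pred) else NA_real_)
  }
  out <- purrr::map_dfr(levels(subjects$group), function(g) {
    one(subjects[subjects$group == g, , drop = FALSE], g)
  })
  if ("plmsi" %in% names(subjects)) {
    out <- dplyr::bind_rows(
      out,
      one(subjects[subjects$plmsi < 15, , drop = FALSE], "plmsi_lt_15"),
      one(subjects[subjects$plmsi >= 15, , drop = FALSE], "plmsi_ge_15"))
  }
  out
}

#' Classify arousals as respiratory-linked
#'
#' An arousal is respiratory-linked if a respiratory event (apnea or
#' hypopnea) intersects the 15-s look-back window `[onset - 15, onset)`.
#'
#' @param arousals arousal [events_table()].
#' @param resp_events respiratory [events_table()].
#' @return list: `arousals` with the `respiratory_linked` flag set, and
#'   `linked_fraction` (NA with a warning when there are no arousals).
#' @export
classify_respiratory_arousals <- function(arousals, resp_events) {
  n <- nrow(arousals)
  if (n == 0) {
    warn("linked fraction undefined: no arousals")
    return(list(arousals = arousals, linked_fraction = NA_real_))
  }
  linked <- vapply(seq_len(n), function(i) {
    on <- arousals$onset[i]
    if (is.null(resp_events) || nrow(resp_events) == 0) return(FALSE)
    any(resp_events$onset < on &
          resp_events$onset + resp_events$duration > on - 15)
  }, logical(1))
  arousals$respiratory_linked <- linked
  list(arousals = arousals, linked_fraction = mean(linked))
}

#' Cohort-level agreement report
#'
#' Pools epoch-level confusion over recordings and reports per-class
#' one-vs-rest metrics with cluster-bootstrap CIs (recordings are the
#' resampling unit, respecting within-subject correlation), Cohen's
#' kappa for sleep states, and — when events are supplied — the
#' arousal-epoch 2x2 matrix, its metrics and kappa.
#'
#' @param ref_hyps,pred_hyps lists of hypnograms.
#' @param ref_events,pred_events optional lists of arousal event tables.
#' @param n_iter bootstrap iterations; @param seed bootstrap seed.
#' @return list of class `agreement_report`.
#' @export
agreement_report <- function(ref_hyps, pred_hyps, ref_events = NULL,
                             pred_events = NULL, n_iter = 1000, seed = 1L) {
  stopifnot(length(ref_hyps) == length(pred_hyps))
  n_rec <- length(ref_hyps)
  cms <- lapply(seq_len(n_rec), function(i) {
    epoch_confusion(ref_hyps[[i]], pred_hyps[[i]])
  })
  pooled <- Reduce(`+`, lapply(cms, unclass))
  pooled <- structure(pooled, class = c("confusion_matrix", "matrix"))
  state_metrics <- one_vs_rest_metrics(pooled)
  boot_metric <- function(stat_fn) {
    bootstrap_ci(seq_len(n_rec), function(idx) {
      stat_fn(Reduce(`+`, lapply(cms[idx], unclass)))
    }, n_iter = n_iter, seed = seed)
  }
  state_kappa <- cohen_kappa(pooled)
  state_kappa_ci <- if (n_rec > 1) boot_metric(cohen_kappa) else NULL

  ar <- NULL
  if (!is.null(ref_events)) {
    acms <- lapply(seq_len(n_rec), function(i) {
      arousal_epoch_confusion(ref_events[[i]], pred_events[[i]],
                              nrow(as_hypnogram(ref_hyps[[i]])))
    })
    apooled <- structure(Reduce(`+`, lapply(acms, unclass)),
                         class = c("confusion_matrix", "matrix"))
    ar <- list(confusion = apooled,
               metrics = binary_metrics(apooled),
               kappa = cohen_kappa(apooled))
  }
  structure(list(
    state_confusion = pooled, state_metrics = state_metrics,
    state_kappa = state_kappa, state_kappa_ci = state_kappa_ci,
    arousal = ar, n_recordings = n_rec
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report: %d recordings>\n", x$n_recordings))
  cat(sprintf("sleep-state kappa %.3f\n", x$state_kappa))
  print(as.data.frame(x$state_metrics))
  if (!is.null(x$arousal)) {
    cat(sprintf("arousal kappa %.3f\n", x$arousal$kappa))
    print(as.data.frame(x$arousal$metrics))
  }
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  out <- tidyr::pivot_longer(x$state_metrics, -"class",
                             names_to = "metric", values_to = "estimate")
  if (!is.null(x$arousal)) {
    out <- dplyr::bind_rows(
      out,
      tidyr::pivot_longer(
        dplyr::mutate(x$arousal$metrics, class = "arousal"),
        -"class", names_to = "metric", values_to = "estimate"))
  }
  out
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble(n_recordings = x$n_recordings,
         state_kappa = x$state_kappa,
         arousal_kappa = if (!is.null(x$arousal)) x$arousal$kappa else NA_real_)
}
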