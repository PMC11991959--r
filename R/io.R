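# EDF (European Data Format) container for the two belt signals.
# 16-bit integer samples; header and per-signal subheaders are fixed-width
# ASCII fields. Written and parsed directly with writeBin/readBin.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a RIP recording to an EDF file
#'
#' Two 16-bit signals labeled by `channel_labels` (default "Thorax",
#' "Abdomen"), one-second data records. Physical scaling covers each
#' channel's range, so the round trip is exact to within 16-bit
#' quantization.
#'
#' @param rec a [rip_recording()]; the sample rate times the record
#'   duration must be a whole number.
#' @param path output file.
#' @param record_duration data-record length in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  stopifnot(inherits(rec, "rip_recording"))
  fs <- rec$sample_rate
  spr <- fs * record_duration
  if (abs(spr - round(spr)) > 1e-9) {
    abort("sample_rate * record_duration must be an integer")
  }
  spr <- as.integer(round(spr))
  chans <- list(rec$thorax, rec$abdomen)
  n_rec <- as.integer(floor(length(rec$thorax) / spr))
  if (n_rec < 1) abort("recording shorter than one data record")
  ns <- 2L
  phys <- lapply(chans, function(x) {
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-9) { lo <- lo - 1; hi <- hi + 1 }
    c(lo, hi)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, width) writeChar(pad_field(x, width), con,
                                     nchars = width, eos = NULL)
  wf("0", 8); wf("synthetic subject", 80); wf("ripsleep recording", 80)
  wf("01.01.00", 8); wf("00.00.00", 8)
  wf(256L + ns * 256L, 8); wf("", 44); wf(n_rec, 8)
  wf(format(record_duration), 8); wf(ns, 4)
  for (lab in rec$channel_labels) wf(lab, 16)
  for (i in 1:ns) wf("RIP belt", 80)
  for (i in 1:ns) wf("uV", 8)
  num8 <- function(x) {  # fit a float into the 8-char ASCII field
    for (dg in 7:1) {
      s <- formatC(x, format = "g", digits = dg)
      if (nchar(s) <= 8) return(s)
    }
    formatC(x, format = "e", digits = 1)
  }
  for (i in 1:ns) wf(num8(phys[[i]][1]), 8)
  for (i in 1:ns) wf(num8(phys[[i]][2]), 8)
  for (i in 1:ns) wf(-32768L, 8)
  for (i in 1:ns) wf(32767L, 8)
  for (i in 1:ns) wf("HP:0.0Hz", 80)
  for (i in 1:ns) wf(spr, 8)
  for (i in 1:ns) wf("", 32)
  dig <- lapply(1:ns, function(i) {
    x <- chans[[i]][seq_len(n_rec * spr)]
    p <- phys[[i]]
    as.integer(round((x - p[1]) / (p[2] - p[1]) * 65535 - 32768))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in 1:ns) writeBin(dig[[i]][idx], con, size = 2,
                             endian = "little")
  }
  invisible(path)
}

#' Read a two-belt RIP recording from an EDF file
#'
#' Selects the thorax and abdomen channels by case-insensitive label
#' patterns, converts 16-bit samples to physical units, and
#' standardizes both channels to `target_rate`.
#'
#' @param path EDF file.
#' @param patterns length-2 character: regex fragments matching the
#'   thorax and abdomen channel labels.
#' @param target_rate output sampling rate (25 Hz).
#' @return a [rip_recording()].
#' @export
read_edf <- function(path, patterns = c("thor", "abdo"), target_rate = 25) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rf <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rf(8); rf(80); rf(80); rf(8); rf(8)
  rf(8)  # header bytes
  rf(44)
  n_rec <- as.integer(rf(8))
  rec_dur <- as.numeric(rf(8))
  ns <- as.integer(rf(4))
  if (is.na(ns) || ns < 2) abort("EDF file must contain at least 2 signals")
  labels <- vapply(1:ns, function(i) rf(16), character(1))
  for (i in 1:ns) rf(80)             # transducer
  for (i in 1:ns) rf(8)              # physical dimension
  pmin_ <- vapply(1:ns, function(i) as.numeric(rf(8)), numeric(1))
  pmax_ <- vapply(1:ns, function(i) as.numeric(rf(8)), numeric(1))
  dmin_ <- vapply(1:ns, function(i) as.numeric(rf(8)), numeric(1))
  dmax_ <- vapply(1:ns, function(i) as.numeric(rf(8)), numeric(1))
  for (i in 1:ns) rf(80)             # prefiltering
  spr <- vapply(1:ns, function(i) as.integer(rf(8)), integer(1))
  for (i in 1:ns) rf(32)
  pick <- vapply(patterns, function(p) {
    hit <- grep(p, labels, ignore.case = TRUE)
    if (length(hit) == 0) {
      abort(sprintf("channel matching '%s' not found; available: %s",
                    p, paste(labels, collapse = ", ")))
    }
    hit[1]
  }, integer(1))
  raw <- lapply(1:ns, function(i) vector("list", n_rec))
  for (r in seq_len(n_rec)) {
    for (i in 1:ns) {
      v <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      if (i %in% pick) raw[[i]][[r]] <- v
    }
  }
  chan <- lapply(pick, function(i) {
    x <- unlist(raw[[i]])
    pmin_[i] + (x - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i])
  })
  rates <- spr[pick] / rec_dur
  sig <- lapply(seq_along(chan), function(j) {
    resample_to(chan[[j]], rates[j], target_rate)
  })
  len <- min(lengths(sig))
  rip_recording(sig[[1]][1:len], sig[[2]][1:len], sample_rate = target_rate,
                channel_labels = labels[pick])
}

resample_to <- function(x, fs, target) {
  if (isTRUE(all.equal(fs, target))) return(x)
  tmp <- rip_recording(x, x, sample_rate = fs)
  standardize(tmp, target)$thorax
}

#' Write / read event annotations as CSV
#'
#' The sidecar dialect has columns `event_type`, `onset_s`,
#' `duration_s`, `label`. Reading validates every row and reports the
#' offending line number for malformed entries.
#'
#' @param events an [events_table()] (arousals and/or respiratory).
#' @param path CSV path.
#' @export
write_events_csv <- function(events, path) {
  out <- data.frame(
    event_type = events$type,
    onset_s = events$onset,
    duration_s = events$duration,
    label = ifelse(is.na(events$respiratory_linked), "",
                   ifelse(events$respiratory_linked, "respiratory", "spontaneous"))
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_type", "onset_s", "duration_s")
  if (!all(need %in% names(df))) {
    abort(paste0("annotation CSV must have columns: ",
                 paste(need, collapse = ", ")))
  }
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$onset_s[i]) || !is.finite(df$duration_s[i]) ||
        df$duration_s[i] < 0 || df$onset_s[i] < 0) {
      abort(sprintf("malformed annotation at line %d of %s", i + 1L, path))
    }
  }
  linked <- if ("label" %in% names(df)) {
    ifelse(df$label == "respiratory", TRUE,
           ifelse(df$label == "spontaneous", FALSE, NA))
  } else NA
  events_table(df$onset_s, df$duration_s, df$event_type, linked)
}

#' Write / read a hypnogram CSV
#'
#' Columns `epoch_index`, `state`; states must be WAKE/NREM/REM/ARTIFACT.
#'
#' @param hyp a hypnogram; @param path CSV path.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  hyp <- as_hypnogram(hyp)
  utils::write.csv(
    data.frame(epoch_index = hyp$epoch, state = as.character(hyp$state)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "state") %in% names(df))) {
    abort("hypnogram CSV must have columns epoch_index, state")
  }
  bad <- which(!df$state %in% hypnogram_states)
  if (length(bad) > 0) {
    abort(sprintf("unknown state token '%s' at line %d of %s",
                  df$state[bad[1]], bad[1] + 1L, path))
  }
  hypnogram(df$state[order(df$epoch_index)])
}

#' Write a scoring summary as JSON
#'
#' @param scoring an `nbs_scoring` (or a named list); the JSON includes
#'   TST, ArI, arousal count and — when respiratory events are given —
#'   the respiratory-linked arousal fraction.
#' @param path output path.
#' @param resp_events optional respiratory [events_table()].
#' @export
write_summary_json <- function(scoring, path, resp_events = NULL) {
  s <- if (inherits(scoring, "nbs_scoring")) {
    out <- list(tst_min = scoring$summary$tst_min,
                ari = scoring$summary$ari,
                n_arousals = scoring$summary$n_arousals)
    if (!is.null(resp_events)) {
      cls <- classify_respiratory_arousals(scoring$arousals, resp_events)
      out$linked_arousal_fraction <- cls$linked_fraction
    }
    out
  } else scoring
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
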