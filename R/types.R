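#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of sleep-state labels at the
#' standard 30-s scoring resolution. States are `WAKE`, `NREM`, `REM`
#' plus `ARTIFACT` for epochs excluded from analysis. Sub-stages N1-N3
#' are not distinguished; they are collapsed into the single `NREM`
#' state.
#'
#' @param states character or factor vector of epoch labels.
#' @param epoch_length epoch duration in seconds (30 by default; the
#'   scoring standard).
#' @return a tibble of class `hypnogram` with columns `epoch` (0-based
#'   index) and `state` (factor over WAKE/NREM/REM/ARTIFACT).
#' @export
hypnogram <- function(states, epoch_length = 30) {
  states <- as.character(states)
  if (length(states) == 0) abort("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(states), hypnogram_states)
  if (length(bad) > 0) {
    abort(paste0("unknown hypnogram state(s): ", paste(bad, collapse = ", ")))
  }
  out <- tibble(
    epoch = seq_along(states) - 1L,
    state = factor(states, levels = hypnogram_states)
  )
  class(out) <- c("hypnogram", class(out))
  attr(out, "epoch_length") <- epoch_length
  out
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<hypnogram: %d epochs (%.1f h)>\n", n,
              n * attr(x, "epoch_length") / 3600))
  print(table(x$state))
  invisible(x)
}

# Accept a hypnogram object or a bare label vector.
as_hypnogram <- function(x) {
  if (inherits(x, "hypnogram")) return(x)
  if (is.data.frame(x) && "state" %in% names(x)) return(hypnogram(x$state))
  hypnogram(x)
}

hypnogram_states_chr <- function(h) as.character(as_hypnogram(h)$state)

#' Construct an event table
#'
#' Timed events (arousals or respiratory events) as a tibble with onset
#' and duration in seconds from recording start. Arousals must last at
#' least 3 s; respiratory events (apnea/hypopnea) at least 10 s, per
#' standard scoring rules.
#'
#' @param onset numeric vector, seconds from recording start.
#' @param duration numeric vector, seconds.
#' @param type character: `"arousal"`, `"apnea"` or `"hypopnea"`.
#' @param respiratory_linked optional logical flag per event (arousals
#'   only): whether a respiratory event precedes it within 15 s.
#' @return tibble with columns onset, duration, type, respiratory_linked.
#' @export
events_table <- function(onset = numeric(), duration = numeric(),
                         type = character(), respiratory_linked = NA) {
  n <- length(onset)
  if (length(duration) != n) abort("onset and duration lengths differ")
  if (any(duration < 0)) abort("event durations must be non-negative")
  type <- if (length(type) == 1L) rep(type, n) else type
  tibble(
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    type = as.character(type),
    respiratory_linked = rep_len(as.logical(respiratory_linked), n)
  ) |> dplyr::arrange(.data$onset)
}

check_no_overlap <- function(ev, what = "events") {
  if (nrow(ev) < 2) return(invisible(TRUE))
  ev <- dplyr::arrange(ev, .data$onset)
  ends <- ev$onset + ev$duration
  if (any(ev$onset[-1] < ends[-nrow(ev)] - 1e-9)) {
    abort(paste0("overlapping ", what, " are not allowed"))
  }
  invisible(TRUE)
}

#' Construct a two-belt RIP recording
#'
#' Holds synchronized thorax and abdomen inductance series (arbitrary
#' units) at a fixed sampling rate. The scoring pipeline standardizes
#' recordings to 25 Hz.
#'
#' @param thorax,abdomen numeric vectors of equal length.
#' @param sample_rate sampling rate in Hz.
#' @param start_time recording start (seconds offset or POSIXct); kept
#'   as metadata only.
#' @param channel_labels length-2 character vector.
#' @return object of class `rip_recording`.
#' @export
rip_recording <- function(thorax, abdomen, sample_rate = 25,
                          start_time = 0,
                          channel_labels = c("Thorax", "Abdomen")) {
  if (length(thorax) != length(abdomen)) {
    abort("thorax and abdomen channels must have equal length")
  }
  if (length(thorax) == 0) abort("empty signal")
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("sample_rate must be positive")
  }
  structure(
    list(thorax = as.numeric(thorax), abdomen = as.numeric(abdomen),
         sample_rate = sample_rate, start_time = start_time,
         channel_labels = channel_labels),
    class = "rip_recording"
  )
}

#' @export
print.rip_recording <- function(x, ...) {
  cat(sprintf("<rip_recording: 2 x %d samples @ %g Hz (%.2f h)>\n",
              length(x$thorax), x$sample_rate,
              length(x$thorax) / x$sample_rate / 3600))
  invisible(x)
}

#' @export
length.rip_recording <- function(x) length(x$thorax)

rec_duration <- function(rec) length(rec$thorax) / rec$sample_rate
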