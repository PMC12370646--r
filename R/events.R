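#' Detect swing-phase peaks in a shank angular-velocity signal
#'
#' Forward swing produces a prominent positive peak in the shank sagittal
#' angular velocity (sign convention shared with the generator; flip the
#' signal for hardware with the opposite convention). Peaks are detected
#' within one section with a minimum separation.
#'
#' @param x shank sagittal angular velocity (deg/s), filtered, full recording.
#' @param section optional list/row with `start_sample`, `end_sample`
#'   (0-based, half-open) restricting the search.
#' @param fs sampling rate in Hz.
#' @param min_height minimum peak height in deg/s.
#' @param min_separation_s minimum peak separation in seconds.
#' @return integer vector of 0-based peak samples (possibly empty).
#' @export
detect_swing_peaks <- function(x, fs, section = NULL, min_height = 20,
                               min_separation_s = 0.4) {
  if (!is.null(section)) {
    idx <- (section$start_sample + 1L):section$end_sample
    seg <- x[idx]
    offset <- section$start_sample
  } else {
    seg <- x
    offset <- 0L
  }
  pk <- pracma::findpeaks(seg, minpeakheight = min_height,
                          minpeakdistance = max(1L, round(min_separation_s * fs)))
  if (is.null(pk)) return(integer(0))
  sort(pk[, 2L]) + offset - 1L # 0-based
}

#' Detect IC and TC events around swing peaks
#'
#' For each swing peak, the first local minimum strictly before the peak is
#' the terminal contact (TC, toe-off) and the first local minimum strictly
#' after it is the initial contact (IC, heel strike). A local minimum is a
#' sample strictly smaller than both neighbours (plateaus resolve to their
#' leftmost sample). Peaks lacking a flanking minimum inside the searched
#' window produce no event on that flank; a valley shared by two peaks serves
#' as IC of the first and TC of the second.
#'
#' @param x signal (full recording scale), filtered.
#' @param peaks 0-based peak samples, sorted.
#' @param section optional `start_sample`/`end_sample` bounds (0-based,
#'   half-open) outside which minima are not searched.
#' @return data frame `type` (`"IC"`/`"TC"`), `sample` (0-based), time-ordered,
#'   deduplicated per (type, sample).
#' @export
detect_ic_tc <- function(x, peaks, section = NULL) {
  if (length(peaks) == 0L)
    return(data.frame(type = character(0), sample = integer(0)))
  lo <- if (!is.null(section)) section$start_sample else 0L
  hi <- if (!is.null(section)) section$end_sample else length(x)
  idx <- (lo + 1L):hi
  mins <- local_minima(x[idx]) + lo - 1L # 0-based
  out <- list()
  for (p in sort(peaks)) {
    before <- mins[mins < p]
    after <- mins[mins > p]
    if (length(before))
      out[[length(out) + 1L]] <- data.frame(type = "TC", sample = max(before))
    if (length(after))
      out[[length(out) + 1L]] <- data.frame(type = "IC", sample = min(after))
  }
  if (length(out) == 0L)
    return(data.frame(type = character(0), sample = integer(0)))
  ev <- unique(do.call(rbind, out))
  ev[order(ev$sample, ev$type), , drop = FALSE]
}

#' Assemble side-specific gait cycles from IC/TC events
#'
#' A gait cycle is a maximal non-overlapping IC -> TC -> IC triple of one
#' side; consecutive cycles share the boundary IC. Leading TCs and incomplete
#' trailing patterns are dropped.
#'
#' @param events data frame with `type` and `sample`, time-ordered, one side.
#' @return data frame `ic_start, tc, ic_end` (0-based samples).
#' @export
assemble_cycles <- function(events) {
  empty <- data.frame(ic_start = integer(0), tc = integer(0),
                      ic_end = integer(0))
  if (nrow(events) == 0L) return(empty)
  events <- events[order(events$sample), , drop = FALSE]
  out <- list()
  i <- 1L
  ic_start <- NA_integer_
  tc <- NA_integer_
  while (i <= nrow(events)) {
    e <- events[i, ]
    if (is.na(ic_start)) {
      if (e$type == "IC") ic_start <- e$sample
    } else if (is.na(tc)) {
      if (e$type == "TC" && e$sample > ic_start) tc <- e$sample
      else if (e$type == "IC") ic_start <- e$sample # restart at later IC
    } else {
      if (e$type == "IC" && e$sample > tc) {
        out[[length(out) + 1L]] <-
          data.frame(ic_start = ic_start, tc = tc, ic_end = e$sample)
        ic_start <- e$sample # boundary IC shared with next cycle
        tc <- NA_integer_
      }
    }
    i <- i + 1L
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Detect gait events and cycles for a whole recording
#'
#' Applies [detect_swing_peaks()] and [detect_ic_tc()] to each shank side
#' within every section. Gait cycles are assembled only inside straight-walk
#' sections; IC events inside turns feed the turn step count.
#'
#' @param recording filtered `raw_recording`.
#' @param sections section table from [segment_recording()].
#' @param min_height,min_separation_s passed to [detect_swing_peaks()].
#' @return list: `events` (participant, side, type, sample, time_s, kind,
#'   ordinal), `cycles` (side, kind, ordinal, ic_start, tc, ic_end).
#' @export
detect_gait_events <- function(recording, sections, min_height = 20,
                               min_separation_s = 0.4) {
  fs <- recording$fs
  ev_all <- list()
  cy_all <- list()
  for (side in c("L", "R")) {
    x <- recording$sensors[[if (side == "L") "shank_l" else "shank_r"]]$gyr_x
    for (si in seq_len(nrow(sections))) {
      sec <- sections[si, ]
      pk <- detect_swing_peaks(x, fs, section = sec, min_height = min_height,
                               min_separation_s = min_separation_s)
      ev <- detect_ic_tc(x, pk, section = sec)
      if (nrow(ev) == 0L) next
      ev$side <- side
      ev$kind <- sec$kind
      ev$ordinal <- sec$ordinal
      ev_all[[length(ev_all) + 1L]] <- ev
      if (sec$kind == "SW") {
        cy <- assemble_cycles(ev)
        if (nrow(cy)) {
          cy$side <- side
          cy$kind <- sec$kind
          cy$ordinal <- sec$ordinal
          cy_all[[length(cy_all) + 1L]] <- cy
        }
      }
    }
  }
  events <- if (length(ev_all)) do.call(rbind, ev_all) else
    data.frame(type = character(0), sample = integer(0), side = character(0),
               kind = character(0), ordinal = integer(0))
  if (nrow(events)) {
    events$participant <- recording$participant_id
    events$time_s <- events$sample / fs
    events <- events[order(events$sample, events$side, events$type),
                     c("participant", "side", "type", "sample", "time_s",
                       "kind", "ordinal")]
    rownames(events) <- NULL
  }
  cycles <- if (length(cy_all)) do.call(rbind, cy_all) else
    data.frame(ic_start = integer(0), tc = integer(0), ic_end = integer(0),
               side = character(0), kind = character(0), ordinal = integer(0))
  rownames(cycles) <- NULL
  list(events = events, cycles = cycles)
}
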