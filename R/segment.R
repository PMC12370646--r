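#' Detect turn boundaries from the waist heading curve
#'
#' Turns appear as prominent peaks in the smoothed absolute heading rate
#' (deg/s). Each rate peak is bracketed by the samples where the rate crosses
#' `onset_frac` of the peak value; the crossing pair is the turn's onset and
#' completion. A trial with two turns therefore yields four boundaries
#' (onset 1, completion 1, onset 2, completion 2), returned in time order as
#' 0-based samples relative to the start of `heading`.
#'
#' @param heading unwrapped (and, if needed, detrended) heading in degrees for
#'   one trial.
#' @param fs sampling rate in Hz.
#' @param min_prominence_deg_s minimum rate-peak height in deg/s.
#' @param min_separation_s minimum separation between rate peaks in seconds.
#' @param onset_frac fraction of the rate peak defining onset/completion.
#' @param smooth_s smoothing window (seconds) applied to heading and rate.
#' @return integer vector of four 0-based boundary samples.
#' @export
detect_turn_peaks <- function(heading, fs, min_prominence_deg_s = 30,
                              min_separation_s = 1.0, onset_frac = 0.15,
                              smooth_s = 0.25) {
  hs <- smooth_ma(heading, fs, smooth_s)
  rate <- c(0, diff(hs)) * fs
  a <- abs(smooth_ma(rate, fs, 0.6 * smooth_s))
  # connected regions above the prominence threshold (robust to flat-topped
  # rate profiles, where discrete peak picking splits one turn in two)
  r <- rle(a > min_prominence_deg_s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(start = starts[r$values], end = ends[r$values])
  if (nrow(reg) > 1L) { # merge regions closer than the minimum separation
    keep <- c(TRUE, reg[-1L, "start"] - reg[-nrow(reg), "end"] >=
                min_separation_s * fs)
    grp <- cumsum(keep)
    reg <- cbind(start = tapply(reg[, "start"], grp, min),
                 end = tapply(reg[, "end"], grp, max))
  }
  if (nrow(reg) < 2L)
    stop("segmentation failure: fewer than 4 turn boundaries in trial")
  peak_val <- vapply(seq_len(nrow(reg)), function(i)
    max(a[reg[i, 1L]:reg[i, 2L]]), 1.0)
  if (nrow(reg) > 2L) { # two turns per trial: keep the two strongest
    sel <- sort(order(peak_val, decreasing = TRUE)[1:2])
    reg <- reg[sel, , drop = FALSE]
    peak_val <- peak_val[sel]
  }
  bounds <- integer(0)
  for (i in seq_len(nrow(reg))) {
    thr <- onset_frac * peak_val[i]
    before <- which(a[seq_len(reg[i, 1L])] < thr)
    after <- which(a[reg[i, 2L]:length(a)] < thr)
    # a turn truncated by the active window ends at the window edge
    onset <- if (length(before)) max(before) + 1L else 1L
    completion <- if (length(after)) reg[i, 2L] + min(after) - 1L else length(a)
    bounds <- c(bounds, onset - 1L, completion - 1L) # 0-based
  }
  bounds <- sort(unique(bounds))
  if (length(bounds) != 4L)
    stop("segmentation failure: fewer than 4 turn boundaries in trial")
  bounds
}

#' Build one trial's sections from its four turn boundaries
#'
#' The first and second boundaries delimit the first turn, the third and
#' fourth the second turn; the active-walking remainders are straight-walk
#' sections: `SW = [active_start, p1), [p2, p3)`, `T = [p1, p2), [p3, p4)`.
#'
#' @param peaks integer vector of exactly four increasing 0-based boundary
#'   samples.
#' @param active length-2 vector, the trial's active interval `[start, end)`.
#' @param trial trial number stored in the output.
#' @return data frame with columns `trial, kind, start_sample, end_sample`
#'   (half-open, 0-based), rows ordered SW, T, SW, T.
#' @export
segment_trial <- function(peaks, active, trial = 1L) {
  if (length(peaks) != 4L) stop("invalid input: exactly 4 peaks required")
  if (any(diff(peaks) <= 0)) stop("invalid input: peaks must be strictly increasing")
  if (length(active) != 2L || active[1L] >= active[2L])
    stop("invalid input: bad active interval")
  if (active[1L] >= peaks[1L] || peaks[4L] > active[2L])
    stop("invalid input: peaks must lie inside the active interval")
  data.frame(
    trial = trial,
    kind = c("SW", "T", "SW", "T"),
    start_sample = as.integer(c(active[1L], peaks[1L], peaks[2L], peaks[3L])),
    end_sample = as.integer(c(peaks[1L], peaks[2L], peaks[3L], peaks[4L]))
  )
}

#' Locate the active (walking) intervals of a recording
#'
#' Activity combines two normalized energies - smoothed shank
#' angular-velocity energy (walking) and smoothed waist heading-rate energy
#' (turning) - each scaled by its own maximum; a sample is active when either
#' exceeds `frac` of its maximum. Short interior drops (stance phases) are
#' closed, and the remaining runs are the trials.
#'
#' @param shank_l,shank_r shank sagittal angular velocity, deg/s (filtered).
#' @param fs sampling rate in Hz.
#' @param heading_rate optional waist heading rate (deg/s, e.g. the waist
#'   vertical-axis gyro); without it only shank energy is used.
#' @param frac energy threshold as a fraction of the maximum.
#' @param close_gap_s close inactive gaps shorter than this (seconds).
#' @param min_trial_s drop active runs shorter than this (seconds).
#' @return integer matrix with columns `start`, `end` (0-based, half-open),
#'   one row per trial.
#' @export
find_active_trials <- function(shank_l, shank_r, fs, heading_rate = NULL,
                               frac = 0.05, close_gap_s = 0.7,
                               min_trial_s = 2) {
  energy <- smooth_ma(shank_l^2 + shank_r^2, fs, 0.3)
  score <- energy / max(energy)
  if (!is.null(heading_rate)) {
    he <- smooth_ma(heading_rate^2, fs, 0.3)
    score <- pmax(score, he / max(he))
  }
  active <- score > frac
  r <- rle(active)
  # close short interior gaps (stance phases)
  n_runs <- length(r$values)
  for (i in seq_len(n_runs)) {
    if (!r$values[i] && i > 1L && i < n_runs &&
        r$lengths[i] < close_gap_s * fs)
      r$values[i] <- TRUE
  }
  active <- inverse.rle(r)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_trial_s * fs
  cbind(start = starts[keep] - 1L, end = ends[keep]) # 0-based half-open
}

#' Segment a whole recording into straight-walk and turn sections
#'
#' Finds the trials from shank activity, detects each trial's turn boundaries
#' on the waist heading, builds the per-trial sections and numbers them
#' SW1..SW6 / T1..T6 chronologically across trials. Trials whose turns cannot
#' be segmented are reported and excluded.
#'
#' @param angles an `angle_series` (from [estimate_orientation()]).
#' @param recording the filtered `raw_recording` (shank channels drive the
#'   activity detection).
#' @param ... passed to [detect_turn_peaks()].
#' @return data frame `participant, trial, kind, ordinal, start_sample,
#'   end_sample`; attribute `failed_trials` lists excluded trials.
#' @export
segment_recording <- function(angles, recording, ...) {
  stopifnot(inherits(angles, "angle_series"), inherits(recording, "raw_recording"))
  fs <- angles$fs
  trials <- find_active_trials(recording$sensors$shank_l$gyr_x,
                               recording$sensors$shank_r$gyr_x, fs,
                               heading_rate = recording$sensors$waist$gyr_z)
  heading <- angles$sensors$waist$heading_deg
  out <- list()
  failed <- integer(0)
  for (tr in seq_len(nrow(trials))) {
    a0 <- trials[tr, "start"]
    a1 <- trials[tr, "end"]
    sec <- tryCatch({
      b <- detect_turn_peaks(heading[(a0 + 1L):a1], fs, ...) + a0
      segment_trial(b, active = c(a0, a1), trial = tr)
    }, error = function(e) {
      warning("trial ", tr, " excluded: ", conditionMessage(e))
      NULL
    })
    if (is.null(sec)) failed <- c(failed, tr) else out[[length(out) + 1L]] <- sec
  }
  if (length(out) == 0L) stop("segmentation failure: no trial segmented")
  sections <- do.call(rbind, out)
  sections$ordinal <- stats::ave(seq_len(nrow(sections)), sections$kind,
                                 FUN = seq_along)
  sections <- data.frame(participant = recording$participant_id,
                         sections[, c("trial", "kind", "ordinal",
                                      "start_sample", "end_sample")])
  attr(sections, "failed_trials") <- failed
  sections
}

#' Compare predicted sections with ground truth
#'
#' Boundaries are matched by section kind and ordinal; errors are absolute
#' time differences. Count mismatches are reported, not raised.
#'
#' @param pred,truth section data frames with `kind, ordinal, start_sample,
#'   end_sample`.
#' @param tol_s tolerance in seconds.
#' @param fs sampling rate in Hz.
#' @return list: `boundaries` (kind, ordinal, boundary, err_s), `frac_within`,
#'   `n_matched`, `n_pred`, `n_truth`, `count_mismatch`.
#' @export
match_to_ground_truth <- function(pred, truth, tol_s = 0.25, fs = 100) {
  m <- merge(pred[, c("kind", "ordinal", "start_sample", "end_sample")],
             truth[, c("kind", "ordinal", "start_sample", "end_sample")],
             by = c("kind", "ordinal"), suffixes = c("_pred", "_true"))
  b <- rbind(
    data.frame(kind = m$kind, ordinal = m$ordinal, boundary = "start",
               err_s = abs(m$start_sample_pred - m$start_sample_true) / fs),
    data.frame(kind = m$kind, ordinal = m$ordinal, boundary = "end",
               err_s = abs(m$end_sample_pred - m$end_sample_true) / fs)
  )
  list(
    boundaries = b,
    frac_within = if (nrow(b)) mean(b$err_s <= tol_s) else NA_real_,
    n_matched = nrow(m), n_pred = nrow(pred), n_truth = nrow(truth),
    count_mismatch = nrow(pred) != nrow(truth)
  )
}
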