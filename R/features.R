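#' Kinematic feature catalogue
#'
#' The base parameters computed by the package, one row per base feature:
#' category (`cycle_based` features exist only for straight-walk sections;
#' `segmentation` features per section; `whole` features per trial or per
#' assessment), the sensor groups each derives from (left/right sensors are
#' grouped: waist, chest, hand, thigh, shank, foot), sidedness and units.
#' New base features can be added by extending this registry and supplying
#' values in the section feature matrix; the construction step is agnostic to
#' the catalogue's content.
#'
#' @return data frame with columns `base, category, sensors, sidedness,
#'   units, scalar`.
#' @export
feature_registry <- function() {
  r <- function(base, category, sensors, sidedness, units, scalar = FALSE)
    data.frame(base = base, category = category, sensors = sensors,
               sidedness = sidedness, units = units, scalar = scalar)
  rbind(
    r("Gait Speed", "cycle_based", "waist", "central", "m/s"),
    r("Cadence", "cycle_based", "shank,waist", "central", "steps/min"),
    r("Step Length", "cycle_based", "shank", "central", "m"),
    r("Double Support", "cycle_based", "shank", "central", "%"),
    r("Shank—Swing RoM", "cycle_based", "shank", "bilateral", "deg"),
    r("Thigh—Max Sagittal Angular Velocity", "cycle_based", "thigh",
      "bilateral", "deg/s"),
    r("Foot—Max Sagittal Angular Velocity", "cycle_based", "foot",
      "bilateral", "deg/s"),
    r("Arm—Swing RoM", "cycle_based", "hand", "bilateral", "deg"),
    r("Trunk—Max Sagittal Angular Velocity", "cycle_based", "chest",
      "central", "deg/s"),
    r("SW—Lumbar—Difference of Sagittal Sway", "segmentation",
      "waist", "central", "deg"),
    r("Straight-Walking Duration", "segmentation", "waist", "central", "s"),
    r("Trunk—Forward Sway Max", "segmentation", "chest", "central", "deg"),
    r("180° Turn—Duration", "segmentation", "waist", "central", "s"),
    r("180° Turn—Steps", "segmentation", "waist,shank", "central",
      "steps"),
    r("180° Turn—Max Angular Velocity", "segmentation", "waist",
      "central", "deg/s"),
    r("180° Turn—Mean Angular Velocity", "segmentation", "waist",
      "central", "deg/s"),
    r("180° Turn—Trunk—Sagittal Mean Sway", "segmentation",
      "chest", "central", "deg"),
    r("WT—Trunk—Difference of Coronal Sway", "whole", "chest",
      "central", "deg"),
    r("Effective Trial Duration", "whole", "waist", "central", "s",
      scalar = TRUE),
    r("180° Turn—Total Duration", "whole", "waist", "central", "s",
      scalar = TRUE)
  )
}

# stance indicator per side within a section: TRUE between an IC and the next
# TC of that side; feet start and end a section in stance
stance_indicator <- function(sec, events_side) {
  n <- sec$end_sample - sec$start_sample
  st <- rep(TRUE, n)
  ev <- events_side[order(events_side$sample), , drop = FALSE]
  pos <- ev$sample - sec$start_sample + 1L # 1-based within section
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "TC") {
      nxt <- ev$sample[ev$type == "IC" & ev$sample > ev$sample[i]]
      to <- if (length(nxt)) min(nxt) - sec$start_sample else n
      st[pos[i]:to] <- FALSE
    }
  }
  st
}

#' Compute gait-cycle-based features for straight-walk sections
#'
#' Per-cycle values averaged across all cycles within each section. Gait
#' speed, cadence and step length use the known path length and the section's
#' IC events; double support is derived from bilateral IC/TC stance overlap.
#'
#' @param recording filtered `raw_recording`.
#' @param sections section table (only SW rows are used).
#' @param events,cycles output of [detect_gait_events()].
#' @param path_length_m straight-walk path length (protocol constant).
#' @return long data frame `base, side, kind, ordinal, value`.
#' @export
compute_cycle_features <- function(recording, sections, events, cycles,
                                   path_length_m = 3.6) {
  fs <- recording$fs
  out <- list()
  add <- function(base, side, ordinal, value)
    out[[length(out) + 1L]] <<- data.frame(base = base, side = side,
                                           kind = "SW", ordinal = ordinal,
                                           value = value)
  sw <- sections[sections$kind == "SW", , drop = FALSE]
  gx <- list(L = recording$sensors$shank_l$gyr_x,
             R = recording$sensors$shank_r$gyr_x)
  thx <- list(L = recording$sensors$thigh_l$gyr_x,
              R = recording$sensors$thigh_r$gyr_x)
  fx <- list(L = recording$sensors$foot_l$gyr_x,
             R = recording$sensors$foot_r$gyr_x)
  wx <- list(L = recording$sensors$wrist_l$gyr_x,
             R = recording$sensors$wrist_r$gyr_x)
  trunk <- recording$sensors$chest$gyr_x
  for (i in seq_len(nrow(sw))) {
    sec <- sw[i, ]
    dur <- (sec$end_sample - sec$start_sample) / fs
    ev <- events[events$kind == "SW" & events$ordinal == sec$ordinal, ,
                 drop = FALSE]
    n_ic <- sum(ev$type == "IC")
    add("Gait Speed", NA, sec$ordinal, path_length_m / dur)
    if (n_ic > 0L) {
      add("Cadence", NA, sec$ordinal, 60 * n_ic / dur)
      add("Step Length", NA, sec$ordinal, path_length_m / n_ic)
    }
    cyc <- cycles[cycles$kind == "SW" & cycles$ordinal == sec$ordinal, ,
                  drop = FALSE]
    if (nrow(cyc) == 0L) next
    # double support: bilateral stance overlap, averaged over all cycles
    st <- list(L = stance_indicator(sec, ev[ev$side == "L", , drop = FALSE]),
               R = stance_indicator(sec, ev[ev$side == "R", , drop = FALSE]))
    both <- st$L & st$R
    ds <- vapply(seq_len(nrow(cyc)), function(j) {
      a <- cyc$ic_start[j] - sec$start_sample + 1L
      b <- cyc$ic_end[j] - sec$start_sample
      100 * mean(both[a:b])
    }, 1.0)
    add("Double Support", NA, sec$ordinal, mean(ds))
    for (side in c("L", "R")) {
      cs <- cyc[cyc$side == side, , drop = FALSE]
      if (nrow(cs) == 0L) next
      rom <- vapply(seq_len(nrow(cs)), function(j)
        sum(pmax(gx[[side]][(cs$tc[j] + 1L):cs$ic_end[j]], 0)) / fs, 1.0)
      add("Shank—Swing RoM", side, sec$ordinal, mean(rom))
      mx <- function(x) mean(vapply(seq_len(nrow(cs)), function(j)
        max(x[(cs$ic_start[j] + 1L):cs$ic_end[j]]), 1.0))
      add("Thigh—Max Sagittal Angular Velocity", side, sec$ordinal,
          mx(thx[[side]]))
      add("Foot—Max Sagittal Angular Velocity", side, sec$ordinal,
          mx(fx[[side]]))
      arm <- vapply(seq_len(nrow(cs)), function(j)
        sum(pmax(wx[[side]][(cs$ic_start[j] + 1L):cs$ic_end[j]], 0)) / fs, 1.0)
      add("Arm—Swing RoM", side, sec$ordinal, mean(arm))
    }
    tav <- vapply(seq_len(nrow(cyc)), function(j)
      max(abs(trunk[(cyc$ic_start[j] + 1L):cyc$ic_end[j]])), 1.0)
    add("Trunk—Max Sagittal Angular Velocity", NA, sec$ordinal, mean(tav))
  }
  if (length(out) == 0L)
    return(data.frame(base = character(0), side = character(0),
                      kind = character(0), ordinal = integer(0),
                      value = numeric(0)))
  do.call(rbind, out)
}

#' Compute per-section (segmentation) features
#'
#' Section-level quantities that do not need gait-cycle detection: lumbar
#' sway change and trunk forward sway over straight walks; duration, step
#' count, heading-rate statistics and trunk sway of each 180 degree turn.
#'
#' @param angles an `angle_series`.
#' @param sections section table.
#' @param events event table from [detect_gait_events()].
#' @return long data frame `base, side, kind, ordinal, value`.
#' @export
compute_segment_features <- function(angles, sections, events) {
  fs <- angles$fs
  out <- list()
  add <- function(base, kind, ordinal, value)
    out[[length(out) + 1L]] <<- data.frame(base = base, side = NA,
                                           kind = kind, ordinal = ordinal,
                                           value = value)
  waist_sag <- angles$sensors$waist$sag_deg
  chest_sag <- angles$sensors$chest$sag_deg
  heading <- angles$sensors$waist$heading_deg
  for (i in seq_len(nrow(sections))) {
    sec <- sections[i, ]
    idx <- (sec$start_sample + 1L):sec$end_sample
    dur <- length(idx) / fs
    if (sec$kind == "SW") {
      add("SW—Lumbar—Difference of Sagittal Sway", "SW", sec$ordinal,
          waist_sag[idx[length(idx)]] - waist_sag[idx[1L]])
      add("Straight-Walking Duration", "SW", sec$ordinal, dur)
      add("Trunk—Forward Sway Max", "SW", sec$ordinal, min(chest_sag[idx]))
    } else {
      add("180° Turn—Duration", "T", sec$ordinal, dur)
      n_ic <- sum(events$kind == "T" & events$ordinal == sec$ordinal &
                    events$type == "IC")
      add("180° Turn—Steps", "T", sec$ordinal, n_ic)
      rate <- abs(c(0, diff(heading[idx])) * fs)
      rate <- smooth_ma(rate, fs, 0.15)
      add("180° Turn—Max Angular Velocity", "T", sec$ordinal,
          max(rate))
      add("180° Turn—Mean Angular Velocity", "T", sec$ordinal,
          mean(rate))
      add("180° Turn—Trunk—Sagittal Mean Sway", "T", sec$ordinal,
          mean(chest_sag[idx]))
    }
  }
  do.call(rbind, out)
}

#' Compute whole-assessment features
#'
#' Trunk coronal sway change per trial, plus two assessment-level scalars:
#' the effective trial duration (sum of all section durations) and the total
#' turning time (sum of the six turn durations).
#'
#' @param angles an `angle_series`.
#' @param sections section table.
#' @return long data frame `base, side, kind, ordinal, value`; scalars carry
#'   `ordinal = NA`.
#' @export
compute_whole_features <- function(angles, sections) {
  fs <- angles$fs
  chest_cor <- angles$sensors$chest$cor_deg
  out <- list()
  for (tr in sort(unique(sections$trial))) {
    rows <- sections[sections$trial == tr, , drop = FALSE]
    a <- min(rows$start_sample) + 1L
    b <- max(rows$end_sample)
    out[[length(out) + 1L]] <- data.frame(
      base = "WT—Trunk—Difference of Coronal Sway", side = NA,
      kind = "WT", ordinal = tr, value = chest_cor[b] - chest_cor[a])
  }
  durs <- (sections$end_sample - sections$start_sample) / fs
  out[[length(out) + 1L]] <- data.frame(
    base = "Effective Trial Duration", side = NA, kind = "WT", ordinal = NA,
    value = sum(durs))
  out[[length(out) + 1L]] <- data.frame(
    base = "180° Turn—Total Duration", side = NA, kind = "WT",
    ordinal = NA, value = sum(durs[sections$kind == "T"]))
  do.call(rbind, out)
}

#' Aggregate section values per base feature (construction step 1)
#'
#' For every base feature (and side, for bilateral ones) the maximum, minimum,
#' mean and mean of difference across its sections are computed, named
#' `-max, -min, -mean, -diff_mean`. `diff_mean` is the mean of absolute
#' consecutive-section differences (a variability measure); the signed
#' alternative, which telescopes to `(last - first)/(n - 1)`, is available via
#' `signed_diff_mean = TRUE`. Assessment-level scalars pass through unchanged.
#'
#' @param sfm long section feature matrix (`base, side, kind, ordinal, value`).
#' @param min_sections aggregates require at least this many non-missing
#'   section values (default 2); groups below it are dropped with a message.
#' @param signed_diff_mean use the signed consecutive-difference mean.
#' @return data frame `base, side, agg1, value`; pass-through scalars have
#'   `agg1 = NA`.
#' @export
construct_step1 <- function(sfm, min_sections = 2L, signed_diff_mean = FALSE) {
  sfm <- sfm[is.finite(sfm$value) | is.na(sfm$ordinal), , drop = FALSE]
  key <- paste(sfm$base, sfm$side, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- sfm[key == k, , drop = FALSE]
    base <- rows$base[1L]
    side <- rows$side[1L]
    v <- rows$value[order(rows$ordinal)]
    v <- v[is.finite(v)]
    if (all(is.na(rows$ordinal)) || nrow(rows) == 1L && is.na(rows$ordinal[1L])) {
      out[[length(out) + 1L]] <- data.frame(base = base, side = side,
                                            agg1 = NA, value = rows$value[1L])
      next
    }
    if (length(v) < min_sections) {
      message("feature '", base, "' side ", side,
              ": fewer than ", min_sections, " sections; aggregates skipped")
      next
    }
    d <- diff(v)
    dm <- if (signed_diff_mean) mean(d) else mean(abs(d))
    out[[length(out) + 1L]] <- data.frame(
      base = base, side = side,
      agg1 = c("max", "min", "mean", "diff_mean"),
      value = c(max(v), min(v), mean(v), dm))
  }
  do.call(rbind, out)
}

#' Collapse bilateral pairs into representative features (construction step 2)
#'
#' For each left/right pair of a base feature and step-1 aggregate, the
#' maximum, minimum and absolute difference are formed, named
#' `"Base-agg1 (max)" / "(min)" / "(diff)"`. Central features become
#' `"Base-agg1"`; scalars keep their base name. Pairs with one side missing
#' are skipped with a message.
#'
#' @param step1 output of [construct_step1()].
#' @return named numeric vector: the participant's constructed feature vector.
#' @export
construct_step2 <- function(step1) {
  out <- numeric(0)
  bil <- step1[!is.na(step1$side), , drop = FALSE]
  cen <- step1[is.na(step1$side), , drop = FALSE]
  for (i in seq_len(nrow(cen))) {
    nm <- if (is.na(cen$agg1[i])) cen$base[i] else
      paste0(cen$base[i], "—", cen$agg1[i])
    out[nm] <- cen$value[i]
  }
  if (nrow(bil)) {
    key <- paste(bil$base, bil$agg1, sep = "\r")
    for (k in unique(key)) {
      rows <- bil[key == k, , drop = FALSE]
      if (!setequal(rows$side, c("L", "R"))) {
        message("bilateral pair incomplete for '", rows$base[1L], "—",
                rows$agg1[1L], "'; skipped")
        next
      }
      l <- rows$value[rows$side == "L"]
      r <- rows$value[rows$side == "R"]
      stem <- paste0(rows$base[1L], "—", rows$agg1[1L])
      out[paste0(stem, " (max)")] <- max(l, r)
      out[paste0(stem, " (min)")] <- min(l, r)
      out[paste0(stem, " (diff)")] <- abs(l - r)
    }
  }
  out
}

#' Map constructed feature names back to their base features
#'
#' Strips the step-2 `" (max|min|diff)"` and step-1 `"-max|-min|-mean|
#' -diff_mean"` suffixes.
#'
#' @param names constructed feature names.
#' @return character vector of base names.
#' @export
constructed_base <- function(names) {
  b <- sub(" \\((max|min|diff)\\)$", "", names)
  sub("—(max|min|mean|diff_mean)$", "", b)
}

#' Extract the constructed feature vector for one recording
#'
#' Runs the full per-participant chain: zero-phase low-pass filtering,
#' orientation estimation, turn/straight segmentation, IC/TC event detection,
#' the three feature categories and the two construction steps.
#'
#' @param recording a `raw_recording`.
#' @param path_length_m protocol path length (m).
#' @param cutoff_hz,order low-pass settings.
#' @param ... passed to [segment_recording()].
#' @return list: `features` (named numeric vector), `sections`, `events`,
#'   `cycles`, `angles`.
#' @export
extract_participant_features <- function(recording, path_length_m = 3.6,
                                         cutoff_hz = 12, order = 4, ...) {
  filt <- lowpass(recording, cutoff_hz = cutoff_hz, order = order)
  angles <- estimate_orientation(filt)
  sections <- segment_recording(angles, filt, ...)
  ge <- detect_gait_events(filt, sections)
  sfm <- rbind(
    compute_cycle_features(filt, sections, ge$events, ge$cycles,
                           path_length_m = path_length_m),
    compute_segment_features(angles, sections, ge$events),
    compute_whole_features(angles, sections)
  )
  features <- construct_step2(construct_step1(sfm))
  list(features = features, sections = sections, events = ge$events,
       cycles = ge$cycles, angles = angles)
}
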