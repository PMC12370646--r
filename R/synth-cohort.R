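#' Simulate a cohort of shuttle-walk participants
#'
#' Draws severity profiles from the default skewed score mix (high scores
#' rare), simulates each participant's recording and ground truth, and rates
#' the five items with rater noise. Per-participant seeds are derived
#' deterministically from the cohort seed.
#'
#' @param n number of participants (>= 1).
#' @param cfg a [protocol_config()]; its `rng_seed` is overridden per
#'   participant by seeds derived from `seed`.
#' @param seed cohort seed.
#' @param rater_noise_sd SD of the rater noise applied when scoring items.
#' @param mix named list overriding the severity mix (`mu`, `sd`, `rho`), see
#'   [sample_severity_profiles()].
#' @param keep_recordings keep raw recordings in memory (`TRUE`, default) or
#'   only ground truth and labels (for large cohorts use
#'   [cohort_feature_table()] which streams participants).
#' @param labels_only skip signal synthesis entirely and return only profiles
#'   and the label table (fast path for studying the score mix).
#' @return an object of class `gait_cohort`: `labels` (data frame with
#'   `participant`, the five item columns, `age`, `sex`, `pd_duration`),
#'   `profiles`, `participants` (list with `recording` and `truth`), `cfg`,
#'   `seed`.
#' @export
simulate_cohort <- function(n, cfg = protocol_config(), seed = 1L,
                            rater_noise_sd = 0.3, mix = list(),
                            keep_recordings = TRUE, labels_only = FALSE) {
  stopifnot(n >= 1)
  profiles <- sample_severity_profiles(
    n, seed = derive_seed(seed, "profiles"),
    mu = mix$mu %||% -1.0, sd = mix$sd %||% 1.0, rho = mix$rho %||% 0.7
  )
  ids <- sprintf("P%03d", seq_len(n))
  participants <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    scores <- assign_item_scores(profiles[[i]], rater_noise_sd,
                                 seed = derive_seed(seed, "rater", i))
    labels[[i]] <- data.frame(
      participant = ids[i], t(scores),
      age = profiles[[i]]$age, sex = profiles[[i]]$sex,
      pd_duration = profiles[[i]]$pd_duration
    )
    if (labels_only) next
    cfg_i <- cfg
    cfg_i$rng_seed <- derive_seed(seed, "participant", i)
    sim <- simulate_participant(profiles[[i]], cfg_i, participant_id = ids[i])
    sim$truth$item_scores <- scores
    sim$truth$subscale <- sum(scores)
    if (!keep_recordings) sim$recording <- NULL
    participants[[i]] <- sim
  }
  structure(
    list(labels = do.call(rbind, labels), profiles = profiles,
         participants = participants, cfg = cfg, seed = seed),
    class = "gait_cohort"
  )
}

#' Write a cohort to disk in the package's CSV dialect
#'
#' One CSV per participant per sensor (`{participant}_{sensor}.csv` with
#' columns `t_s, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`), a `labels.csv`,
#' a ground-truth `sections.csv` (half-open, 0-based sample intervals) and a
#' `manifest.csv` indexing the files.
#'
#' @param cohort a `gait_cohort` with recordings kept.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (p in cohort$participants) {
    if (is.null(p$recording))
      stop("cohort was simulated with keep_recordings = FALSE")
    id <- p$recording$participant_id
    for (sn in names(p$recording$sensors)) {
      f <- file.path(dir, sprintf("%s_%s.csv", id, sn))
      data.table::fwrite(p$recording$sensors[[sn]], f)
      manifest[[length(manifest) + 1L]] <-
        data.frame(participant = id, sensor = sn, file = basename(f))
    }
  }
  data.table::fwrite(cohort$labels, file.path(dir, "labels.csv"))
  sec <- do.call(rbind, lapply(cohort$participants, function(p) {
    data.frame(participant = p$truth$participant_id,
               p$truth$sections[, c("trial", "kind", "ordinal", "start_sample",
                                    "end_sample")])
  }))
  data.table::fwrite(sec, file.path(dir, "sections.csv"))
  data.table::fwrite(do.call(rbind, manifest), file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read one participant's recording from a cohort directory
#'
#' @param dir cohort directory written by [write_cohort()].
#' @param participant participant id, e.g. `"P001"`.
#' @param fs sampling rate in Hz of the stored streams.
#' @return a `raw_recording`.
#' @export
read_recording <- function(dir, participant, fs = 100) {
  sensors <- lapply(sensor_layout(), function(sn) {
    f <- file.path(dir, sprintf("%s_%s.csv", participant, sn))
    if (!file.exists(f)) stop("missing sensor stream: ", f)
    as.data.frame(data.table::fread(f))
  })
  names(sensors) <- sensor_layout()
  n <- unique(vapply(sensors, nrow, 1L))
  if (length(n) != 1L) stop("sensor streams differ in length")
  structure(list(participant_id = participant, fs = fs, n_samples = n,
                 sensors = sensors),
            class = "raw_recording")
}

#' Validate a raw recording's invariants
#'
#' All ten sensors present with equal lengths, finite values, positive
#' sampling rate.
#'
#' @param recording a `raw_recording`.
#' @return `TRUE`, invisibly; stops otherwise.
#' @export
validate_recording <- function(recording) {
  stopifnot(inherits(recording, "raw_recording"))
  if (!setequal(names(recording$sensors), sensor_layout()))
    stop("recording must contain exactly the ten layout sensors")
  n <- vapply(recording$sensors, nrow, 1L)
  if (length(unique(n)) != 1L) stop("sensor streams differ in length")
  if (recording$fs <= 0) stop("fs must be > 0")
  ok <- vapply(recording$sensors, function(s)
    all(vapply(s, function(col) all(is.finite(col)), TRUE)), TRUE)
  if (!all(ok)) stop("non-finite values in sensor streams")
  invisible(TRUE)
}
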