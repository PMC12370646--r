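#' Kinematic targets implied by a severity profile
#'
#' Deterministic, monotone mapping from latent severities to the kinematic
#' quantities the generator realizes. Gait speed, step length and the swing
#' ranges of motion decrease with gait severity; turn duration and turn step
#' count increase with freezing and postural-instability severity; forward
#' trunk tilt magnitude increases with posture severity; trunk angular
#' velocity and arm swing decrease with chair-rise (axial) severity.
#' `turn_steps` is the continuous target; `turn_steps_realized` is the integer
#' step count actually placed in each turn.
#'
#' @param profile a [severity_profile()].
#' @return named list of kinematic targets (units in field names' docs).
#' @export
kinematic_targets <- function(profile) {
  stopifnot(inherits(profile, "severity_profile"))
  th <- profile$theta
  v <- 1.1 - 0.6 * th[["gait"]] # m/s
  sl <- 0.60 - 0.25 * th[["gait"]] # m
  ts <- 4 + 5 * th[["fog"]] + 3 * th[["stability"]] # steps per turn
  list(
    speed = v,
    step_length = sl,
    cadence = 60 * v / sl, # steps/min
    swing_rom = 70 - 40 * th[["gait"]], # deg per swing
    double_support = 0.20 + 0.15 * th[["stability"]], # fraction of cycle
    turn_duration = 2.0 + 1.2 * th[["stability"]] + 0.8 * th[["fog"]], # s
    turn_steps = ts,
    turn_steps_realized = as.integer(round(ts)),
    turn_step_rom = 12 - 4 * th[["fog"]], # deg, shuffling steps when freezing
    trunk_tilt = -(4 + 16 * th[["posture"]]), # deg, forward negative
    trunk_av = 22 - 14 * th[["chair"]], # deg/s
    arm_rom = 40 - 25 * th[["chair"]], # deg
    thigh_rom = 35 - 20 * th[["gait"]], # deg
    foot_rom = 85 - 45 * th[["gait"]], # deg
    sway_sw_diff = 1.0 + 2.5 * th[["stability"]], # deg per SW section
    sway_wt_cor = 0.8 + 2.0 * th[["stability"]], # deg per trial
    asym = 1 - 0.08 * th[["gait"]] # right-side amplitude multiplier
  )
}

#' Sensor layout of the assessment
#' @return character vector of the ten sensor names.
#' @export
sensor_layout <- function() {
  c("waist", "chest", "wrist_l", "wrist_r", "thigh_l", "thigh_r",
    "shank_l", "shank_r", "foot_l", "foot_r")
}

# normalized heading progress within a turn: raised-cosine ramp up, plateau,
# ramp down ("cosine trapezoid"); returns n values of cumulative progress in
# (0, 1].
turn_progress <- function(n, ramp_frac = 0.2) {
  u <- (seq_len(n) - 0.5) / n
  s <- ifelse(u < ramp_frac, (1 - cos(pi * u / ramp_frac)) / 2,
    ifelse(u > 1 - ramp_frac, (1 - cos(pi * (1 - u) / ramp_frac)) / 2, 1)
  )
  cumsum(s) / sum(s)
}

# add a half-sine bump with amplitude A over 1-based index support [s0, s1]
add_bump <- function(x, s0, s1, A) {
  if (s1 <= s0) return(x)
  idx <- max(1L, s0):min(length(x), s1)
  x[idx] <- x[idx] + A * sin(pi * (idx - s0) / (s1 - s0))
  x
}

# write one C1-smooth swing template into x (1-based indices): the signal
# descends from the stance baseline to a minimum of -depth exactly at `tc`,
# rises through a sin^2 swing lobe peaking at A, falls back to -depth exactly
# at `ic`, and recovers to the baseline. Smooth joins keep the zero-phase
# filtered signal's local minima at tc and ic.
write_swing <- function(x, tc, ic, A, depth, base, flank_w) {
  n <- length(x)
  d0 <- max(1L, tc - flank_w):tc
  x[d0] <- base - (base + depth) * (1 + cos(pi * (d0 - tc) / flank_w)) / 2
  sw <- tc:min(n, ic)
  u <- (sw - tc) / (ic - tc)
  x[sw] <- -depth + (A + depth) * sin(pi * u)^2
  d1 <- min(n, ic):min(n, ic + flank_w)
  x[d1] <- base - (base + depth) * (1 + cos(pi * (d1 - ic) / flank_w)) / 2
  x
}

#' Simulate one participant's shuttle-walk recording
#'
#' Kinematics-first synthesis: per-sensor angular-velocity and tilt
#' trajectories are generated directly from stride-periodic templates whose
#' amplitudes and timing follow [kinematic_targets()]; accelerometer channels
#' are the gravity projection of the tilt plus noise. Each trial is a
#' straight walk, a 180 degree turn, the return walk and a second 180 degree
#' turn, separated by standing pauses. The shank sagittal angular velocity is
#' stride-periodic with swing peaks flanked by local minima placed exactly at
#' the ground-truth terminal-contact (TC, before the peak) and initial-contact
#' (IC, after the peak) instants.
#'
#' @param profile a [severity_profile()].
#' @param cfg a [protocol_config()].
#' @param participant_id id string stored in the outputs.
#' @return list with elements `recording` (class `raw_recording`: `fs`,
#'   `n_samples`, `participant_id`, `sensors` - named list of data frames with
#'   columns `t_s, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`) and `truth`
#'   (class `ground_truth`: `sections`, `events` (0-based samples),
#'   `item_scores`, `subscale`, `generator_params`, `tilt` - true waist/chest
#'   angle series).
#' @export
simulate_participant <- function(profile, cfg = protocol_config(),
                                 participant_id = "P001") {
  stopifnot(inherits(profile, "severity_profile"),
            inherits(cfg, "protocol_config"))
  if (any(!is.finite(profile$theta))) stop("severity thetas must be finite")
  fs <- cfg$fs_hz
  dt <- 1 / fs
  kin <- kinematic_targets(profile)

  # --- timeline (samples, 0-based section boundaries, half-open) ------------
  pad0 <- round(0.8 * fs)
  gap <- round(1.5 * fs)
  pad_end <- round(0.8 * fs)
  n_sw <- round(cfg$path_length_m / kin$speed * fs)
  n_turn <- round(kin$turn_duration * fs)
  trial_len <- 2L * n_sw + 2L * n_turn

  sections <- do.call(rbind, lapply(seq_len(cfg$n_trials), function(tr) {
    base <- pad0 + (tr - 1L) * (trial_len + gap)
    data.frame(
      trial = tr, kind = c("SW", "T", "SW", "T"),
      start_sample = base + c(0L, n_sw, n_sw + n_turn, 2L * n_sw + n_turn),
      end_sample = base + c(n_sw, n_sw + n_turn, 2L * n_sw + n_turn, trial_len)
    )
  }))
  sections$ordinal <- stats::ave(seq_len(nrow(sections)), sections$kind,
                                 FUN = seq_along)
  N <- pad0 + cfg$n_trials * trial_len + (cfg$n_trials - 1L) * gap + pad_end
  t_s <- (seq_len(N) - 1L) * dt

  # --- gait events (ground truth, 0-based samples) --------------------------
  sw_dur <- n_sw / fs
  ev <- list()
  step_tab <- list() # per-step info used for signal templates
  for (si in seq_len(nrow(sections))) {
    sec <- sections[si, ]
    if (sec$kind == "SW") {
      n_steps <- max(2L, round(cfg$path_length_m / kin$step_length))
      step_dur <- sw_dur / n_steps
      swing <- (1 - kin$double_support) * step_dur
      k <- seq_len(n_steps) - 1L
      ic_t <- (k + 0.95) * step_dur
      sides <- rep_len(if (sec$ordinal %% 2L == 1L) c("L", "R") else c("R", "L"),
                       n_steps)
      st <- data.frame(
        side = sides,
        ic = sec$start_sample + round(ic_t * fs),
        tc = sec$start_sample + round((ic_t - swing) * fs),
        swing_s = swing, rom = kin$swing_rom, kind = "SW",
        ordinal = sec$ordinal, step_dur = step_dur
      )
    } else {
      n_steps <- kin$turn_steps_realized
      p <- (sec$end_sample - sec$start_sample) / fs / n_steps
      swing <- 0.7 * p
      k <- seq_len(n_steps) - 1L
      ic_t <- (k + 0.85) * p
      sides <- rep_len(c("L", "R"), n_steps)
      st <- data.frame(
        side = sides,
        ic = sec$start_sample + round(ic_t * fs),
        tc = sec$start_sample + round((ic_t - swing) * fs),
        swing_s = swing, rom = kin$turn_step_rom, kind = "T",
        ordinal = sec$ordinal, step_dur = p
      )
    }
    step_tab[[si]] <- st
    ev[[si]] <- data.frame(
      side = rep(st$side, 2L),
      type = rep(c("TC", "IC"), each = nrow(st)),
      sample = c(st$tc, st$ic), kind = st$kind[1L], ordinal = st$ordinal[1L]
    )
  }
  steps <- do.call(rbind, step_tab)
  events <- do.call(rbind, ev)
  events <- events[order(events$sample, events$side, events$type), ]
  events$time_s <- events$sample / fs
  rownames(events) <- NULL

  # --- shank / thigh / foot sagittal angular velocity -----------------------
  stance_base <- 8 # deg/s during active sections
  dip_depth <- 25 # deg/s below zero at TC/IC
  limb <- list()
  for (side in c("L", "R")) {
    amp_mul <- if (side == "R") kin$asym else 1
    shank <- thigh <- foot <- numeric(N)
    for (si in seq_len(nrow(sections))) {
      idx <- (sections$start_sample[si] + 1L):sections$end_sample[si]
      shank[idx] <- shank[idx] + stance_base
      thigh[idx] <- thigh[idx] + 5
      foot[idx] <- foot[idx] + 5
    }
    ss <- steps[steps$side == side, ]
    for (j in seq_len(nrow(ss))) {
      s <- ss[j, ]
      # swing amplitude giving integral(positive part) ~ the RoM target
      A <- amp_mul * (2 * s$rom / s$swing_s + dip_depth)
      flank_w <- max(3L, round(min(0.1, 0.25 * s$swing_s) * fs))
      shank <- write_swing(shank, s$tc + 1L, s$ic + 1L, A, dip_depth,
                           stance_base, flank_w)
      mul <- if (s$kind == "SW") 1 else 0.3
      s0 <- s$tc + 1L + round(0.15 * s$swing_s * fs)
      s1 <- s$ic + 1L - round(0.15 * s$swing_s * fs)
      supp <- 0.7 * s$swing_s
      thigh <- add_bump(thigh, s0, s1,
                        amp_mul * mul * pi * kin$thigh_rom / (2 * supp))
      foot <- add_bump(foot, s0, s1,
                       amp_mul * mul * pi * kin$foot_rom / (2 * supp))
    }
    limb[[side]] <- list(shank = shank, thigh = thigh, foot = foot)
  }

  # --- wrist sagittal angular velocity (arm swing, antiphase L/R) -----------
  wrist <- list(L = numeric(N), R = numeric(N))
  for (si in seq_len(nrow(sections))) {
    sec <- sections[si, ]
    idx <- (sec$start_sample + 1L):sec$end_sample
    st <- step_tab[[si]]
    stride <- 2 * st$step_dur[1L]
    mul <- if (sec$kind == "SW") 1 else 0.3
    C <- pi * kin$arm_rom / stride * mul
    ph <- 2 * pi * (t_s[idx] - t_s[idx[1L]]) / stride
    wrist$L[idx] <- C * sin(ph)
    wrist$R[idx] <- kin$asym * C * sin(ph + pi)
  }

  # --- waist / chest tilt and heading ---------------------------------------
  heading <- numeric(N)
  cur <- 0
  turn_rows <- which(sections$kind == "T")
  for (si in seq_len(nrow(sections))) {
    sec <- sections[si, ]
    idx <- (sec$start_sample + 1L):sec$end_sample
    if (sec$kind == "T") {
      dir <- if (sec$ordinal %% 2L == 1L) 1 else -1
      heading[idx] <- cur + dir * 180 * turn_progress(length(idx))
      cur <- cur + dir * 180
    } else {
      heading[idx] <- cur
    }
    # hold value until the next section starts
    nxt <- if (si < nrow(sections)) sections$start_sample[si + 1L] else N
    if (sec$end_sample < nxt) heading[(sec$end_sample + 1L):nxt] <- cur
  }

  waist_sag <- rep(-(3 + 8 * profile$theta[["posture"]]), N)
  for (si in seq_len(nrow(sections))) {
    sec <- sections[si, ]
    idx <- (sec$start_sample + 1L):sec$end_sample
    ramp <- seq(0, 1, length.out = length(idx))
    if (sec$kind == "SW") waist_sag[idx] <- waist_sag[idx] + kin$sway_sw_diff * ramp
    else waist_sag[idx] <- waist_sag[idx] + kin$sway_sw_diff * (1 - ramp)
  }
  waist_cor <- numeric(N)

  chest_sag <- rep(kin$trunk_tilt, N)
  for (si in seq_len(nrow(sections))) {
    sec <- sections[si, ]
    idx <- (sec$start_sample + 1L):sec$end_sample
    f_step <- 1 / step_tab[[si]]$step_dur[1L]
    B <- kin$trunk_av / (2 * pi * f_step)
    chest_sag[idx] <- chest_sag[idx] +
      B * sin(2 * pi * f_step * (t_s[idx] - t_s[idx[1L]]))
  }
  # coronal sway drifts across each trial, recovering between trials
  knot_t <- c(0)
  knot_v <- c(0)
  for (tr in seq_len(cfg$n_trials)) {
    rows <- sections[sections$trial == tr, ]
    knot_t <- c(knot_t, min(rows$start_sample), max(rows$end_sample))
    knot_v <- c(knot_v, 0, kin$sway_wt_cor)
  }
  knot_t <- c(knot_t, N)
  knot_v <- c(knot_v, 0)
  chest_cor <- stats::approx(knot_t, knot_v, xout = seq_len(N) - 1L,
                             rule = 2)$y

  # --- assemble sensors -----------------------------------------------------
  g <- 9.81
  deg2rad <- pi / 180
  grav_acc <- function(sag, cor) {
    phi <- sag * deg2rad
    psi <- cor * deg2rad
    cbind(acc_x = -g * sin(psi), acc_y = g * sin(phi) * cos(psi),
          acc_z = g * cos(phi) * cos(psi))
  }
  dderiv <- function(x) c(0, diff(x)) * fs

  mk_sensor <- function(acc, gx, gy, gz) {
    data.frame(t_s = t_s, acc_x = acc[, 1L], acc_y = acc[, 2L],
               acc_z = acc[, 3L], gyr_x = gx, gyr_y = gy, gyr_z = gz)
  }
  zero <- numeric(N)
  flat_acc <- cbind(acc_x = zero, acc_y = zero, acc_z = rep(g, N))
  sensors <- list(
    waist = mk_sensor(grav_acc(waist_sag, waist_cor), dderiv(waist_sag),
                      dderiv(waist_cor), dderiv(heading)),
    chest = mk_sensor(grav_acc(chest_sag, chest_cor), dderiv(chest_sag),
                      dderiv(chest_cor), dderiv(heading)),
    wrist_l = mk_sensor(flat_acc, wrist$L, zero, zero),
    wrist_r = mk_sensor(flat_acc, wrist$R, zero, zero),
    thigh_l = mk_sensor(flat_acc, limb$L$thigh, zero, zero),
    thigh_r = mk_sensor(flat_acc, limb$R$thigh, zero, zero),
    shank_l = mk_sensor(flat_acc, limb$L$shank, zero, zero),
    shank_r = mk_sensor(flat_acc, limb$R$shank, zero, zero),
    foot_l = mk_sensor(flat_acc, limb$L$foot, zero, zero),
    foot_r = mk_sensor(flat_acc, limb$R$foot, zero, zero)
  )

  if (cfg$noise_sd_gyro > 0 || cfg$noise_sd_acc > 0) {
    sensors <- with_seed(derive_seed(cfg$rng_seed, participant_id, "noise"), {
      lapply(sensors, function(s) {
        for (ch in c("acc_x", "acc_y", "acc_z"))
          s[[ch]] <- s[[ch]] + stats::rnorm(N, 0, cfg$noise_sd_acc)
        for (ch in c("gyr_x", "gyr_y", "gyr_z"))
          s[[ch]] <- s[[ch]] + stats::rnorm(N, 0, cfg$noise_sd_gyro)
        s
      })
    })
  }

  recording <- structure(
    list(participant_id = participant_id, fs = fs, n_samples = N,
         sensors = sensors),
    class = "raw_recording"
  )

  scores <- assign_item_scores(profile, rater_noise_sd = 0,
                               seed = derive_seed(cfg$rng_seed, participant_id,
                                                  "scores"))
  truth <- structure(
    list(
      participant_id = participant_id,
      sections = sections[, c("trial", "kind", "ordinal", "start_sample",
                              "end_sample")],
      events = data.frame(participant = participant_id,
                          events[, c("side", "type", "sample", "time_s",
                                     "kind", "ordinal")]),
      item_scores = scores,
      subscale = sum(scores),
      generator_params = kin,
      tilt = list(
        waist = data.frame(t_s = t_s, sag_deg = waist_sag, cor_deg = waist_cor,
                           heading_deg = heading),
        chest = data.frame(t_s = t_s, sag_deg = chest_sag, cor_deg = chest_cor,
                           heading_deg = heading)
      )
    ),
    class = "ground_truth"
  )
  list(recording = recording, truth = truth)
}
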