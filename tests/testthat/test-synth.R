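test_that("a default assessment yields 6 straight-walk and 6 turn sections", {
  p <- severity_profile()
  sim <- simulate_participant(p, clean_cfg())
  sec <- sim$truth$sections
  expect_equal(nrow(sec), 12L)
  expect_equal(sum(sec$kind == "SW"), 6L)
  expect_equal(sum(sec$kind == "T"), 6L)
  # SW and T alternate within each trial, starting with SW
  for (tr in 1:3) expect_equal(sec$kind[sec$trial == tr], c("SW", "T", "SW", "T"))
  # sections are disjoint, ordered, and partition each trial's active interval
  expect_true(all(diff(sec$start_sample) > 0))
  expect_true(all(sec$start_sample < sec$end_sample))
  within_trial <- split(sec, sec$trial)
  for (tt in within_trial)
    expect_equal(tt$start_sample[-1L], tt$end_sample[-4L])
})

test_that("simulation is deterministic and byte-identical after serialization", {
  p <- severity_profile(0.2, 0.5, 0.1, 0.4, 0.3)
  cfg <- protocol_config(rng_seed = 99L)
  s1 <- simulate_participant(p, cfg)
  s2 <- simulate_participant(p, cfg)
  expect_identical(s1$recording$sensors, s2$recording$sensors)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  data.table::fwrite(s1$recording$sensors$shank_l, f1)
  data.table::fwrite(s2$recording$sensors$shank_l, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("gait speed and swing RoM targets fall with gait severity", {
  cfg <- clean_cfg()
  lo <- simulate_participant(severity_profile(theta_gait = 0.1), cfg)
  hi <- simulate_participant(severity_profile(theta_gait = 0.9), cfg)
  expect_lt(hi$truth$generator_params$speed, lo$truth$generator_params$speed)
  expect_lt(hi$truth$generator_params$swing_rom,
            lo$truth$generator_params$swing_rom)
})

test_that("kinematic targets are strictly monotone in their driving theta", {
  grid <- seq(0, 1, length.out = 11)
  tg <- function(i, ...) kinematic_targets(severity_profile(...))[[i]]
  speed <- vapply(grid, function(g) tg("speed", theta_gait = g), 1.0)
  rom <- vapply(grid, function(g) tg("swing_rom", theta_gait = g), 1.0)
  expect_true(all(diff(speed) < 0))
  expect_true(all(diff(rom) < 0))
  for (drv in c("theta_fog", "theta_stability")) {
    args <- function(g) stats::setNames(list(g), drv)
    steps <- vapply(grid, function(g) do.call(tg, c(list("turn_steps"), args(g))), 1.0)
    dur <- vapply(grid, function(g) do.call(tg, c(list("turn_duration"), args(g))), 1.0)
    expect_true(all(diff(steps) > 0))
    expect_true(all(diff(dur) > 0))
  }
  tilt <- vapply(grid, function(g) tg("trunk_tilt", theta_posture = g), 1.0)
  expect_true(all(diff(abs(tilt)) > 0)) # forward tilt magnitude grows
  expect_true(all(tilt < 0)) # forward is negative
})

test_that("ground-truth gait events are ordered IC < TC < IC within cycles", {
  ev <- demo_sim()$truth$events
  for (side in c("L", "R")) {
    for (ord in 1:6) {
      e <- ev[ev$side == side & ev$kind == "SW" & ev$ordinal == ord, ]
      e <- e[order(e$sample), ]
      cyc <- assemble_cycles(e)
      expect_gt(nrow(cyc), 0L)
      expect_true(all(cyc$ic_start < cyc$tc & cyc$tc < cyc$ic_end))
      # consecutive cycles share the boundary IC
      if (nrow(cyc) > 1L)
        expect_equal(cyc$ic_start[-1L], cyc$ic_end[-nrow(cyc)])
    }
    e <- ev[ev$side == side, ]
    expect_true(all(diff(e$sample[order(e$sample)]) >= 0))
  }
})

test_that("item scores follow clip(round(4*theta + noise), 0, 4)", {
  expect_equal(unname(assign_item_scores(severity_profile(), 0, seed = 1)),
               rep(0L, 5))
  expect_equal(unname(assign_item_scores(severity_profile(1, 1, 1, 1, 1), 0,
                                         seed = 1)), rep(4L, 5))
  # Monte-Carlo oracle: theta 0.5, rater noise 0.5 -> mean score ~ 2.0
  p <- severity_profile(0.5, 0.5, 0.5, 0.5, 0.5)
  scores <- vapply(1:2000, function(s)
    mean(assign_item_scores(p, 0.5, seed = s)), 1.0) # 2000 x 5 draws
  expect_lt(abs(mean(scores) - 2.0), 0.05)
  expect_true(all(vapply(1:50, function(s)
    all(assign_item_scores(p, 0.5, seed = s) %in% 0:4), TRUE)))
  # determinism given seed
  expect_identical(assign_item_scores(p, 0.5, seed = 42),
                   assign_item_scores(p, 0.5, seed = 42))
})

test_that("cohort labels have the documented shape and score spread", {
  co <- simulate_cohort(225, seed = 7, labels_only = TRUE)
  expect_equal(nrow(co$labels), 225L)
  expect_true(all(item_names() %in% names(co$labels)))
  co2 <- simulate_cohort(200, seed = 7, labels_only = TRUE)
  for (it in item_names())
    expect_gte(length(unique(co2$labels[[it]])), 3L)
  # a cohort of one is still valid
  one <- simulate_cohort(1, clean_cfg(), seed = 3)
  expect_equal(nrow(one$labels), 1L)
  expect_equal(one$participants[[1]]$truth$subscale,
               sum(one$participants[[1]]$truth$item_scores))
})

test_that("invalid profiles and configurations are rejected", {
  expect_error(severity_profile(theta_gait = 1.2), "\\[0, 1\\]")
  expect_error(severity_profile(theta_gait = NaN), "finite")
  expect_error(protocol_config(fs_hz = 10), "stride dynamics")
  expect_error(protocol_config(path_length_m = -1), "path_length_m")
})

test_that("cohort files round-trip through the CSV dialect", {
  co <- simulate_cohort(2, clean_cfg(), seed = 5)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "P001_shank_l.csv")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  labs <- utils::read.csv(file.path(dir, "labels.csv"))
  expect_equal(names(labs)[1:6], c("participant", item_names()))
  sec <- utils::read.csv(file.path(dir, "sections.csv"))
  expect_equal(names(sec), c("participant", "trial", "kind", "ordinal",
                             "start_sample", "end_sample"))
  rec <- read_recording(dir, "P002", fs = 100)
  expect_true(validate_recording(rec))
  expect_equal(rec$sensors$waist$gyr_z,
               co$participants[[2]]$recording$sensors$waist$gyr_z,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
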