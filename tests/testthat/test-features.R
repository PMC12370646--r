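test_that("step-1 aggregates follow the declared arithmetic", {
  sfm <- data.frame(base = "Gait Speed", side = NA, kind = "SW",
                    ordinal = 1:6, value = c(1, 2, 3, 4, 5, 6))
  s1 <- construct_step1(sfm)
  v <- stats::setNames(s1$value, s1$agg1)
  expect_equal(v[["max"]], 6)
  expect_equal(v[["min"]], 1)
  expect_equal(v[["mean"]], 3.5)
  expect_equal(v[["diff_mean"]], 1.0)
  # constant sections
  sfm$value <- 7
  s2 <- construct_step1(sfm)
  expect_equal(sort(unique(s2$value[s2$agg1 != "diff_mean"])), 7)
  expect_equal(s2$value[s2$agg1 == "diff_mean"], 0)
  # signed alternative telescopes to (last - first)/(n - 1)
  sfm$value <- c(2, 9, 1, 5, 3, 12)
  s3 <- construct_step1(sfm, signed_diff_mean = TRUE)
  expect_equal(s3$value[s3$agg1 == "diff_mean"], (12 - 2) / 5)
})

test_that("a base feature is replaced by its four aggregate names", {
  sfm <- data.frame(base = "Gait Speed", side = c(rep("L", 6), rep("R", 6)),
                    kind = "SW", ordinal = rep(1:6, 2),
                    value = c(10, 10, 10, 10, 10, 10, 12, 12, 12, 12, 12, 12))
  s1 <- construct_step1(sfm)
  expect_equal(nrow(s1), 8L) # 2 sides x 4 aggregates
  feats <- construct_step2(s1)
  # pair collapse: 8 side-features -> 12 constructed features
  expect_length(feats, 12L)
  expect_equal(feats[["Gait Speed—mean (max)"]], 12)
  expect_equal(feats[["Gait Speed—mean (min)"]], 10)
  expect_equal(feats[["Gait Speed—mean (diff)"]], 2)
  expect_true(all(c("Gait Speed—max (max)", "Gait Speed—min (diff)",
                    "Gait Speed—diff_mean (min)") %in% names(feats)))
})

test_that("construction invariants hold on random section tables", {
  set.seed(9)
  for (rep in 1:25) {
    vals_l <- stats::rnorm(6, 10, 4)
    vals_r <- stats::rnorm(6, 10, 4)
    sfm <- rbind(
      data.frame(base = "B", side = "L", kind = "SW", ordinal = 1:6,
                 value = vals_l),
      data.frame(base = "B", side = "R", kind = "SW", ordinal = 1:6,
                 value = vals_r),
      data.frame(base = "C", side = NA, kind = "T", ordinal = 1:6,
                 value = stats::rnorm(6))
    )
    s1 <- construct_step1(sfm)
    # min <= mean <= max per base/side
    for (k in unique(paste(s1$base, s1$side))) {
      rows <- s1[which(paste(s1$base, s1$side) == k), ]
      v <- stats::setNames(rows$value, rows$agg1)
      expect_lte(v[["min"]], v[["mean"]])
      expect_lte(v[["mean"]], v[["max"]])
      expect_gte(v[["diff_mean"]], 0)
    }
    feats <- construct_step2(s1)
    for (agg in c("max", "min", "mean", "diff_mean")) {
      trip <- feats[paste0("B—", agg, c(" (max)", " (min)", " (diff)"))]
      expect_equal(unname(trip[1] - trip[2]), unname(trip[3]))
      expect_gte(unname(trip[3]), 0)
      # (diff) = |L - R| on the step-1 aggregates
      l <- s1$value[which(s1$side == "L" & s1$agg1 == agg)]
      r <- s1$value[which(s1$side == "R" & s1$agg1 == agg)]
      expect_equal(unname(trip[3]), abs(l - r))
    }
  }
})

test_that("one-sided bilateral pairs are skipped with a message", {
  sfm <- data.frame(base = "B", side = "L", kind = "SW", ordinal = 1:6,
                    value = 1:6)
  s1 <- construct_step1(sfm)
  expect_message(feats <- construct_step2(s1), "incomplete")
  expect_length(feats, 0L)
})

# synthetic angle series for direct section-feature checks
toy_angles <- function(n, fs = 100, waist_sag = rep(0, n),
                       chest_sag = rep(0, n), chest_cor = rep(0, n),
                       heading = rep(0, n)) {
  t_s <- (seq_len(n) - 1) / fs
  structure(list(fs = fs, participant_id = "T1", sensors = list(
    waist = data.frame(t_s = t_s, sag_deg = waist_sag, cor_deg = 0,
                       heading_deg = heading),
    chest = data.frame(t_s = t_s, sag_deg = chest_sag, cor_deg = chest_cor,
                       heading_deg = heading)
  )), class = "angle_series")
}

test_that("turn features follow their definitions on constructed sections", {
  fs <- 100
  n <- 600
  # turn of exactly 2.0 s (200 samples), heading ramps 180 degrees
  heading <- c(rep(0, 200), 180 * turn_progress(200), rep(180, 200))
  ang <- toy_angles(n, fs, heading = heading)
  sections <- data.frame(trial = 1, kind = "T", ordinal = 1,
                         start_sample = 200L, end_sample = 400L)
  events <- data.frame(side = rep(c("L", "R"), each = 4), type = "IC",
                       sample = as.integer(seq(210, 380, length.out = 8)),
                       kind = "T", ordinal = 1)
  sf <- compute_segment_features(ang, sections, events)
  val <- function(b) sf$value[sf$base == b]
  expect_equal(val("180° Turn—Duration"), 2.0)
  expect_equal(val("180° Turn—Steps"), 8)
  # sigmoid 180 degree ramp over 2 s: mean rate 90 deg/s, max above mean
  expect_equal(val("180° Turn—Mean Angular Velocity"), 90, tolerance = 2)
  expect_gt(val("180° Turn—Max Angular Velocity"),
            val("180° Turn—Mean Angular Velocity"))
})

test_that("sway features difference start and end of their window", {
  fs <- 100
  n <- 400
  ang <- toy_angles(n, fs, waist_sag = seq(-3, 1, length.out = n),
                    chest_cor = rep(2, n))
  sections <- data.frame(trial = 1, kind = c("SW", "T", "SW", "T"),
                         ordinal = c(1, 1, 2, 2),
                         start_sample = c(0L, 100L, 200L, 300L),
                         end_sample = c(100L, 200L, 300L, 400L))
  sf <- compute_segment_features(ang, sections, events = data.frame(
    side = character(0), type = character(0), sample = integer(0),
    kind = character(0), ordinal = integer(0)))
  sway <- sf[sf$base == "SW—Lumbar—Difference of Sagittal Sway", ]
  expect_equal(sway$value, rep(0.99 * 4 / 3.99, 2), tolerance = 1e-6)
  wt <- compute_whole_features(ang, sections)
  # coronal tilt identical at start and end -> difference 0
  expect_equal(wt$value[wt$base == "WT—Trunk—Difference of Coronal Sway"], 0)
  # all four sections of 1 s -> effective duration 4 s
  expect_equal(wt$value[wt$base == "Effective Trial Duration"], 4)
  expect_equal(wt$value[wt$base == "180° Turn—Total Duration"], 2)
})

test_that("extracted features hit the generator targets on clean data", {
  sim <- demo_sim()
  f <- demo_extract()$features
  gp <- sim$truth$generator_params
  expect_equal(unname(f[["Gait Speed—mean"]]), gp$speed, tolerance = 0.05)
  expect_equal(unname(f[["Double Support—mean"]]), 100 * gp$double_support,
               tolerance = 2)
  expect_equal(unname(f[["180° Turn—Duration—mean"]]), gp$turn_duration,
               tolerance = 0.3)
  expect_equal(unname(f[["Trunk—Max Sagittal Angular Velocity—mean"]]),
               gp$trunk_av, tolerance = 1)
  # identical cycles within a section: mean equals the single-cycle value,
  # so across sections with identical targets the spread is tiny
  expect_lt(f[["Shank—Swing RoM—diff_mean (max)"]] /
              f[["Shank—Swing RoM—mean (max)"]], 0.05)
})

test_that("cycle features fall with gait severity (noise off)", {
  mono <- single_theta_features("gait")
  rho_rom <- stats::cor(mono$theta,
                        mono$features[, "Shank—Swing RoM—mean (max)"],
                        method = "spearman")
  rho_speed <- stats::cor(mono$theta, mono$features[, "Gait Speed—mean"],
                          method = "spearman")
  expect_lte(rho_rom, -0.9)
  expect_lte(rho_speed, -0.9)
})

test_that("turn step count rises with freezing severity (noise off)", {
  mono <- single_theta_features("fog")
  rho <- stats::cor(mono$theta, mono$features[, "180° Turn—Steps—mean"],
                    method = "spearman")
  expect_gte(rho, 0.9)
})
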