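# shared fixtures, computed lazily once per test run
.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

clean_cfg <- function(...) {
  protocol_config(noise_sd_gyro = 0, noise_sd_acc = 0, ...)
}

# one mid-severity noise-free participant, reused across tests
demo_sim <- function() {
  get_fixture("demo_sim", {
    p <- severity_profile(0.3, 0.4, 0.5, 0.3, 0.6)
    simulate_participant(p, clean_cfg(rng_seed = 7L))
  })
}

demo_extract <- function() {
  get_fixture("demo_extract", extract_participant_features(demo_sim()$recording))
}

# build a raw_recording from flat gravity-aligned sensors, with overrides
# given as sensors$<name>$<channel> vectors
make_recording <- function(n, fs = 100, overrides = list(), id = "T001") {
  t_s <- (seq_len(n) - 1) / fs
  flat <- data.frame(t_s = t_s, acc_x = 0, acc_y = 0, acc_z = 9.81,
                     gyr_x = 0, gyr_y = 0, gyr_z = 0)
  sensors <- stats::setNames(rep(list(flat), 10), sensor_layout())
  for (sn in names(overrides)) {
    for (ch in names(overrides[[sn]])) sensors[[sn]][[ch]] <- overrides[[sn]][[ch]]
  }
  structure(list(participant_id = id, fs = fs, n_samples = n,
                 sensors = sensors),
            class = "raw_recording")
}

# independent brute-force oracle: strict local minima with plateau resolved to
# the leftmost sample, by exhaustive scan
brute_minima <- function(x) {
  out <- integer(0)
  i <- 2L
  n <- length(x)
  while (i < n) {
    if (x[i] < x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] > x[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# independent brute-force IC/TC oracle: nearest strict local minimum before
# and after each peak
brute_ic_tc <- function(x, peaks0) {
  mins0 <- brute_minima(x) - 1L
  out <- list()
  for (p in sort(peaks0)) {
    b <- mins0[mins0 < p]
    a <- mins0[mins0 > p]
    if (length(b)) out[[length(out) + 1L]] <- data.frame(type = "TC", sample = max(b))
    if (length(a)) out[[length(out) + 1L]] <- data.frame(type = "IC", sample = min(a))
  }
  if (!length(out)) return(data.frame(type = character(0), sample = integer(0)))
  ev <- unique(do.call(rbind, out))
  ev[order(ev$sample, ev$type), , drop = FALSE]
}

# FFT amplitude of the component at frequency f
fft_amplitude <- function(x, f, fs) {
  n <- length(x)
  2 * abs(stats::fft(x))[round(f * n / fs) + 1L] / n
}

# cohorts in which a single severity varies and the others stay at 0.3,
# for monotonic feature-severity checks (noise off)
single_theta_features <- function(which_theta, n = 50) {
  get_fixture(paste0("mono_", which_theta, "_", n), {
    thetas <- seq(0, 1, length.out = n)
    feats <- vector("list", n)
    for (i in seq_len(n)) {
      th <- rep(0.3, 5)
      names(th) <- c("chair", "gait", "fog", "stability", "posture")
      th[which_theta] <- thetas[i]
      p <- severity_profile(th[["chair"]], th[["gait"]], th[["fog"]],
                            th[["stability"]], th[["posture"]])
      sim <- simulate_participant(p, clean_cfg(rng_seed = 100L + i))
      feats[[i]] <- extract_participant_features(sim$recording)$features
    }
    nms <- unique(unlist(lapply(feats, names)))
    mat <- matrix(NA_real_, n, length(nms), dimnames = list(NULL, nms))
    for (i in seq_len(n)) mat[i, names(feats[[i]])] <- feats[[i]]
    list(theta = thetas, features = mat)
  })
}

# fabricate label tables quickly (profiles + rater only, no signals)
label_table <- function(n, seed = 1L, rater_noise_sd = 0.3) {
  simulate_cohort(n, seed = seed, rater_noise_sd = rater_noise_sd,
                  labels_only = TRUE)$labels
}
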