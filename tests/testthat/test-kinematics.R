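make_recording <- function(times, wrist, thumb = NULL, index = NULL,
                           switch_release = times[1]) {
  n <- length(times)
  flat <- cbind(rep(0, n), rep(0, n), rep(0, n))
  apart <- cbind(rep(30, n), rep(0, n), rep(0, n))
  structure(list(subject_id = "S1", session = "PRE", block = NA,
                 trial_index = 1L, sample_times = times, fs = 1 / diff(times)[1],
                 wrist_xyz = wrist, thumb_xyz = thumb %||% flat,
                 index_xyz = index %||% apart,
                 switch_release_time = switch_release),
            class = "trial_recording")
}

test_that("constant and uniform motion give the expected profiles", {
  times <- seq(0, 2, by = 0.005)
  n <- length(times)
  still <- make_recording(times, cbind(rep(5, n), rep(-3, n), rep(2, n)))
  prof <- differentiate_and_smooth(still)
  # residual filter transients are physically negligible
  expect_lt(max(abs(prof$tangential_velocity)), 1e-3)
  expect_lt(max(abs(prof$tangential_acceleration)), 0.1)
  expect_equal(prof$grip_aperture, rep(30, n), tolerance = 1e-6)

  # straight line at 100 mm/s: interior plateau within 0.1%
  line <- make_recording(times, cbind(100 * times, rep(0, n), rep(0, n)))
  prof <- differentiate_and_smooth(line)
  mid <- seq(round(n * 0.3), round(n * 0.7))
  expect_lt(max(abs(prof$tangential_velocity[mid] - 100)) / 100, 0.001)
})

test_that("minimum-jerk extrema match the dense numerical oracle within 1%", {
  rows <- data.frame(vel_amplitude = 1.875 * 350 / 1, movement_time = 1000,
                     mga = 70, mga_latency = 600)
  rec <- generate_trajectories(rows, seed = 3, noise_sd = 0)[[1]]
  prof <- differentiate_and_smooth(rec)
  oracle <- minjerk_oracle(350, 1)
  expect_lt(abs(max(prof$tangential_velocity) - oracle$vel_peak) /
              oracle$vel_peak, 0.01)
  expect_lt(abs(max(prof$tangential_acceleration) - oracle$acc_peak) /
              oracle$acc_peak, 0.01)
  expect_lt(abs(min(prof$tangential_acceleration) + oracle$dec_peak) /
              oracle$dec_peak, 0.01)
})

test_that("input validation rejects short, non-uniform and NaN recordings", {
  times <- seq(0, 2, by = 0.005)
  n <- length(times)
  w <- cbind(rep(0, n), rep(0, n), rep(0, n))
  short <- make_recording(times[1:5], w[1:5, ])
  expect_error(differentiate_and_smooth(short), "too short")
  jitter <- make_recording(c(times[1:100], times[101:n] + 0.003), w)
  expect_error(differentiate_and_smooth(jitter), "non-uniform")
  w_bad <- w; w_bad[50, 2] <- NA
  expect_error(differentiate_and_smooth(make_recording(times, w_bad)),
               "NaN/NA.*50")
})

test_that("onset detection follows the threshold-after-switch-release rule", {
  times <- seq(0, 1, by = 0.005)
  # speed ramp crossing 10 mm/s exactly at sample 41 (t = 0.200); integer
  # arithmetic keeps the crossing exact
  speed <- pmax(0, (seq_along(times) - 21) * 0.5)
  prof <- make_profile(times, speed)
  expect_equal(detect_onset(prof, 0), times[41])
  # movement entirely before switch release is not an onset
  speed2 <- ifelse(times < 0.3, 50, 0)
  expect_error(detect_onset(make_profile(times, speed2), 0.5),
               "no movement detected")
  expect_error(detect_onset(prof, 5), "outside the recorded span")

  # minimum-jerk starting at switch release: onset at the analytic root of
  # 30 D tau^2 (1-tau)^2 / T = 10, i.e. 0.0319 s for D = 350 mm, T = 1 s
  rows <- data.frame(vel_amplitude = 656.25, movement_time = 1000,
                     mga = 70, mga_latency = 600)
  rec <- generate_trajectories(rows, seed = 2, noise_sd = 0,
                               switch_release = 0.1, reaction_time = 0)[[1]]
  prof <- differentiate_and_smooth(rec)
  onset <- detect_onset(prof, rec$switch_release_time)
  oracle_onset <- 0.1 + minjerk_oracle(350, 1)$onset
  expect_lt(abs(onset - oracle_onset), 0.0075)  # one sample + smoothing bound
})

test_that("grasp end detection finds the stabilised grasp", {
  times <- seq(0, 2, by = 0.005)
  # aperture opens, closes, then is constant from t = 1.2 with the wrist still
  ap <- aperture_stub <- numeric(length(times))
  ap[times <= 0.6] <- 30 + 40 * times[times <= 0.6] / 0.6
  closing <- times > 0.6 & times <= 1.2
  ap[closing] <- 70 - 45 * (times[closing] - 0.6) / 0.6
  ap[times > 1.2] <- 25
  speed <- ifelse(times < 1.0, 400, 0)
  prof <- make_profile(times, speed, aperture = ap)
  end <- detect_grasp_end(prof, onset_time = 0.05)
  expect_lt(abs(end - 1.2), 0.011)

  # monotonically opening grip to the last sample: no closure
  prof2 <- make_profile(times, speed, aperture = 30 + 20 * times)
  expect_error(detect_grasp_end(prof2, onset_time = 0.05), "no closure")

  # closure that never stabilises before the recording ends
  ap3 <- ifelse(times <= 1, 30 + 40 * times, 70 - 100 * (times - 1))
  prof3 <- make_profile(times, rep(400, length(times)), aperture = ap3)
  expect_error(detect_grasp_end(prof3, onset_time = 0.05),
               "no grasp end detected")
})

test_that("extraction is scale-equivariant and symmetric for minimum jerk", {
  rows <- data.frame(vel_amplitude = 700, movement_time = 1100,
                     mga = 75, mga_latency = 650)
  rec <- generate_trajectories(rows, seed = 4, noise_sd = 0)[[1]]
  pars <- extract_trial_parameters(rec)

  # time-reversal symmetry of minimum jerk: acceleration and deceleration
  # peaks agree within 0.5%
  expect_lt(abs(pars$acc_amplitude - pars$dec_amplitude) / pars$acc_amplitude,
            0.005)

  # scaling all positions by k (with detection thresholds expressed in the
  # same scaled units) scales amplitudes by k and leaves latencies unchanged
  k <- 2.5
  rec2 <- rec
  rec2$wrist_xyz <- rec$wrist_xyz * k
  rec2$thumb_xyz <- rec$thumb_xyz * k
  rec2$index_xyz <- rec$index_xyz * k
  pars2 <- extract_trial_parameters(rec2, config = list(
    onset_threshold = 10 * k,
    end = list(aperture_rate_threshold = 5 * k, speed_threshold = 20 * k)))
  for (p in c("acc_amplitude", "vel_amplitude", "dec_amplitude", "mga"))
    expect_equal(pars2[[p]], k * pars[[p]], tolerance = 1e-6)
  for (p in c("acc_latency", "vel_latency", "dec_latency", "mga_latency",
              "movement_time"))
    expect_equal(pars2[[p]], pars[[p]], tolerance = 1e-9)
})

test_that("with filtering bypassed and no noise, peaks match analytic values", {
  rows <- data.frame(vel_amplitude = 656.25, movement_time = 1000,
                     mga = 70, mga_latency = 600)
  rec <- generate_trajectories(rows, seed = 5, noise_sd = 0)[[1]]
  pars <- extract_trial_parameters(rec, config = list(filter = list(bypass = TRUE)))
  # discretisation-level agreement: O(dt) on a 200 Hz grid
  expect_lt(abs(pars$vel_amplitude - 656.25) / 656.25, 0.005)
  expect_lt(abs(pars$acc_amplitude - 10 / sqrt(3) * 350) / 2020.7, 0.01)
})
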