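# Minimum-jerk kernel: closed forms for a point-to-point reach of distance D
# (mm) and duration T (s). tau = (t - t0)/T in [0,1].
minjerk_pos <- function(tau, D) D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
minjerk_speed <- function(tau, D, T) (D / T) * 30 * tau^2 * (1 - tau)^2
minjerk_accel <- function(tau, D, T) (D / T^2) * (60 * tau - 180 * tau^2 + 120 * tau^3)

# first tau in (0, 1/2) where the minimum-jerk speed reaches `threshold` mm/s
minjerk_onset_tau <- function(D, T, threshold = 10) {
  if (minjerk_speed(0.5, D, T) <= threshold)
    stop("peak velocity does not exceed the onset threshold", call. = FALSE)
  stats::uniroot(function(tau) minjerk_speed(tau, D, T) - threshold,
                 c(1e-9, 0.5), tol = 1e-12)$root
}

# raised-cosine grip aperture: opens from a0 to mga at t_mga, closes to a1 at
# t_close, constant outside [t_open, t_close]
aperture_profile <- function(t, t_open, t_mga, t_close, a0, mga, a1) {
  a <- numeric(length(t))
  a[t <= t_open] <- a0
  up <- t > t_open & t <= t_mga
  a[up] <- a0 + (mga - a0) / 2 * (1 - cos(pi * (t[up] - t_open) / (t_mga - t_open)))
  dn <- t > t_mga & t <= t_close
  a[dn] <- a1 + (mga - a1) / 2 * (1 + cos(pi * (t[dn] - t_mga) / (t_close - t_mga)))
  a[t > t_close] <- a1
  a
}

#' Embed trial parameters into synthetic marker trajectories
#'
#' Builds one \code{trial_recording} per input row: the wrist follows a
#' minimum-jerk path along the sagittal axis whose distance and duration are
#' chosen so that the row's peak velocity and movement time are realised
#' (peak velocity of a minimum-jerk reach is \eqn{1.875 D/T}); the
#' thumb--index distance follows a single-peaked raised-cosine profile that
#' attains the row's MGA at the row's MGA latency and closes onto the object
#' at movement end. Gaussian measurement noise (default 0.01 mm, a typical
#' motion-capture resolution) is added to every coordinate.
#'
#' Each recording carries a \code{ground_truth} list with the nine parameters
#' implied by the continuous (pre-noise, pre-sampling) profiles, computed with
#' the same operational definitions the extractor uses: onset at the 10 mm/s
#' velocity threshold after switch release, latencies relative to that onset,
#' grasp end at aperture stabilisation (closed forms where available, a dense
#' 10 kHz evaluation for the end rule). Round-trip tests compare extraction
#' against these values.
#'
#' @param rows Data.frame with columns \code{vel_amplitude} (mm/s),
#'   \code{movement_time} (ms), \code{mga} (mm), \code{mga_latency} (ms);
#'   optional \code{acc_latency}/\code{dec_latency} are checked for the
#'   single-peak ordering, and identification columns (\code{subject_id},
#'   \code{session}, \code{block}, \code{trial}) are carried through.
#' @param seed Integer seed for the measurement noise.
#' @param fs Sampling rate in Hz (default 200).
#' @param noise_sd Marker noise SD in mm (default 0.01).
#' @param switch_release Time of switch release in s from recording start.
#' @param reaction_time Delay from switch release to motion start in s.
#' @param start_aperture,final_aperture Grip aperture (mm) at rest and on the
#'   object.
#' @param tail Still time appended after movement end in s.
#' @return A list of \code{trial_recording} objects.
#' @examples
#' rows <- data.frame(vel_amplitude = 656.25, movement_time = 1000,
#'                    mga = 70, mga_latency = 600)
#' rec <- generate_trajectories(rows, seed = 1)[[1]]
#' rec$ground_truth$vel_amplitude
#' @export
generate_trajectories <- function(rows, seed = 1L, fs = 200,
                                  noise_sd = 0.01,
                                  switch_release = 0.1,
                                  reaction_time = 0.05,
                                  start_aperture = 30,
                                  final_aperture = 25,
                                  tail = 0.4) {
  check_columns(rows, c("vel_amplitude", "movement_time", "mga", "mga_latency"),
                "trial parameter rows")
  if (all(c("acc_latency", "vel_latency", "dec_latency") %in% names(rows))) {
    bad <- rows$vel_latency <= rows$acc_latency | rows$vel_latency >= rows$dec_latency
    if (any(bad))
      stop(sprintf("row(s) %s violate the latency ordering acc < vel < dec",
                   paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  check_number(fs, "fs", lower = 20)
  check_number(noise_sd, "noise_sd", lower = 0)

  with_seed(seed, {
    lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      T <- r$movement_time / 1000
      if (T <= 0) stop("movement_time must be positive", call. = FALSE)
      D <- r$vel_amplitude * T / 1.875
      t0 <- switch_release + reaction_time
      tau_on <- minjerk_onset_tau(D, T)
      t_on <- t0 + tau_on * T
      t_mga <- t_on + r$mga_latency / 1000
      if (t_mga <= t0 || t_mga >= t0 + T)
        stop("mga_latency must place the aperture peak inside the movement",
             call. = FALSE)

      dur <- t0 + T + tail
      times <- seq(0, dur, by = 1 / fs)
      tau <- pmin(pmax((times - t0) / T, 0), 1)
      wrist_y <- minjerk_pos(tau, D)
      ap <- aperture_profile(times, t0, t_mga, t0 + T,
                             start_aperture, r$mga, final_aperture)

      # analytic / dense-grid ground truth under the extractor's definitions
      tau_acc <- (3 - sqrt(3)) / 6
      tau_dec <- (3 + sqrt(3)) / 6
      dense_t <- seq(t_mga, dur, by = 1e-4)
      dense_ap <- aperture_profile(dense_t, t0, t_mga, t0 + T,
                                   start_aperture, r$mga, final_aperture)
      ap_rate <- c(diff(dense_ap) / 1e-4, 0)
      dense_tau <- pmin(pmax((dense_t - t0) / T, 0), 1)
      dense_speed <- minjerk_speed(dense_tau, D, T)
      # last violation of either stabilisation condition; end is just after it
      ok <- abs(ap_rate) < 5 & dense_speed < 20
      t_end <- if (all(ok)) dense_t[1] else dense_t[max(which(!ok)) + 1L]

      ground_truth <- list(
        acc_latency = (tau_acc - tau_on) * T * 1000,
        acc_amplitude = (10 / sqrt(3)) * D / T^2,
        vel_latency = (0.5 - tau_on) * T * 1000,
        vel_amplitude = 1.875 * D / T,
        dec_latency = (tau_dec - tau_on) * T * 1000,
        dec_amplitude = (10 / sqrt(3)) * D / T^2,
        mga_latency = r$mga_latency,
        mga = r$mga,
        movement_time = (t_end - t_on) * 1000,
        onset_time = t_on, reach_distance = D
      )

      n <- length(times)
      noise <- function() stats::rnorm(n, 0, noise_sd)
      wrist <- cbind(x = noise(), y = wrist_y + noise(), z = noise())
      hand_y <- wrist_y + 60  # marker offset of the grip point along the reach
      thumb <- cbind(x = ap / 2 + noise(), y = hand_y + noise(), z = noise())
      index <- cbind(x = -ap / 2 + noise(), y = hand_y + noise(), z = noise())

      structure(
        list(subject_id = as.character(r$subject_id %||% sprintf("S%04d", i)),
             session = as.character(r$session %||% NA_character_),
             block = r$block %||% NA_integer_,
             trial_index = as.integer(r$trial %||% i),
             sample_times = times, fs = fs,
             wrist_xyz = wrist, thumb_xyz = thumb, index_xyz = index,
             switch_release_time = switch_release,
             ground_truth = ground_truth),
        class = "trial_recording"
      )
    })
  })
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> subject %s, %s trial %d: %d samples @ %g Hz, switch release %.3f s\n",
              x$subject_id, x$session %||% "?", x$trial_index,
              length(x$sample_times), x$fs, x$switch_release_time))
  invisible(x)
}
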