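#' Differentiate and smooth a trial recording
#'
#' Computes the wrist tangential velocity (speed), tangential acceleration
#' (time derivative of speed) and the grip aperture (Euclidean thumb--index
#' distance) from the marker positions of one trial. Positions are low-pass
#' filtered with a zero-phase Butterworth filter (filtered forwards and
#' backwards, so no latency bias is introduced) before central-difference
#' differentiation; the speed series is filtered again before the
#' acceleration is taken, which suppresses the noise amplification of double
#' differentiation while leaving the slow reach dynamics untouched.
#'
#' @param recording A \code{trial_recording} (see
#'   \code{\link{generate_trajectories}} / \code{\link{read_trial_recording}}).
#' @param filter_config List: \code{cutoff} (Hz, default 10), \code{order}
#'   (default 4), \code{bypass} (logical, default FALSE disables all
#'   filtering).
#' @return A \code{kinematic_profile}: list with \code{sample_times},
#'   \code{tangential_velocity} (mm/s, >= 0), \code{tangential_acceleration}
#'   (mm/s^2, signed), \code{grip_aperture} (mm) and \code{fs}.
#' @export
differentiate_and_smooth <- function(recording, filter_config = list()) {
  stopifnot(is.list(recording))
  times <- recording$sample_times
  if (length(times) < 10) stop("recording too short (< 10 samples)", call. = FALSE)
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-12)
    stop("non-uniform sampling", call. = FALSE)
  dt <- stats::median(dt)
  fs <- 1 / dt

  mats <- list(wrist = recording$wrist_xyz, thumb = recording$thumb_xyz,
               index = recording$index_xyz)
  for (m in names(mats)) {
    bad <- which(!stats::complete.cases(mats[[m]]))
    if (length(bad))
      stop(sprintf("NaN/NA samples in %s marker at indices: %s", m,
                   paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }

  cutoff <- filter_config$cutoff %||% 10
  ord <- filter_config$order %||% 4
  bypass <- isTRUE(filter_config$bypass)
  bf <- if (!bypass) signal::butter(ord, cutoff / (fs / 2), type = "low")
  # filtfilt starts from zero initial conditions; pad with odd reflections of
  # the endpoints so level and slope are preserved and no edge transient
  # leaks into the recording
  zerophase <- function(col) {
    n <- length(col)
    np <- min(n - 1L, as.integer(ceiling(fs)))
    head_pad <- 2 * col[1] - col[(np + 1):2]
    tail_pad <- 2 * col[n] - col[(n - 1):(n - np)]
    out <- signal::filtfilt(bf, c(head_pad, col, tail_pad))
    out[(np + 1):(np + n)]
  }
  smooth_cols <- function(x) {
    if (bypass) return(x)
    apply(x, 2, zerophase)
  }
  wrist <- smooth_cols(mats$wrist)
  thumb <- smooth_cols(mats$thumb)
  index <- smooth_cols(mats$index)

  cgrad <- function(y) {  # central differences, one-sided at the ends
    n <- length(y)
    g <- numeric(n)
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
    g[1] <- (y[2] - y[1]) / dt
    g[n] <- (y[n] - y[n - 1]) / dt
    g
  }
  vel <- apply(wrist, 2, cgrad)
  speed <- sqrt(rowSums(vel^2))
  # the norm re-injects high-frequency noise; a second zero-phase pass keeps
  # flat extrema well conditioned before peak finding and differentiation
  speed_s <- if (bypass) speed else pmax(0, zerophase(speed))
  accel <- cgrad(speed_s)
  aperture <- sqrt(rowSums((thumb - index)^2))

  structure(list(sample_times = times,
                 tangential_velocity = speed_s,
                 tangential_acceleration = accel,
                 grip_aperture = aperture,
                 fs = fs),
            class = "kinematic_profile")
}

#' Detect movement onset
#'
#' Movement onset is the first sample at or after switch release where the
#' wrist tangential velocity reaches the threshold (10 mm/s by default).
#'
#' @param profile A \code{kinematic_profile}.
#' @param switch_release_time Switch release time in s (must lie within the
#'   recording).
#' @param threshold Velocity threshold in mm/s.
#' @return Onset time in s.
#' @export
detect_onset <- function(profile, switch_release_time, threshold = 10) {
  stopifnot(inherits(profile, "kinematic_profile"))
  times <- profile$sample_times
  if (switch_release_time < times[1] || switch_release_time > times[length(times)])
    stop("switch_release_time outside the recorded span", call. = FALSE)
  eligible <- times >= switch_release_time & profile$tangential_velocity >= threshold
  if (!any(eligible)) stop("no movement detected", call. = FALSE)
  times[which(eligible)[1]]
}

#' Detect the end of the grasp
#'
#' The grasp end is the first time after the grip-closure phase (after the
#' aperture maximum) at which the grip aperture has stabilised -- its rate of
#' change stays below \code{aperture_rate_threshold} for at least
#' \code{dwell} seconds -- while the wrist is essentially still (speed below
#' \code{speed_threshold}). The returned time is the start of the qualifying
#' dwell window, i.e. before any lift of the object.
#'
#' @param profile A \code{kinematic_profile}.
#' @param onset_time Movement onset in s (search starts after it).
#' @param end_config List: \code{aperture_rate_threshold} (mm/s, default 5),
#'   \code{dwell} (s, default 0.05), \code{speed_threshold} (mm/s, default 20).
#' @return Grasp end time in s.
#' @export
detect_grasp_end <- function(profile, onset_time, end_config = list()) {
  stopifnot(inherits(profile, "kinematic_profile"))
  ap_thr <- end_config$aperture_rate_threshold %||% 5
  dwell <- end_config$dwell %||% 0.05
  spd_thr <- end_config$speed_threshold %||% 20
  times <- profile$sample_times
  n <- length(times)
  dt <- 1 / profile$fs
  on_idx <- which(times >= onset_time)[1]
  ap <- profile$grip_aperture
  mga_idx <- on_idx - 1L + which.max(ap[on_idx:n])
  if (mga_idx >= n - 1L)
    stop("no closure: grip aperture still opening at the end of the recording",
         call. = FALSE)
  rate <- c(diff(ap) / dt, 0)
  dwell_n <- max(1L, ceiling(dwell / dt))
  speed <- profile$tangential_velocity
  for (i in (mga_idx + 1L):(n - dwell_n)) {
    if (speed[i] < spd_thr && all(abs(rate[i:(i + dwell_n)]) < ap_thr))
      return(times[i])
  }
  stop("no grasp end detected", call. = FALSE)
}

#' Extract the nine trial-level kinematic parameters
#'
#' Runs smoothing/differentiation, onset and grasp-end detection on a trial
#' recording and measures: the acceleration peak (maximum acceleration
#' between onset and the velocity peak), the velocity peak (maximum speed
#' between onset and grasp end), the deceleration peak (magnitude of the most
#' negative acceleration between the velocity peak and grasp end), the MGA
#' (maximum grip aperture between onset and grasp end) -- each with its
#' latency in ms from movement onset -- and the overall movement time (onset
#' to stabilised grasp, ms). Ties at a peak take the earliest sample.
#'
#' @param recording A \code{trial_recording}.
#' @param config List merging \code{filter} (see
#'   \code{\link{differentiate_and_smooth}}), \code{onset_threshold} (mm/s)
#'   and \code{end} (see \code{\link{detect_grasp_end}}).
#' @return One-row data.frame with the columns of
#'   \code{\link{kin_parameters}} plus \code{subject_id}, \code{session},
#'   \code{block}, \code{trial}.
#' @export
extract_trial_parameters <- function(recording, config = list()) {
  profile <- differentiate_and_smooth(recording, config$filter %||% list())
  onset <- detect_onset(profile, recording$switch_release_time,
                        threshold = config$onset_threshold %||% 10)
  end <- detect_grasp_end(profile, onset, config$end %||% list())
  times <- profile$sample_times
  i_on <- which(times >= onset)[1]
  i_end <- which(times >= end)[1]
  if (i_end <= i_on + 2L) stop("movement window too short", call. = FALSE)

  speed <- profile$tangential_velocity
  accel <- profile$tangential_acceleration
  ap <- profile$grip_aperture

  i_vp <- i_on - 1L + which.max(speed[i_on:i_end])
  i_acc <- i_on - 1L + which.max(accel[i_on:i_vp])
  i_dec <- i_vp - 1L + which.min(accel[i_vp:i_end])
  i_mga <- i_on - 1L + which.max(ap[i_on:i_end])

  lat <- function(i) (times[i] - onset) * 1000
  out <- data.frame(
    subject_id = recording$subject_id %||% NA_character_,
    session = recording$session %||% NA_character_,
    block = recording$block %||% NA_integer_,
    trial = recording$trial_index %||% NA_integer_,
    acc_latency = lat(i_acc),
    acc_amplitude = accel[i_acc],
    vel_latency = lat(i_vp),
    vel_amplitude = speed[i_vp],
    dec_latency = lat(i_dec),
    dec_amplitude = abs(accel[i_dec]),
    mga_latency = lat(i_mga),
    mga = ap[i_mga],
    movement_time = (end - onset) * 1000,
    stringsAsFactors = FALSE
  )
  out
}

#' Extract parameters from a list of recordings into a long cohort table
#'
#' @param recordings List of \code{trial_recording}s.
#' @param config Extraction config passed to
#'   \code{\link{extract_trial_parameters}}.
#' @param puberty Optional named vector mapping subject_id to puberty score,
#'   merged into the output.
#' @return A long-format \code{cohort_table} data.frame.
#' @export
extract_trials <- function(recordings, config = list(), puberty = NULL) {
  wide <- do.call(rbind, lapply(recordings, extract_trial_parameters,
                                config = config))
  long <- do.call(rbind, lapply(kin_parameters(), function(p) {
    data.frame(subject_id = wide$subject_id,
               puberty = if (is.null(puberty)) NA_real_
                         else unname(puberty[wide$subject_id]),
               sex = NA_character_,
               session = wide$session, block = wide$block, trial = wide$trial,
               parameter = p, value = wide[[p]], stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  class(long) <- c("cohort_table", "data.frame")
  long
}
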