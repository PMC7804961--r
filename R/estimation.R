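#' Default effect specification for the arm-length-estimation task
#'
#' The estimation outcome is analysed in percent of the veridical forearm
#' length, so the baseline sits at 100. The POST-PRE difference is linear in
#' puberty with a zero very early on the scale,
#' \eqn{d(p) = -k (p - c^*)}: beyond the crossing, participants estimate
#' their arm as increasingly shorter after tool use (one residual SD at the
#' top of the scale with the defaults), while the youngest are essentially
#' unaffected. A mild inverted-U shared puberty curve adds the curvature that
#' makes the quadratic trend model the better fit for this task.
#'
#' @param target_crossing Puberty value of the reversal (default 7.5).
#' @param strength Slope \eqn{k} of the difference in percent points per
#'   puberty unit (default 0.8).
#' @param puberty_curve Shared (both-session) curve coefficients
#'   \code{c(a1, a2)} on the percent scale.
#' @param residual_sd,subject_sd Noise SDs in percent points.
#' @return An \code{\link{effect_spec}} on the percent scale.
#' @export
default_estimation_spec <- function(target_crossing = 7.5,
                                    strength = 0.8,
                                    puberty_curve = c(1, -0.04),
                                    residual_sd = 10,
                                    subject_sd = 8) {
  effect_spec(baseline = 100,
              puberty_curve = puberty_curve,
              interaction_curve = c(0, -strength, 0),
              subject_sd = subject_sd, residual_sd = residual_sd,
              target_crossing = target_crossing)
}

#' Generate arm-length-estimation trials
#'
#' Draws the estimation outcome on the percent-of-veridical-arm-length scale
#' from the generative model of \code{spec} and converts it back to a raw
#' estimated distance (mm-free, same unit as \code{forearm_length}), so the
#' output table looks like recorded data: the analysis re-applies the percent
#' transform.
#'
#' @param cohort A cohort with \code{subject_id}, \code{puberty_score},
#'   \code{forearm_length}.
#' @param spec An \code{\link{effect_spec}} on the percent scale.
#' @param n_trials Trials per session (default 18).
#' @param sessions Session labels (PRE first).
#' @param seed Integer seed.
#' @return Data.frame: \code{subject_id}, \code{puberty}, \code{session},
#'   \code{trial}, \code{estimate}, \code{forearm_length}.
#' @export
generate_estimation_trials <- function(cohort,
                                       spec = default_estimation_spec(),
                                       n_trials = 18,
                                       sessions = c("PRE", "POST"),
                                       seed = 1L) {
  check_columns(cohort, c("subject_id", "puberty_score", "forearm_length"),
                "cohort")
  stopifnot(inherits(spec, "effect_spec"))
  n_sub <- nrow(cohort)
  n_trials <- as.integer(n_trials)
  with_seed(seed, {
    b <- stats::rnorm(n_sub, 0, spec$subject_sd)
    rows <- list()
    for (si in 1:2) {
      s <- c(-0.5, 0.5)[si]
      mu <- effect_mean(spec, cohort$puberty_score, s) + b
      pct <- matrix(mu, n_sub, n_trials) +
        matrix(stats::rnorm(n_sub * n_trials, 0, spec$residual_sd), n_sub)
      rows[[si]] <- data.frame(
        subject_id = rep(cohort$subject_id, times = n_trials),
        puberty = rep(cohort$puberty_score, times = n_trials),
        session = sessions[si],
        trial = rep(seq_len(n_trials), each = n_sub),
        estimate = as.vector(pct) / 100 * rep(cohort$forearm_length, n_trials),
        forearm_length = rep(cohort$forearm_length, times = n_trials),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate per-subject gesture-imitation scores
#'
#' Scores rise linearly with puberty plus Gaussian noise, clamped to the
#' 0--72 range of the 24-item, 3-points-per-item test.
#'
#' @param cohort A cohort data.frame.
#' @param intercept,slope Linear model of the mean score on puberty
#'   (defaults near the reference cohort's marginals).
#' @param sd Between-subject noise SD.
#' @param seed Integer seed.
#' @return Data.frame: \code{subject_id}, \code{puberty}, \code{score}.
#' @export
generate_imitation_scores <- function(cohort, intercept = 46, slope = 0.8,
                                      sd = 5, seed = 1L) {
  check_columns(cohort, c("subject_id", "puberty_score"), "cohort")
  with_seed(seed, {
    sc <- intercept + slope * cohort$puberty_score +
      stats::rnorm(nrow(cohort), 0, sd)
    data.frame(subject_id = cohort$subject_id,
               puberty = cohort$puberty_score,
               score = pmin(72, pmax(0, round(sc))),
               stringsAsFactors = FALSE)
  })
}
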