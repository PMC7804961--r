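#' Default cohort profile: per-score marginals of the reference cohort
#'
#' Per-puberty-score marginals of the 90-participant developmental cohort the
#' synthetic generator emulates: sample size, sex split, mean age, mean height,
#' mean forearm length and mean gesture-imitation score for each puberty score
#' (5--20). The puberty score is the sum of five self-rated pubertal
#' development items, each scored 1--4. These marginals drive the default
#' sampling weights and covariate means of \code{\link{generate_cohort}}.
#'
#' @return A data.frame with one row per puberty score and columns
#'   \code{puberty}, \code{n}, \code{n_female}, \code{n_male},
#'   \code{age_mean} (years), \code{height_mean} (cm),
#'   \code{forearm_mean} (cm), \code{imitation_mean} (score / 72).
#' @export
cohort_profile <- function() {
  data.frame(
    puberty  = 5:20,
    n        = c(4L, 6L, 7L, 7L, 8L, 4L, 5L, 3L, 2L, 4L, 8L, 3L, 6L, 3L, 11L, 9L),
    n_female = c(1L, 2L, 4L, 2L, 3L, 1L, 3L, 2L, 2L, 1L, 5L, 2L, 4L, 2L, 9L, 3L),
    n_male   = c(3L, 4L, 3L, 5L, 5L, 3L, 2L, 1L, 0L, 3L, 3L, 1L, 2L, 1L, 2L, 6L),
    age_mean = c(9.7, 9.6, 10.0, 11.0, 12.1, 11.5, 13.5, 13.1,
                 12.6, 14.8, 14.6, 15.9, 15.3, 15.7, 17.8, 19.8),
    height_mean = c(144, 133, 140, 144, 153, 143, 160, 160,
                    158, 168, 167, 172, 171, 165, 165, 172),
    forearm_mean = c(19.1, 19.8, 20.2, 21.1, 22.2, 21.3, 23.6, 24.5,
                     24.0, 24.7, 24.7, 25.5, 25.3, 23.5, 24.4, 25.0),
    imitation_mean = c(49.7, 52.7, 54.1, 54.7, 57.3, 58.3, 56.2, 56.3,
                       60.0, 60.5, 62.1, 59.0, 48.0, 60.0, 59.9, 61.5)
  )
}

#' Printed reference results of the study the pipeline reproduces
#'
#' The published point estimates that \code{\link{reproduce_study}} compares a
#' re-analysis against: per-parameter crossing points with their intervals of
#' equivalence on the puberty scale, the meta-parameter crossing, first-
#' principal-component explained-variance percentages, the linear-vs-quadratic
#' likelihood-ratio chi-squares, the arm-length-estimation crossing point and
#' the height--forearm Pearson correlation. The original data archive is
#' available from the Open Science Framework (accession \code{osf.io/3g9mz}).
#'
#' @return A list with elements \code{crossings} (data.frame: parameter,
#'   crossing_point, interval_lo, interval_hi), \code{crossing_mean},
#'   \code{crossing_median}, \code{meta_crossing}, \code{meta_interval},
#'   \code{explained_variance_pct} (named: freehand reaching/grasping,
#'   tool-use reaching/grasping), \code{lrt_chi2} (named: freehand, tooluse,
#'   armlength), \code{armlength_crossing}, \code{armlength_interval},
#'   \code{height_forearm_r}.
#' @export
reference_study_values <- function() {
  crossings <- data.frame(
    parameter = kin_parameters(),
    crossing_point = c(12.45, 17.23, 16.24, 17.54, 14.29, 16.71,
                       16.71, 18.02, 12.15),
    interval_lo = c(5, 16, 14, 16, 11, 15, 15, 17, 10),
    interval_hi = c(17, 18, 17, 19, 17, 18, 18, 19, 15)
  )
  list(
    crossings = crossings,
    crossing_mean = 15.7,
    crossing_median = 16.7,
    meta_crossing = 16.0,
    meta_interval = c(14, 17),
    explained_variance_pct = c(freehand_reaching = 66.2,
                               freehand_grasping = 62.3,
                               tooluse_reaching = 60.9,
                               tooluse_grasping = 60.4),
    lrt_chi2 = c(freehand = 7.28, tooluse = 3.03, armlength = 11.26),
    armlength_crossing = 7.5,
    armlength_interval = c(6, 8),
    height_forearm_r = 0.89
  )
}
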