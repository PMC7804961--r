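#' Generate a synthetic developmental cohort
#'
#' Draws subjects whose puberty scores follow a configurable distribution over
#' the 5--20 scale and whose anthropometrics follow the per-score means of the
#' reference cohort profile (\code{\link{cohort_profile}}) with Gaussian
#' jitter. The within-score jitter correlation between height and forearm
#' length is solved analytically so that the pooled height--forearm Pearson
#' correlation equals \code{height_forearm_r} in population (0.89 by default,
#' the value observed in the reference cohort). Tool length is assigned from
#' height: 25 cm up to 122 cm, 32 cm for 123--146 cm, 40 cm from 147 cm.
#'
#' @param n_subjects Number of subjects to draw (>= 1).
#' @param puberty_weights Non-negative sampling weights over puberty scores
#'   5--20 (length 16, need not sum to 1). Defaults to the reference cohort's
#'   per-score sample sizes.
#' @param seed Integer seed; identical inputs and seed give identical cohorts.
#' @param height_forearm_r Target population Pearson correlation between
#'   height and forearm length.
#' @param height_sd,forearm_sd,age_sd Within-score jitter standard deviations
#'   (cm, cm, years).
#' @param left_handed_prop Proportion of left-handed subjects.
#' @return A data.frame of class \code{cohort} with one row per subject:
#'   \code{subject_id}, \code{puberty_score}, \code{sex}, \code{age},
#'   \code{height}, \code{forearm_length}, \code{handedness},
#'   \code{tool_length}.
#' @examples
#' cohort <- generate_cohort(90, seed = 1)
#' range(cohort$puberty_score)
#' @export
generate_cohort <- function(n_subjects,
                            puberty_weights = cohort_profile()$n,
                            seed = 1L,
                            height_forearm_r = 0.89,
                            height_sd = 7,
                            forearm_sd = 1.5,
                            age_sd = 1,
                            left_handed_prop = 6 / 90) {
  check_number(n_subjects, "n_subjects", lower = 1)
  if (!is.numeric(puberty_weights) || length(puberty_weights) != 16L ||
      anyNA(puberty_weights) || any(puberty_weights < 0) ||
      sum(puberty_weights) <= 0)
    stop("`puberty_weights` must be 16 non-negative weights over scores 5:20, not all zero",
         call. = FALSE)
  check_number(height_forearm_r, "height_forearm_r", lower = -1, upper = 1)

  profile <- cohort_profile()
  w <- puberty_weights / sum(puberty_weights)

  # solve the within-score jitter correlation giving the target pooled r:
  # pooled cov = between-score cov of the means + rho_w * sd_h * sd_f
  mu_h <- profile$height_mean
  mu_f <- profile$forearm_mean
  m_h <- sum(w * mu_h); m_f <- sum(w * mu_f)
  b_h <- sum(w * (mu_h - m_h)^2)
  b_f <- sum(w * (mu_f - m_f)^2)
  b_hf <- sum(w * (mu_h - m_h) * (mu_f - m_f))
  rho_w <- (height_forearm_r * sqrt((b_h + height_sd^2) * (b_f + forearm_sd^2)) -
              b_hf) / (height_sd * forearm_sd)
  if (abs(rho_w) > 0.99) {
    warning("target height-forearm correlation not attainable with these jitter SDs; clamping")
    rho_w <- max(min(rho_w, 0.99), -0.99)
  }

  with_seed(seed, {
    n <- as.integer(n_subjects)
    idx <- sample.int(16L, n, replace = TRUE, prob = w)
    ps <- profile$puberty[idx]
    p_female <- ifelse(profile$n[idx] > 0,
                       profile$n_female[idx] / profile$n[idx], 0.5)
    sex <- ifelse(stats::runif(n) < p_female, "F", "M")
    age <- pmax(6, profile$age_mean[idx] + stats::rnorm(n, 0, age_sd))
    e_h <- stats::rnorm(n)
    e_f <- rho_w * e_h + sqrt(1 - rho_w^2) * stats::rnorm(n)
    height <- profile$height_mean[idx] + height_sd * e_h
    forearm <- pmax(10, profile$forearm_mean[idx] + forearm_sd * e_f)
    handedness <- ifelse(stats::runif(n) < left_handed_prop, "L", "R")
    tool_length <- ifelse(height <= 122, 25, ifelse(height < 147, 32, 40))
    out <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      puberty_score = ps,
      sex = sex,
      age = round(age, 1),
      height = round(height, 1),
      forearm_length = round(forearm, 1),
      handedness = handedness,
      tool_length = tool_length,
      stringsAsFactors = FALSE
    )
    class(out) <- c("cohort", "data.frame")
    out
  })
}
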