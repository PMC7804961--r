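#' Specify the generative effect structure for one kinematic parameter
#'
#' The synthetic generator mirrors the analysis model: for subject \eqn{i},
#' session \eqn{s} (coded -1/2 for PRE, +1/2 for POST) and trial \eqn{t},
#' \deqn{y_{ist} = \beta_0 + b_i + \beta_1 s + f(p_i) + g(p_i) s + \epsilon_{ist},}
#' with \eqn{p_i} the puberty score, \eqn{f} a shared (both-session) puberty
#' polynomial, \eqn{g} the session-by-puberty interaction polynomial,
#' \eqn{b_i \sim N(0, \sigma_b^2)} a subject random intercept and
#' \eqn{\epsilon \sim N(0, \sigma_e^2)} trial noise. The POST-PRE difference
#' function is \eqn{d(p) = \beta_1 + g(p)}; when \code{target_crossing} is
#' given, the constant term of \eqn{g} is adjusted so that \eqn{d} vanishes
#' exactly at that puberty value.
#'
#' @param baseline Intercept \eqn{\beta_0} in the parameter's units.
#' @param session_main Session main effect \eqn{\beta_1} (POST-PRE shift at
#'   the origin of the puberty polynomial).
#' @param puberty_curve Coefficients \code{c(a1, a2)} of
#'   \eqn{f(p) = a_1 p + a_2 p^2} (intercept absorbed in \code{baseline}).
#' @param interaction_curve Coefficients \code{c(g0, g1, g2)} of
#'   \eqn{g(p) = g_0 + g_1 p + g_2 p^2}.
#' @param subject_sd,residual_sd Random-intercept and trial-noise SDs (>= 0).
#' @param target_crossing Optional puberty value at which the POST-PRE
#'   difference must be exactly zero; overrides \code{g0}.
#' @return An object of class \code{effect_spec}.
#' @examples
#' es <- effect_spec(baseline = 656, interaction_curve = c(0, -20, 0),
#'                   residual_sd = 70, subject_sd = 70, target_crossing = 16)
#' difference_function(es, 16)  # exactly 0 by construction
#' @export
effect_spec <- function(baseline = 0,
                        session_main = 0,
                        puberty_curve = c(0, 0),
                        interaction_curve = c(0, 0, 0),
                        subject_sd = 1,
                        residual_sd = 1,
                        target_crossing = NULL) {
  check_number(baseline, "baseline")
  check_number(session_main, "session_main")
  stopifnot(is.numeric(puberty_curve), length(puberty_curve) == 2L,
            is.numeric(interaction_curve), length(interaction_curve) == 3L)
  check_number(subject_sd, "subject_sd", lower = 0)
  check_number(residual_sd, "residual_sd", lower = 0)
  g <- as.numeric(interaction_curve)
  if (!is.null(target_crossing)) {
    cstar <- check_number(target_crossing, "target_crossing")
    # d(c*) = session_main + g0 + g1 c* + g2 c*^2 = 0
    g[1] <- -(session_main + g[2] * cstar + g[3] * cstar^2)
  }
  structure(
    list(baseline = baseline, session_main = session_main,
         puberty_curve = as.numeric(puberty_curve), interaction_curve = g,
         subject_sd = subject_sd, residual_sd = residual_sd,
         target_crossing = if (is.null(target_crossing)) NA_real_ else target_crossing),
    class = "effect_spec"
  )
}

#' Analytic POST-PRE difference of an effect specification
#'
#' Evaluates \eqn{d(p) = \beta_1 + g(p)}, the population difference between
#' the POST and PRE session curves at puberty score \code{p}.
#'
#' @param spec An \code{\link{effect_spec}}.
#' @param p Puberty score(s).
#' @return Numeric vector of population differences.
#' @export
difference_function <- function(spec, p) {
  stopifnot(inherits(spec, "effect_spec"))
  g <- spec$interaction_curve
  spec$session_main + g[1] + g[2] * p + g[3] * p^2
}

# population mean for given puberty and session contrast s (+-1/2)
effect_mean <- function(spec, p, s) {
  f <- spec$puberty_curve
  g <- spec$interaction_curve
  spec$baseline + spec$session_main * s + f[1] * p + f[2] * p^2 +
    (g[1] + g[2] * p + g[3] * p^2) * s
}

#' Default effect specifications for the nine kinematic parameters
#'
#' Physiologically plausible baselines for a 35 cm reach (peak velocity near
#' 656 mm/s, movement time near 1 s, MGA near 70 mm) together with a
#' session-by-puberty interaction that reverses the tool-use after-effect at
#' \code{target_crossing}: after tool use, latencies shorten and amplitudes
#' grow below the crossing and do the opposite above it, the adult-typical
#' pattern. Interaction slopes are one third of the residual SD per puberty
#' unit, so the after-effect reaches roughly 1.7 residual SDs at the low end
#' of the 5--20 scale when the crossing sits at 16. Residual and
#' between-subject SDs are stated assumptions (the reference study reports no
#' variance components); both default to the same per-parameter value.
#'
#' @param target_crossing Puberty value where the after-effect reverses
#'   (default 16); \code{NA} for no interaction (null session effect).
#' @param effect_scale Multiplier on the interaction slopes (0 gives a null
#'   interaction; larger values give stronger reversals).
#' @param quadratic Logical; add a quadratic interaction component (for
#'   power studies of the linear-vs-quadratic selection).
#' @return Named list of \code{\link{effect_spec}} objects, one per parameter
#'   of \code{\link{kin_parameters}}.
#' @export
default_effect_specs <- function(target_crossing = 16,
                                 effect_scale = 1,
                                 quadratic = FALSE) {
  base <- data.frame(
    parameter = kin_parameters(),
    baseline = c(180, 2020, 470, 656, 760, 2020, 600, 70, 1000),
    sd       = c(30, 250, 40, 70, 50, 250, 60, 6, 80),
    # sign of the late-puberty (adult-like) after-effect: latencies lengthen,
    # amplitudes shrink after tool use
    dir      = c(1, -1, 1, -1, 1, -1, 1, -1, 1)
  )
  specs <- lapply(seq_len(nrow(base)), function(i) {
    sd_i <- base$sd[i]
    slope <- effect_scale * base$dir[i] * sd_i / 3
    quad <- if (quadratic) effect_scale * base$dir[i] * sd_i / 60 else 0
    if (is.na(target_crossing) || effect_scale == 0) {
      effect_spec(baseline = base$baseline[i], subject_sd = sd_i,
                  residual_sd = sd_i)
    } else {
      effect_spec(baseline = base$baseline[i],
                  interaction_curve = c(0, slope, quad),
                  subject_sd = sd_i, residual_sd = sd_i,
                  target_crossing = target_crossing)
    }
  })
  names(specs) <- base$parameter
  specs
}

#' Generate trial-level kinematic parameters for a cohort
#'
#' Draws every subject x session x trial cell of the nine kinematic
#' parameters from the generative model of \code{\link{effect_spec}}. To
#' emulate the strong cross-parameter correlation of real reach-to-grasp
#' trials (fast trials have short latencies and high peaks), a fraction
#' \code{shared_frac} of both the subject-intercept and the trial-noise
#' variance is carried by a latent "vigour" factor common to all parameters,
#' loading positively on amplitudes and negatively on latencies and movement
#' time. With the default 0.35 (and the default session-by-puberty effects,
#' which add shared structure of their own) the first-principal-component
#' explained variance lands near 65%, in the range reported for real data.
#'
#' @param cohort A cohort data.frame from \code{\link{generate_cohort}} (or
#'   any data.frame with \code{subject_id} and \code{puberty_score}).
#' @param effects Named list of \code{\link{effect_spec}}s, one per parameter
#'   (default \code{\link{default_effect_specs}()}).
#' @param n_trials Trials per subject x session cell (default 18).
#' @param sessions Condition labels; first is coded -1/2, second +1/2.
#' @param seed Integer seed.
#' @param shared_frac Fraction of noise variance on the shared latent factor,
#'   in [0, 1).
#' @return A long-format data.frame of class \code{cohort_table}:
#'   \code{subject_id}, \code{puberty}, \code{sex}, \code{session},
#'   \code{block} (NA here), \code{trial}, \code{parameter}, \code{value}.
#' @examples
#' cohort <- generate_cohort(10, seed = 1)
#' tab <- generate_trial_parameters(cohort, n_trials = 3, seed = 2)
#' head(tab)
#' @export
generate_trial_parameters <- function(cohort,
                                      effects = default_effect_specs(),
                                      n_trials = 18,
                                      sessions = c("PRE", "POST"),
                                      seed = 1L,
                                      shared_frac = 0.35) {
  check_columns(cohort, c("subject_id", "puberty_score"), "cohort")
  check_number(n_trials, "n_trials", lower = 1)
  check_number(shared_frac, "shared_frac", lower = 0, upper = 0.999)
  stopifnot(is.list(effects), length(effects) >= 1,
            !is.null(names(effects)), all(nzchar(names(effects))))
  lapply(effects, function(e) stopifnot(inherits(e, "effect_spec")))
  stopifnot(length(sessions) == 2L)

  pars <- names(effects)
  vigour_sign <- ifelse(grepl("latency|movement_time", pars), -1, 1)
  n_sub <- nrow(cohort)
  n_trials <- as.integer(n_trials)
  s_codes <- c(-0.5, 0.5)

  with_seed(seed, {
    # subject-level draws: shared factor + own component per parameter
    b_shared <- stats::rnorm(n_sub)
    b_own <- matrix(stats::rnorm(n_sub * length(pars)), n_sub)
    rows <- vector("list", 2L * length(pars))
    k <- 0L
    n_cell <- n_sub * n_trials
    for (si in 1:2) {
      u_shared <- matrix(stats::rnorm(n_cell), n_sub)  # trial vigour factor
      e_own <- array(stats::rnorm(n_cell * length(pars)),
                     dim = c(n_sub, n_trials, length(pars)))
      for (pi in seq_along(pars)) {
        sp <- effects[[pi]]
        mu <- effect_mean(sp, cohort$puberty_score, s_codes[si])
        b <- sp$subject_sd * (sqrt(shared_frac) * vigour_sign[pi] * b_shared +
                                sqrt(1 - shared_frac) * b_own[, pi])
        eps <- sp$residual_sd * (sqrt(shared_frac) * vigour_sign[pi] * u_shared +
                                   sqrt(1 - shared_frac) * e_own[, , pi])
        vals <- (mu + b) + eps  # n_sub x n_trials
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = rep(cohort$subject_id, times = n_trials),
          puberty = rep(cohort$puberty_score, times = n_trials),
          sex = rep(cohort$sex %||% NA_character_, times = n_trials),
          session = sessions[si],
          block = NA_integer_,
          trial = rep(seq_len(n_trials), each = n_sub),
          parameter = pars[pi],
          value = as.vector(vals),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$subject_id, out$session, out$trial, out$parameter), ]
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Generate trial-level parameters for the tool-use session (blocks)
#'
#' Same generative model as \code{\link{generate_trial_parameters}} but over
#' tool-use blocks: the condition contrasts block 1 (FIRST, -1/2) against
#' block 4 (LAST, +1/2); blocks 2 and 3 are drawn at the midpoint (contrast
#' 0), mirroring a gradual practice effect. The interaction curve of each
#' \code{\link{effect_spec}} is interpreted against the linear puberty model
#' of the tool-use analysis.
#'
#' @inheritParams generate_trial_parameters
#' @param n_trials Trials per block (default 12).
#' @param blocks Block indices to generate (default 1:4).
#' @return A \code{cohort_table} data.frame with \code{block} filled in and
#'   \code{session} set to \code{"TOOL"}.
#' @export
generate_block_parameters <- function(cohort,
                                      effects = default_effect_specs(),
                                      n_trials = 12,
                                      blocks = 1:4,
                                      seed = 1L,
                                      shared_frac = 0.35) {
  check_columns(cohort, c("subject_id", "puberty_score"), "cohort")
  check_number(n_trials, "n_trials", lower = 1)
  stopifnot(all(blocks %in% 1:4))
  pars <- names(effects)
  vigour_sign <- ifelse(grepl("latency|movement_time", pars), -1, 1)
  n_sub <- nrow(cohort)
  n_trials <- as.integer(n_trials)
  contrast <- (blocks - 2.5) / 3  # block 1 -> -1/2, block 4 -> +1/2

  with_seed(seed, {
    b_shared <- stats::rnorm(n_sub)
    b_own <- matrix(stats::rnorm(n_sub * length(pars)), n_sub)
    rows <- list(); k <- 0L
    n_cell <- n_sub * n_trials
    for (bi in seq_along(blocks)) {
      u_shared <- matrix(stats::rnorm(n_cell), n_sub)
      e_own <- array(stats::rnorm(n_cell * length(pars)),
                     dim = c(n_sub, n_trials, length(pars)))
      for (pi in seq_along(pars)) {
        sp <- effects[[pi]]
        mu <- effect_mean(sp, cohort$puberty_score, contrast[bi])
        b <- sp$subject_sd * (sqrt(shared_frac) * vigour_sign[pi] * b_shared +
                                sqrt(1 - shared_frac) * b_own[, pi])
        eps <- sp$residual_sd * (sqrt(shared_frac) * vigour_sign[pi] * u_shared +
                                   sqrt(1 - shared_frac) * e_own[, , pi])
        vals <- (mu + b) + eps
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = rep(cohort$subject_id, times = n_trials),
          puberty = rep(cohort$puberty_score, times = n_trials),
          sex = rep(cohort$sex %||% NA_character_, times = n_trials),
          session = "TOOL",
          block = blocks[bi],
          trial = rep(seq_len(n_trials), each = n_sub),
          parameter = pars[pi],
          value = as.vector(vals),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Pivot a long cohort table to one row per trial
#'
#' @param table A long \code{cohort_table} (columns \code{subject_id},
#'   \code{puberty}, \code{session}, \code{block}, \code{trial},
#'   \code{parameter}, \code{value}).
#' @return A wide data.frame with one column per parameter.
#' @export
cohort_table_wide <- function(table) {
  check_columns(table, c("subject_id", "puberty", "session", "trial",
                         "parameter", "value"), "cohort table")
  if (!"block" %in% names(table)) table$block <- NA_integer_
  blk <- ifelse(is.na(table$block), 0L, table$block)
  key <- paste(table$subject_id, table$session, blk, table$trial, sep = "\r")
  first <- !duplicated(key)
  wide <- table[first, c("subject_id", "puberty", "session", "block", "trial")]
  for (p in unique(table$parameter)) {
    sel <- table$parameter == p
    wide[[p]] <- table$value[sel][match(key[first], key[sel])]
  }
  rownames(wide) <- NULL
  wide
}
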