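#' Fit the random-intercept mixed model for one outcome
#'
#' Fits \code{outcome ~ condition + basis(covariate) + condition:basis +
#' (1 | subject)} with lme4, the model family used for all three analyses:
#' free-hand PRE/POST sessions with a degree-2 (or degree-1) orthogonal
#' puberty basis, tool-use FIRST/LAST blocks with a linear puberty covariate,
#' and the arm-length-estimation variant. The condition factor is coded
#' sum-to-zero as -1/2 (first level) / +1/2 (second level), which makes the
#' condition coefficient the POST-PRE (or LAST-FIRST) shift at the origin of
#' the puberty basis and keeps Type III Wald tests coding-invariant.
#'
#' @param table Trial-level data: either a long \code{cohort_table} (the
#'   outcome is then selected by \code{outcome} from the \code{parameter}
#'   column) or a wide table with the outcome as a column.
#' @param outcome Name of the outcome (a kinematic parameter, "meta", ...).
#' @param condition Name of the condition column (default "session"); must
#'   have exactly two levels, ordered so that the reference (PRE / FIRST)
#'   comes first.
#' @param condition_levels Optional explicit level order.
#' @param covariate Covariate column (default "puberty").
#' @param degree Polynomial degree of the covariate basis (1 or 2).
#' @param interaction Include condition x covariate interaction terms
#'   (default TRUE).
#' @param method "REML" (coefficient/Wald reporting) or "ML" (for likelihood
#'   ratio comparisons).
#' @return An object of class \code{kin_lmm}: list with \code{fit} (the
#'   lmerMod), \code{beta}, \code{vcov}, \code{terms} (coefficient blocks per
#'   model term), \code{basis}, \code{outcome}, \code{condition_levels},
#'   \code{random_intercept_variance}, \code{residual_variance},
#'   \code{log_likelihood}, \code{method}, \code{n_obs}, \code{n_subjects},
#'   \code{converged}, \code{singular}.
#' @export
fit_lmm <- function(table, outcome,
                    condition = "session",
                    condition_levels = NULL,
                    covariate = "puberty",
                    degree = 2,
                    interaction = TRUE,
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  df <- lmm_frame(table, outcome, condition, condition_levels, covariate)
  if (length(unique(df$subject)) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (stats::sd(df$y) == 0) stop("outcome is constant", call. = FALSE)

  basis <- orthogonal_poly_basis(df$x, degree = degree)
  P <- basis$columns
  dat <- data.frame(y = df$y, s = df$s, subject = df$subject)
  pub_terms <- character(0); int_terms <- character(0)
  for (d in seq_len(degree)) {
    dat[[paste0("P", d)]] <- P[, d]
    pub_terms <- c(pub_terms, paste0("P", d))
    if (interaction) {
      dat[[paste0("sP", d)]] <- df$s * P[, d]
      int_terms <- c(int_terms, paste0("sP", d))
    }
  }
  rhs <- paste(c("s", pub_terms, int_terms, "(1 | subject)"), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = (method == "REML")),
    message = function(m) {
      if (grepl("singular", conditionMessage(m))) invokeRestart("muffleMessage")
    }
  )
  singular <- lme4::isSingular(fit)
  if (singular)
    warning(sprintf("singular fit for %s: random-intercept variance is zero",
                    outcome), call. = FALSE)
  conv <- fit@optinfo$conv$lme4
  converged <- is.null(conv$code) || conv$code == 0

  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fit = fit,
    beta = lme4::fixef(fit),
    vcov = as.matrix(stats::vcov(fit)),
    terms = list(condition = "s", covariate = pub_terms,
                 interaction = int_terms),
    basis = basis,
    outcome = outcome,
    condition = condition,
    condition_levels = attr(df, "condition_levels"),
    covariate = covariate,
    degree = degree,
    random_intercept_variance = vc$vcov[vc$grp == "subject"],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    log_likelihood = as.numeric(stats::logLik(fit)),
    method = method,
    n_obs = nrow(dat),
    n_subjects = length(unique(dat$subject)),
    converged = converged,
    singular = singular,
    rows_used = attr(df, "rows_used")
  ), class = "kin_lmm")
}

# reference level (-1/2) first: PRE/FIRST and block 1 are the baselines
default_condition_levels <- function(cond) {
  u <- unique(cond)
  for (known in list(c("PRE", "POST"), c("FIRST", "LAST"), c("1", "4")))
    if (setequal(u, known)) return(known)
  sort(u)
}

# normalise long/wide input into y, s (+-1/2), x, subject
lmm_frame <- function(table, outcome, condition, condition_levels, covariate) {
  stopifnot(is.data.frame(table))
  if ("parameter" %in% names(table) && outcome %in% table$parameter &&
      !outcome %in% names(table)) {
    table <- cohort_table_wide(table)
  }
  check_columns(table, c(outcome, condition, covariate, "subject_id"),
                "trial table")
  keep <- stats::complete.cases(table[, c(outcome, condition, covariate,
                                          "subject_id")])
  table <- table[keep, ]
  cond <- as.character(table[[condition]])
  lev <- condition_levels %||% default_condition_levels(cond)
  if (length(lev) != 2 || !all(cond %in% lev))
    stop(sprintf("`%s` must have exactly two levels", condition), call. = FALSE)
  df <- data.frame(y = table[[outcome]],
                   s = ifelse(cond == lev[2], 0.5, -0.5),
                   x = table[[covariate]],
                   subject = as.character(table$subject_id),
                   stringsAsFactors = FALSE)
  attr(df, "condition_levels") <- lev
  attr(df, "rows_used") <- which(keep)
  df
}

#' @export
print.kin_lmm <- function(x, ...) {
  cat(sprintf("<kin_lmm> %s ~ %s (+-1/2) + poly(%s, %d)%s + (1 | subject), %s\n",
              x$outcome, x$condition, x$covariate, x$degree,
              if (length(x$terms$interaction)) " + interaction" else "",
              x$method))
  cat(sprintf("  n = %d obs, %d subjects; sigma_b^2 = %.4g, sigma_e^2 = %.4g%s\n",
              x$n_obs, x$n_subjects, x$random_intercept_variance,
              x$residual_variance, if (x$singular) " (singular)" else ""))
  print(wald_type3(x))
  invisible(x)
}

#' Type III Wald chi-square tests
#'
#' For each model term (condition, covariate, interaction) computes the Wald
#' statistic \eqn{\chi^2 = \hat\beta' V^{-1} \hat\beta} on the term's
#' coefficient block, with degrees of freedom equal to the block size. Under
#' the sum-to-zero condition coding used by \code{\link{fit_lmm}} these are
#' the Type III tests conventionally reported for this design.
#'
#' @param fit A \code{kin_lmm}.
#' @return Data.frame with columns \code{term}, \code{chi2}, \code{df},
#'   \code{p}.
#' @export
wald_type3 <- function(fit) {
  stopifnot(inherits(fit, "kin_lmm"))
  if (!fit$converged) stop("model did not converge", call. = FALSE)
  blocks <- Filter(length, fit$terms)
  out <- lapply(names(blocks), function(term) {
    idx <- match(blocks[[term]], names(fit$beta))
    b <- fit$beta[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    if (qr(V)$rank < length(idx))
      stop(sprintf("rank-deficient coefficient block for term '%s'", term),
           call. = FALSE)
    chi2 <- as.numeric(t(b) %*% solve(V, b))
    data.frame(term = term, chi2 = chi2, df = length(idx),
               p = stats::pchisq(chi2, df = length(idx), lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Likelihood-ratio choice between quadratic and linear covariate trends
#'
#' Fits the degree-2 and degree-1 models by maximum likelihood on the same
#' rows and compares them: \eqn{\chi^2 = 2(\ell_{quad} - \ell_{lin})} on 2
#' degrees of freedom (the quadratic main and quadratic interaction
#' coefficients). The quadratic model is selected when p < \code{alpha};
#' otherwise the more parsimonious linear model is retained for all
#' parameters of the task.
#'
#' @inheritParams fit_lmm
#' @param alpha Selection level (default 0.05).
#' @return List with \code{chi2}, \code{df}, \code{p}, \code{selected}
#'   ("linear" or "quadratic"), \code{fit_linear}, \code{fit_quadratic}.
#' @export
lrt_poly_vs_linear <- function(table, outcome,
                               condition = "session",
                               condition_levels = NULL,
                               covariate = "puberty",
                               interaction = TRUE,
                               alpha = 0.05) {
  f2 <- fit_lmm(table, outcome, condition, condition_levels, covariate,
                degree = 2, interaction = interaction, method = "ML")
  f1 <- fit_lmm(table, outcome, condition, condition_levels, covariate,
                degree = 1, interaction = interaction, method = "ML")
  if (!identical(f1$rows_used, f2$rows_used))
    stop("linear and quadratic fits used different rows", call. = FALSE)
  chi2 <- 2 * (f2$log_likelihood - f1$log_likelihood)
  if (chi2 < -1e-6)
    stop("nesting violated: quadratic ML log-likelihood below linear", call. = FALSE)
  chi2 <- max(chi2, 0)
  df <- length(f2$beta) - length(f1$beta)
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p,
       selected = if (p < alpha) "quadratic" else "linear",
       fit_linear = f1, fit_quadratic = f2)
}
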