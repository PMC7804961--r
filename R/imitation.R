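#' Linear-vs-quadratic regression of gesture-imitation scores on puberty
#'
#' The gesture-imitation task yields one total score per subject (0--72).
#' Ordinary (non-mixed) regressions of the total score on the puberty score
#' are fitted at degree 1 and degree 2 and compared by likelihood ratio; the
#' quadratic model is kept only when it fits significantly better, the same
#' parsimony rule used for the mixed models.
#'
#' @param scores Per-subject imitation totals in [0, 72].
#' @param puberty Per-subject puberty scores (same length).
#' @param alpha Selection level (default 0.05).
#' @return List with \code{linear_fit}, \code{quadratic_fit} (lm objects),
#'   \code{chi2}, \code{df}, \code{p}, \code{selected}.
#' @export
imitation_regression <- function(scores, puberty, alpha = 0.05) {
  stopifnot(length(scores) == length(puberty))
  if (length(scores) < 4) stop("need at least 4 subjects", call. = FALSE)
  if (any(scores < 0 | scores > 72, na.rm = TRUE))
    stop("imitation scores must lie in [0, 72]", call. = FALSE)
  keep <- stats::complete.cases(scores, puberty)
  d <- data.frame(y = scores[keep], p = puberty[keep])
  f1 <- stats::lm(y ~ p, data = d)
  f2 <- stats::lm(y ~ p + I(p^2), data = d)
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(f2)) -
                        as.numeric(stats::logLik(f1))))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(linear_fit = f1, quadratic_fit = f2, chi2 = chi2, df = 1, p = p,
       selected = if (p < alpha) "quadratic" else "linear")
}
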