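#' First-principal-component meta-parameter
#'
#' Summarises a set of kinematic parameters into a single per-trial score:
#' the first principal component of the spectral decomposition of the
#' parameters' correlation matrix (the correlation rather than covariance
#' matrix, so the component does not depend on measurement units). Scores
#' are the standardised parameters projected on the first eigenvector; the
#' eigenvector sign is fixed so that the loading on
#' \code{orientation_reference} is positive, making the score orientation
#' reproducible. Rows with missing values are dropped (count recorded).
#'
#' @param table Wide trial table (or long \code{cohort_table}, pivoted
#'   internally) containing \code{parameter_names} columns.
#' @param parameter_names Parameters to combine (default the nine of
#'   \code{\link{kin_parameters}}).
#' @param orientation_reference Parameter whose loading is forced positive
#'   (default \code{"vel_amplitude"}, falling back to the first name).
#' @return An object of class \code{meta_parameter}: list with
#'   \code{loadings} (unit norm), \code{explained_variance_fraction}
#'   (\eqn{\lambda_1 / p}), \code{eigenvalues}, \code{scores} (one per
#'   retained row), \code{rows_used}, \code{n_dropped}, \code{center},
#'   \code{scale}, \code{orientation_reference}.
#' @examples
#' cohort <- generate_cohort(15, seed = 1)
#' tab <- cohort_table_wide(generate_trial_parameters(cohort, n_trials = 4, seed = 2))
#' mp <- pca_meta(tab)
#' mp$explained_variance_fraction
#' @export
pca_meta <- function(table, parameter_names = kin_parameters(),
                     orientation_reference = "vel_amplitude") {
  if ("parameter" %in% names(table) && !all(parameter_names %in% names(table)))
    table <- cohort_table_wide(table)
  check_columns(table, parameter_names, "trial table")
  X <- as.matrix(table[, parameter_names, drop = FALSE])
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 10) stop("need at least 10 complete rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant parameter(s): %s",
                 paste(parameter_names[sds == 0], collapse = ", ")), call. = FALSE)
  ctr <- colMeans(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  if (!orientation_reference %in% parameter_names)
    orientation_reference <- parameter_names[1]
  ref <- v1[match(orientation_reference, parameter_names)]
  if (ref < 0) v1 <- -v1
  names(v1) <- parameter_names
  Z <- scale(X, center = ctr, scale = sds)
  structure(list(
    loadings = v1,
    explained_variance_fraction = eig$values[1] / length(parameter_names),
    eigenvalues = eig$values,
    scores = as.numeric(Z %*% v1),
    rows_used = which(complete),
    n_dropped = n_dropped,
    center = ctr, scale = sds,
    orientation_reference = orientation_reference
  ), class = "meta_parameter")
}

#' Score new rows on an existing meta-parameter
#'
#' Applies the frozen loadings, centring and scaling of a fitted
#' \code{\link{pca_meta}} to new trials.
#'
#' @param meta A \code{meta_parameter}.
#' @param table Wide trial table containing the same parameter columns.
#' @return Numeric vector of meta-parameter scores.
#' @export
score_meta <- function(meta, table) {
  stopifnot(inherits(meta, "meta_parameter"))
  pars <- names(meta$loadings)
  check_columns(table, pars, "trial table")
  Z <- scale(as.matrix(table[, pars, drop = FALSE]),
             center = meta$center, scale = meta$scale)
  as.numeric(Z %*% meta$loadings)
}

#' @export
print.meta_parameter <- function(x, ...) {
  cat(sprintf("<meta_parameter> %d parameters, first PC explains %.1f%% of variance (%d rows%s)\n",
              length(x$loadings), 100 * x$explained_variance_fraction,
              length(x$scores),
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  print(round(x$loadings, 3))
  invisible(x)
}
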