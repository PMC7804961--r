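#' Predict per-condition curves on a puberty grid
#'
#' Evaluates the fixed-effect part of a fitted model
#' (\code{\link{fit_lmm}}) for each condition over a fine covariate grid
#' (random effects at zero): the PRE and POST (or FIRST and LAST) curves,
#' their pointwise difference, and the standard error of the difference from
#' the fixed-effect covariance via the delta contrast \eqn{c' V c}, where
#' \eqn{c} is the difference of the two design rows at that grid point.
#'
#' @param fit A converged \code{kin_lmm}.
#' @param grid Covariate grid (default \code{seq(from, to, by = step)} over
#'   \code{grid_range}).
#' @param grid_range Default c(5, 20), the puberty scale.
#' @param step Grid step (default 0.01 puberty units).
#' @return An object of class \code{condition_curves}: list with \code{grid},
#'   \code{pre_curve}, \code{post_curve}, \code{difference},
#'   \code{difference_se}, \code{condition_levels}, \code{outcome},
#'   \code{extrapolated} (logical per grid point).
#' @export
predict_condition_curves <- function(fit, grid = NULL,
                                     grid_range = c(5, 20), step = 0.01) {
  stopifnot(inherits(fit, "kin_lmm"))
  if (!fit$converged) stop("model did not converge", call. = FALSE)
  if (is.null(grid)) grid <- seq(grid_range[1], grid_range[2], by = step)
  obs_range <- range(fit$basis$knots)
  extrapolated <- grid < obs_range[1] | grid > obs_range[2]
  if (any(extrapolated))
    warning(sprintf("%d grid point(s) outside the observed covariate range [%g, %g]",
                    sum(extrapolated), obs_range[1], obs_range[2]), call. = FALSE)

  P <- eval_poly_basis(fit$basis, grid)
  nm <- names(fit$beta)
  design_row <- function(s) {
    X <- matrix(0, nrow = length(grid), ncol = length(nm),
                dimnames = list(NULL, nm))
    X[, "(Intercept)"] <- 1
    X[, "s"] <- s
    for (d in seq_len(fit$degree)) {
      X[, paste0("P", d)] <- P[, d]
      if (length(fit$terms$interaction))
        X[, paste0("sP", d)] <- s * P[, d]
    }
    X
  }
  X_pre <- design_row(-0.5)
  X_post <- design_row(0.5)
  C <- X_post - X_pre
  diff <- as.numeric(C %*% fit$beta)
  se <- sqrt(rowSums((C %*% fit$vcov) * C))

  structure(list(grid = grid,
                 pre_curve = as.numeric(X_pre %*% fit$beta),
                 post_curve = as.numeric(X_post %*% fit$beta),
                 difference = diff,
                 difference_se = se,
                 condition_levels = fit$condition_levels,
                 outcome = fit$outcome,
                 extrapolated = extrapolated),
            class = "condition_curves")
}

#' Pointwise Wald tests of the condition difference along the grid
#'
#' At every grid point, a two-sided z-test of \code{difference /
#' difference_se}. No multiplicity correction is applied: the interval of
#' equivalence is defined through the pointwise 5% level.
#'
#' @param curves A \code{condition_curves}.
#' @param alpha Significance level (default 0.05), stored for downstream use.
#' @return The \code{condition_curves} with \code{pointwise_p} and
#'   \code{alpha} added.
#' @export
pointwise_difference_test <- function(curves, alpha = 0.05) {
  stopifnot(inherits(curves, "condition_curves"))
  z <- curves$difference / curves$difference_se
  curves$pointwise_p <- 2 * stats::pnorm(-abs(z))
  curves$alpha <- alpha
  curves
}

#' Crossing point and interval of equivalence
#'
#' The crossing point is the covariate value where the two condition curves
#' intersect: a sign change of the pointwise difference, located by linear
#' interpolation between grid points. The interval of equivalence is the
#' maximal contiguous run of grid points where the pointwise difference is
#' not significant at \code{alpha}, taken around the crossing (or, when the
#' difference never changes sign, around the point of minimum |z|). When the
#' difference changes sign more than once, all roots are returned and the one
#' inside the widest non-significant run is primary.
#'
#' @param curves A \code{condition_curves} (pointwise p-values are computed
#'   if absent).
#' @param alpha Significance level (default 0.05).
#' @return An object of class \code{crossing_result}: list with
#'   \code{crossing_point} (NA when the curves do not cross),
#'   \code{all_crossings}, \code{equivalence_interval} (c(lo, hi), NA when
#'   empty), \code{pointwise_p}, \code{alpha}, \code{no_reversal},
#'   \code{min_abs_z_point}, \code{grid}, \code{outcome}.
#' @export
crossing_and_equivalence <- function(curves, alpha = 0.05) {
  stopifnot(inherits(curves, "condition_curves"))
  if (is.null(curves$pointwise_p) || !identical(curves$alpha, alpha))
    curves <- pointwise_difference_test(curves, alpha)
  g <- curves$grid
  d <- curves$difference
  p <- curves$pointwise_p
  n <- length(g)

  # roots of the difference: exact zeros and sign changes (linear interpolation)
  roots <- g[d == 0]
  sc <- which(d[-n] * d[-1] < 0)
  roots <- sort(unique(c(roots,
    g[sc] + (g[sc + 1] - g[sc]) * d[sc] / (d[sc] - d[sc + 1]))))

  # contiguous non-significant runs
  mask <- p > alpha
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  run_of <- function(x) {
    if (!nrow(runs)) return(NA_integer_)
    hit <- which(g[runs$start] - 1e-12 <= x & x <= g[runs$end] + 1e-12)
    if (length(hit)) hit[1] else NA_integer_
  }

  min_abs_z_point <- g[which.min(abs(d / curves$difference_se))]
  crossing <- NA_real_
  interval <- c(NA_real_, NA_real_)
  no_reversal <- length(roots) == 0

  if (length(roots)) {
    run_idx <- vapply(roots, run_of, integer(1))
    if (any(!is.na(run_idx))) {
      widths <- ifelse(is.na(run_idx), -Inf,
                       runs$end[run_idx] - runs$start[run_idx])
      best <- which.max(widths)
      crossing <- roots[best]
      ri <- run_idx[best]
      interval <- c(g[runs$start[ri]], g[runs$end[ri]])
    } else {
      crossing <- roots[1]
    }
    if (length(roots) > 1)
      message(sprintf("%d crossings found for %s; primary = %.2f (widest non-significant run)",
                      length(roots), curves$outcome %||% "outcome", crossing))
  } else {
    ri <- run_of(min_abs_z_point)
    if (!is.na(ri)) interval <- c(g[runs$start[ri]], g[runs$end[ri]])
  }

  structure(list(crossing_point = crossing,
                 all_crossings = roots,
                 equivalence_interval = interval,
                 pointwise_p = p,
                 alpha = alpha,
                 no_reversal = no_reversal,
                 min_abs_z_point = min_abs_z_point,
                 grid = g,
                 outcome = curves$outcome),
            class = "crossing_result")
}

#' @export
print.crossing_result <- function(x, ...) {
  if (is.na(x$crossing_point)) {
    cat(sprintf("<crossing_result> %s: no reversal detected (min |z| at %.2f)\n",
                x$outcome %||% "outcome", x$min_abs_z_point))
  } else {
    iv <- if (anyNA(x$equivalence_interval)) "none"
          else sprintf("[%d; %d]", floor(x$equivalence_interval[1]),
                       ceiling(x$equivalence_interval[2]))
    cat(sprintf("<crossing_result> %s: crossing %.2f, interval of equivalence %s (alpha = %g)\n",
                x$outcome %||% "outcome", x$crossing_point, iv, x$alpha))
  }
  invisible(x)
}

#' Aggregate per-parameter crossing points
#'
#' Combines the crossing points of several parameters into their mean and
#' median, and carries the meta-parameter's crossing and global interval of
#' equivalence as the primary estimate (the meta-parameter is preferred
#' because a global interval of equivalence exists only for a single fitted
#' curve, not for an average of crossings).
#'
#' @param results Named list of \code{crossing_result}s, or a numeric vector
#'   of crossing points.
#' @param meta_result Optional \code{crossing_result} for the meta-parameter.
#' @return List with \code{mean}, \code{median}, \code{n_crossings},
#'   \code{per_parameter} (named vector), \code{meta_crossing},
#'   \code{meta_interval}, \code{no_reversal}.
#' @examples
#' aggregate_crossings(c(12, 16, 20))$mean  # 16
#' @export
aggregate_crossings <- function(results, meta_result = NULL) {
  if (is.numeric(results)) {
    values <- results
  } else {
    values <- vapply(results, function(r) {
      stopifnot(inherits(r, "crossing_result"))
      r$crossing_point
    }, numeric(1))
  }
  values <- values[!is.na(values)]
  no_reversal <- length(values) == 0
  if (no_reversal)
    warning("no reversal detected: no parameter has a crossing point", call. = FALSE)
  list(mean = if (no_reversal) NA_real_ else mean(values),
       median = if (no_reversal) NA_real_ else stats::median(values),
       n_crossings = length(values),
       per_parameter = values,
       meta_crossing = if (is.null(meta_result)) NA_real_
                       else meta_result$crossing_point,
       meta_interval = if (is.null(meta_result)) c(NA_real_, NA_real_)
                       else meta_result$equivalence_interval,
       no_reversal = no_reversal)
}

#' Build a publication-style crossing table
#'
#' One row per parameter plus Overall rows (Average, Median, Meta-parameter)
#' with the crossing point (2 decimals) and the interval of equivalence.
#' Interval endpoints are rounded outward to integer puberty scores in the
#' display columns; exact endpoints are kept in \code{interval_lo_exact} /
#' \code{interval_hi_exact}.
#'
#' @param results Named list of per-parameter \code{crossing_result}s.
#' @param meta_result Optional meta-parameter \code{crossing_result}.
#' @return Data.frame with columns \code{parameter}, \code{crossing_point},
#'   \code{interval_lo}, \code{interval_hi}, \code{interval_lo_exact},
#'   \code{interval_hi_exact}.
#' @export
crossing_table <- function(results, meta_result = NULL) {
  row1 <- function(name, cp, iv) {
    data.frame(parameter = name,
               crossing_point = round(cp, 2),
               interval_lo = if (anyNA(iv)) NA else floor(iv[1] + 1e-9),
               interval_hi = if (anyNA(iv)) NA else ceiling(iv[2] - 1e-9),
               interval_lo_exact = iv[1], interval_hi_exact = iv[2],
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(results), function(nm)
    row1(nm, results[[nm]]$crossing_point, results[[nm]]$equivalence_interval))
  agg <- aggregate_crossings(results, meta_result)
  rows <- c(rows, list(
    row1("Average", agg$mean, c(NA_real_, NA_real_)),
    row1("Median", agg$median, c(NA_real_, NA_real_))))
  if (!is.null(meta_result))
    rows <- c(rows, list(row1("Meta-parameter", agg$meta_crossing,
                              agg$meta_interval)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Base-graphics plot of condition curves with the pointwise band
#'
#' @param x A \code{condition_curves}.
#' @param ... Passed to \code{matplot}.
#' @export
plot.condition_curves <- function(x, ...) {
  graphics::matplot(x$grid, cbind(x$pre_curve, x$post_curve), type = "l",
                    lty = c(1, 2), col = c("firebrick", "steelblue"),
                    xlab = "puberty score", ylab = x$outcome %||% "outcome", ...)
  graphics::legend("topleft", legend = x$condition_levels, lty = c(1, 2),
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
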