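#' Run the free-hand PRE/POST analysis end to end
#'
#' Reproduces the full free-hand workflow on a trial-level table: (1) build
#' the nine-parameter meta-parameter (first PC of the correlation matrix);
#' (2) decide the puberty trend degree (linear vs quadratic) by likelihood
#' ratio on the meta-parameter -- the chosen degree is then used for every
#' parameter of the task; (3) fit the random-intercept model per parameter
#' and on the meta-parameter, with Type III Wald tests; (4) build the
#' reaching-component and grasping-component meta-parameters, whose
#' session and interaction Wald tests serve as the component-wise global
#' p-values; (5) compute per-parameter and meta-parameter crossing points
#' and intervals of equivalence and the publication-style crossing table.
#'
#' @param trials A long \code{cohort_table} (or wide trial table) with PRE
#'   and POST sessions and at least 2 subjects.
#' @param config List of options: \code{alpha} (default 0.05),
#'   \code{grid_range} (default c(5, 20)), \code{grid_step} (default 0.01),
#'   \code{parameters} (default \code{\link{kin_parameters}}),
#'   \code{orientation_reference}, \code{condition_levels}
#'   (default c("PRE", "POST")).
#' @return An \code{analysis_report}: list with \code{variant},
#'   \code{degree}, \code{lrt}, \code{meta}, \code{meta_fit},
#'   \code{meta_wald}, \code{meta_crossing}, \code{parameters} (per-parameter
#'   list of fit / wald / crossing), \code{components} (reaching, grasping:
#'   explained variance, Wald table), \code{crossing_table},
#'   \code{aggregate}, \code{config}, \code{provenance}.
#' @export
run_freehand_analysis <- function(trials, config = list()) {
  run_session_analysis(trials, config, variant = "freehand",
                       condition = "session",
                       condition_levels = config$condition_levels %||%
                         c("PRE", "POST"))
}

#' Run the tool-use FIRST/LAST block analysis
#'
#' Same workflow as \code{\link{run_freehand_analysis}} on the tool-use
#' session: blocks 1 and 4 are contrasted as FIRST/LAST (intermediate blocks
#' are dropped with a message), and the covariate degree is again selected by
#' likelihood ratio on the meta-parameter (a linear trend in the reference
#' analysis).
#'
#' @param trials A \code{cohort_table} containing a \code{block} column with
#'   blocks 1 and 4 present.
#' @inheritParams run_freehand_analysis
#' @return An \code{analysis_report}.
#' @export
run_tooluse_analysis <- function(trials, config = list()) {
  if ("parameter" %in% names(trials) && !"block" %in% names(trials))
    stop("tool-use trials must carry a `block` column", call. = FALSE)
  wide <- if ("parameter" %in% names(trials)) cohort_table_wide(trials) else trials
  check_columns(wide, "block", "tool-use trials")
  if (!all(c(1, 4) %in% wide$block))
    stop("tool-use analysis needs blocks 1 (FIRST) and 4 (LAST)", call. = FALSE)
  dropped <- sum(!wide$block %in% c(1, 4))
  if (dropped > 0)
    message(sprintf("ignoring %d trials from intermediate blocks 2-3", dropped))
  wide <- wide[wide$block %in% c(1, 4), ]
  wide$block_factor <- ifelse(wide$block == 1, "FIRST", "LAST")
  run_session_analysis(wide, config, variant = "tooluse",
                       condition = "block_factor",
                       condition_levels = c("FIRST", "LAST"))
}

# shared engine behind the free-hand and tool-use drivers
run_session_analysis <- function(trials, config, variant, condition,
                                 condition_levels) {
  alpha <- config$alpha %||% 0.05
  grid_range <- config$grid_range %||% c(5, 20)
  step <- config$grid_step %||% 0.01
  pars <- config$parameters %||% kin_parameters()
  wide <- if ("parameter" %in% names(trials)) cohort_table_wide(trials) else trials
  check_columns(wide, c("subject_id", "puberty", condition, pars),
                sprintf("%s trials", variant))
  lev <- unique(as.character(wide[[condition]]))
  if (!setequal(lev, condition_levels))
    stop(sprintf("%s analysis needs condition levels %s", variant,
                 paste(condition_levels, collapse = "/")), call. = FALSE)
  if (length(unique(wide$subject_id)) < 2)
    stop("need at least 2 subjects", call. = FALSE)

  meta <- pca_meta(wide, pars,
                   orientation_reference = config$orientation_reference %||%
                     "vel_amplitude")
  wide$meta <- score_meta(meta, wide)

  lrt <- lrt_poly_vs_linear(wide, "meta", condition = condition,
                            condition_levels = condition_levels, alpha = alpha)
  degree <- if (lrt$selected == "quadratic") 2 else 1

  fit_one <- function(outcome) {
    fit <- fit_lmm(wide, outcome, condition = condition,
                   condition_levels = condition_levels, degree = degree)
    curves <- pointwise_difference_test(
      predict_condition_curves(fit, grid_range = grid_range, step = step),
      alpha)
    list(fit = fit, wald = wald_type3(fit),
         crossing = crossing_and_equivalence(curves, alpha))
  }
  per_par <- lapply(pars, fit_one)
  names(per_par) <- pars
  meta_res <- fit_one("meta")

  component_meta <- function(comp_pars) {
    cm <- pca_meta(wide, comp_pars,
                   orientation_reference = intersect(
                     c("vel_amplitude", "mga"), comp_pars)[1])
    wide$comp <- score_meta(cm, wide)
    fit <- fit_lmm(wide, "comp", condition = condition,
                   condition_levels = condition_levels, degree = degree)
    list(explained_variance_fraction = cm$explained_variance_fraction,
         loadings = cm$loadings, wald = wald_type3(fit))
  }
  components <- list()
  if (all(reaching_parameters() %in% pars))
    components$reaching <- component_meta(reaching_parameters())
  if (all(grasping_parameters() %in% pars))
    components$grasping <- component_meta(grasping_parameters())

  crossings <- lapply(per_par, `[[`, "crossing")
  report <- list(
    variant = variant,
    degree = degree,
    lrt = lrt[c("chi2", "df", "p", "selected")],
    meta = meta,
    meta_fit = meta_res$fit,
    meta_wald = meta_res$wald,
    meta_crossing = meta_res$crossing,
    parameters = per_par,
    components = components,
    crossing_table = crossing_table(crossings, meta_res$crossing),
    aggregate = aggregate_crossings(crossings, meta_res$crossing),
    config = list(alpha = alpha, grid_range = grid_range, grid_step = step,
                  parameters = pars, condition = condition,
                  condition_levels = condition_levels),
    provenance = report_provenance()
  )
  class(report) <- "analysis_report"
  report
}

#' Run the arm-length-estimation analysis
#'
#' Transforms each estimate to percent of the veridical forearm length
#' (making the outcome comparable across body sizes), selects the puberty
#' trend degree by likelihood ratio, fits the random-intercept session model
#' with Type III Wald tests and computes the crossing point and interval of
#' equivalence of the estimation curves.
#'
#' @param estimates Data.frame with \code{subject_id}, \code{puberty},
#'   \code{session}, \code{trial}, \code{estimate}, \code{forearm_length}.
#' @inheritParams run_freehand_analysis
#' @return An \code{analysis_report} with a single \code{pct_arm_length}
#'   outcome.
#' @export
run_armlength_analysis <- function(estimates, config = list()) {
  check_columns(estimates, c("subject_id", "puberty", "session", "estimate",
                             "forearm_length"), "estimation trials")
  if (any(estimates$forearm_length <= 0, na.rm = TRUE))
    stop("forearm_length must be positive", call. = FALSE)
  alpha <- config$alpha %||% 0.05
  grid_range <- config$grid_range %||% c(5, 20)
  step <- config$grid_step %||% 0.01
  lev <- config$condition_levels %||% c("PRE", "POST")
  estimates$pct_arm_length <- 100 * estimates$estimate / estimates$forearm_length
  if (stats::sd(estimates$pct_arm_length) == 0) {
    # degenerate case: estimates exactly proportional to the veridical arm
    # length leave nothing to model; report "no effects" instead of failing
    report <- list(variant = "armlength", degree = NA_integer_, lrt = NULL,
                   fit = NULL, wald = NULL, crossing = NULL, curves = NULL,
                   constant_outcome = unique(estimates$pct_arm_length),
                   config = list(alpha = alpha), provenance = report_provenance())
    class(report) <- "analysis_report"
    return(report)
  }

  lrt <- lrt_poly_vs_linear(estimates, "pct_arm_length",
                            condition = "session", condition_levels = lev,
                            alpha = alpha)
  degree <- if (lrt$selected == "quadratic") 2 else 1
  fit <- fit_lmm(estimates, "pct_arm_length", condition = "session",
                 condition_levels = lev, degree = degree)
  curves <- pointwise_difference_test(
    predict_condition_curves(fit, grid_range = grid_range, step = step), alpha)
  crossing <- crossing_and_equivalence(curves, alpha)
  report <- list(variant = "armlength",
                 degree = degree,
                 lrt = lrt[c("chi2", "df", "p", "selected")],
                 fit = fit, wald = wald_type3(fit),
                 crossing = crossing, curves = curves,
                 config = list(alpha = alpha, grid_range = grid_range,
                               grid_step = step, condition_levels = lev),
                 provenance = report_provenance())
  class(report) <- "analysis_report"
  report
}

#' Run the gesture-imitation analysis
#'
#' @param scores Data.frame with \code{subject_id}, \code{puberty},
#'   \code{score} (0--72).
#' @param config List; \code{alpha} (default 0.05).
#' @return An \code{analysis_report} wrapping
#'   \code{\link{imitation_regression}}.
#' @export
run_imitation_analysis <- function(scores, config = list()) {
  check_columns(scores, c("puberty", "score"), "imitation scores")
  res <- imitation_regression(scores$score, scores$puberty,
                              alpha = config$alpha %||% 0.05)
  report <- list(variant = "imitation",
                 selected = res$selected,
                 chi2 = res$chi2, df = res$df, p = res$p,
                 linear_fit = res$linear_fit,
                 quadratic_fit = res$quadratic_fit,
                 config = list(alpha = config$alpha %||% 0.05),
                 provenance = report_provenance())
  class(report) <- "analysis_report"
  report
}

report_provenance <- function() {
  list(package_version = as.character(utils::packageVersion("toolplast")),
       r_version = R.version.string,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> variant: %s\n", x$variant))
  if (!is.null(x$lrt))
    cat(sprintf("  trend selection: %s (LRT chi2(%d) = %.2f, p = %.3g)\n",
                x$lrt$selected, x$lrt$df, x$lrt$chi2, x$lrt$p))
  if (!is.null(x$meta)) {
    cat(sprintf("  meta-parameter: first PC explains %.1f%% of variance\n",
                100 * x$meta$explained_variance_fraction))
    print(x$meta_wald)
    print(x$meta_crossing)
    cat("  crossing table:\n")
    print(x$crossing_table[, 1:4])
  }
  if (identical(x$variant, "armlength")) {
    print(x$wald)
    print(x$crossing)
  }
  if (identical(x$variant, "imitation"))
    cat(sprintf("  selected: %s (chi2(%d) = %.2f, p = %.3g)\n",
                x$selected, x$df, x$chi2, x$p))
  invisible(x)
}

#' Re-run the full study from a local data archive and compare
#'
#' Points the pipeline at a directory containing the study's trial-level
#' exports (the original archive is distributed through the Open Science
#' Framework, accession \code{osf.io/3g9mz}; it must be downloaded
#' separately) and compares the recomputed quantities against the printed
#' reference values of \code{\link{reference_study_values}} at documented
#' tolerances. File names and column mappings are configurable so renamed
#' exports can be adapted without editing code; missing files are listed and
#' the run proceeds with what is present.
#'
#' @param data_dir Directory with long-format CSVs.
#' @param config List: \code{files} (named list with entries
#'   \code{freehand}, \code{tooluse}, \code{armlength}, \code{imitation},
#'   \code{cohort}; defaults \code{freehand.csv} etc.), \code{mapping}
#'   (column mapping per file, see \code{\link{read_cohort_table}}),
#'   \code{tolerances} (\code{crossing} 0.05, \code{explained_variance_pct}
#'   0.5, \code{chi2} 0.05, \code{correlation} 0.005), plus the options of
#'   the individual drivers.
#' @return List with \code{reports} (per analysis), \code{comparison}
#'   (data.frame: quantity, value, reference, tolerance, pass),
#'   \code{missing} (files not found).
#' @export
reproduce_study <- function(data_dir, config = list()) {
  files <- utils::modifyList(
    list(freehand = "freehand.csv", tooluse = "tooluse.csv",
         armlength = "armlength.csv", imitation = "imitation.csv",
         cohort = "cohort.csv"),
    config$files %||% list())
  tol <- utils::modifyList(
    list(crossing = 0.05, explained_variance_pct = 0.5, chi2 = 0.05,
         correlation = 0.005),
    config$tolerances %||% list())
  ref <- reference_study_values()
  mapping <- config$mapping %||% list()

  path_of <- function(key) file.path(data_dir, files[[key]])
  missing <- names(files)[!vapply(names(files), function(k)
    file.exists(path_of(k)), logical(1))]
  if (length(missing))
    message("missing file(s), running a partial reproduction: ",
            paste(unlist(files[missing]), collapse = ", "))

  reports <- list()
  comp <- list()
  add <- function(quantity, value, reference, tolerance) {
    comp[[length(comp) + 1L]] <<- data.frame(
      quantity = quantity, value = value, reference = reference,
      tolerance = tolerance, pass = is.finite(value) &&
        abs(value - reference) <= tolerance, stringsAsFactors = FALSE)
  }

  if (!"freehand" %in% missing) {
    tab <- read_cohort_table(path_of("freehand"), mapping$freehand)
    reports$freehand <- run_freehand_analysis(tab, config)
    r <- reports$freehand
    add("freehand_lrt_chi2", r$lrt$chi2, ref$lrt_chi2[["freehand"]], tol$chi2)
    add("freehand_meta_crossing", r$meta_crossing$crossing_point,
        ref$meta_crossing, tol$crossing)
    add("freehand_crossing_mean", r$aggregate$mean, ref$crossing_mean, tol$crossing)
    add("freehand_crossing_median", r$aggregate$median, ref$crossing_median,
        tol$crossing)
    add("freehand_reaching_evf_pct",
        100 * r$components$reaching$explained_variance_fraction,
        ref$explained_variance_pct[["freehand_reaching"]],
        tol$explained_variance_pct)
    add("freehand_grasping_evf_pct",
        100 * r$components$grasping$explained_variance_fraction,
        ref$explained_variance_pct[["freehand_grasping"]],
        tol$explained_variance_pct)
    for (p in kin_parameters())
      add(paste0("crossing_", p), r$parameters[[p]]$crossing$crossing_point,
          ref$crossings$crossing_point[ref$crossings$parameter == p],
          tol$crossing)
  }
  if (!"tooluse" %in% missing) {
    tab <- read_cohort_table(path_of("tooluse"), mapping$tooluse)
    reports$tooluse <- run_tooluse_analysis(tab, config)
    r <- reports$tooluse
    add("tooluse_lrt_chi2", r$lrt$chi2, ref$lrt_chi2[["tooluse"]], tol$chi2)
    add("tooluse_reaching_evf_pct",
        100 * r$components$reaching$explained_variance_fraction,
        ref$explained_variance_pct[["tooluse_reaching"]],
        tol$explained_variance_pct)
    add("tooluse_grasping_evf_pct",
        100 * r$components$grasping$explained_variance_fraction,
        ref$explained_variance_pct[["tooluse_grasping"]],
        tol$explained_variance_pct)
  }
  if (!"armlength" %in% missing) {
    est <- utils::read.csv(path_of("armlength"), stringsAsFactors = FALSE)
    m <- mapping$armlength
    if (!is.null(m)) for (k in names(m)) names(est)[names(est) == m[[k]]] <- k
    reports$armlength <- run_armlength_analysis(est, config)
    r <- reports$armlength
    add("armlength_lrt_chi2", r$lrt$chi2, ref$lrt_chi2[["armlength"]], tol$chi2)
    add("armlength_crossing", r$crossing$crossing_point,
        ref$armlength_crossing, tol$crossing)
  }
  if (!"imitation" %in% missing) {
    sc <- utils::read.csv(path_of("imitation"), stringsAsFactors = FALSE)
    m <- mapping$imitation
    if (!is.null(m)) for (k in names(m)) names(sc)[names(sc) == m[[k]]] <- k
    reports$imitation <- run_imitation_analysis(sc, config)
  }
  if (!"cohort" %in% missing) {
    co <- utils::read.csv(path_of("cohort"), stringsAsFactors = FALSE)
    m <- mapping$cohort
    if (!is.null(m)) for (k in names(m)) names(co)[names(co) == m[[k]]] <- k
    if (all(c("height", "forearm_length") %in% names(co)))
      add("height_forearm_r", stats::cor(co$height, co$forearm_length),
          ref$height_forearm_r, tol$correlation)
  }

  list(reports = reports,
       comparison = if (length(comp)) do.call(rbind, comp) else
         data.frame(quantity = character(), value = numeric(),
                    reference = numeric(), tolerance = numeric(),
                    pass = logical()),
       missing = missing)
}
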