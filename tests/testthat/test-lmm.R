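sim_table <- function(n_sub = 30, n_trials = 6, seed = 21, ...) {
  cohort <- generate_cohort(n_sub, seed = seed)
  generate_trial_parameters(cohort, one_param_specs(...), n_trials = n_trials,
                            seed = seed + 1)
}

test_that("with zero between-subject variance the fit reduces to OLS", {
  cohort <- small_cohort(25, seed = 41)
  spec <- effect_spec(baseline = 50, session_main = 2,
                      puberty_curve = c(1, -0.02),
                      interaction_curve = c(0, 0.5, 0),
                      subject_sd = 0, residual_sd = 3)
  tab <- generate_trial_parameters(cohort, list(y = spec), n_trials = 5,
                                   seed = 42)
  wide <- cohort_table_wide(tab)
  fit <- suppressWarnings(fit_lmm(wide, "y"))
  expect_true(fit$singular)

  b <- orthogonal_poly_basis(wide$puberty, 2)
  s <- ifelse(wide$session == "POST", 0.5, -0.5)
  X <- data.frame(y = wide$y, s = s, P1 = b$columns[, 1], P2 = b$columns[, 2])
  ols <- lm(y ~ s + P1 + P2 + s:P1 + s:P2, data = X)
  expect_equal(unname(fit$beta[c("s", "P1", "P2")]),
               unname(coef(ols)[c("s", "P1", "P2")]), tolerance = 1e-6)
  expect_equal(unname(fit$beta[c("sP1", "sP2")]),
               unname(coef(ols)[c("s:P1", "s:P2")]), tolerance = 1e-6)
})

test_that("in a balanced design the condition coefficient is the mean difference", {
  cohort <- small_cohort(20, seed = 43)
  spec <- effect_spec(baseline = 10, session_main = 1.5, subject_sd = 0,
                      residual_sd = 2)
  tab <- generate_trial_parameters(cohort, list(y = spec), n_trials = 6,
                                   seed = 44)
  wide <- cohort_table_wide(tab)
  fit <- suppressWarnings(fit_lmm(wide, "y"))
  mean_diff <- mean(wide$y[wide$session == "POST"]) -
    mean(wide$y[wide$session == "PRE"])
  expect_equal(unname(fit$beta["s"]), mean_diff, tolerance = 1e-8)
})

test_that("single-coefficient Wald chi-square equals (beta/SE)^2 exactly", {
  tab <- sim_table(seed = 45)
  fit <- fit_lmm(tab, "vel_amplitude")
  w <- wald_type3(fit)
  se_s <- sqrt(fit$vcov["s", "s"])
  expect_equal(w$chi2[w$term == "condition"],
               unname((fit$beta["s"] / se_s)^2), tolerance = 1e-10)
  expect_equal(w$df, c(1, 2, 2))
  expect_true(all(w$p >= 0 & w$p <= 1))
})

test_that("Type III Wald tests agree with car::Anova on the same design", {
  tab <- sim_table(seed = 46)
  fit <- fit_lmm(tab, "vel_amplitude")
  w <- wald_type3(fit)

  wide <- cohort_table_wide(tab)
  dat <- data.frame(y = wide$vel_amplitude,
                    s = ifelse(wide$session == "POST", 0.5, -0.5),
                    x = wide$puberty, subject = wide$subject_id)
  refit <- lme4::lmer(y ~ s * poly(x, 2) + (1 | subject), data = dat)
  ca <- car::Anova(refit, type = "III")
  expect_equal(w$chi2[w$term == "condition"], ca["s", "Chisq"],
               tolerance = 1e-6)
  expect_equal(w$chi2[w$term == "covariate"], ca["poly(x, 2)", "Chisq"],
               tolerance = 1e-6)
  expect_equal(w$chi2[w$term == "interaction"], ca["s:poly(x, 2)", "Chisq"],
               tolerance = 1e-6)
})

test_that("fitted values and Type III p-values are basis-invariant", {
  tab <- sim_table(seed = 47)
  fit <- fit_lmm(tab, "vel_amplitude")
  w <- wald_type3(fit)

  wide <- cohort_table_wide(tab)
  xc <- wide$puberty - mean(wide$puberty)
  dat <- data.frame(y = wide$vel_amplitude,
                    s = ifelse(wide$session == "POST", 0.5, -0.5),
                    xc = xc, xc2 = xc^2, subject = wide$subject_id)
  raw <- lme4::lmer(y ~ s + xc + xc2 + s:xc + s:xc2 + (1 | subject),
                    data = dat)
  expect_equal(unname(fitted(fit$fit)), unname(fitted(raw)), tolerance = 1e-8)
  bb <- lme4::fixef(raw)[c("s:xc", "s:xc2")]
  Vb <- as.matrix(vcov(raw))[c("s:xc", "s:xc2"), c("s:xc", "s:xc2")]
  chi2_raw <- as.numeric(t(bb) %*% solve(Vb, bb))
  expect_equal(w$chi2[w$term == "interaction"], chi2_raw, tolerance = 1e-6)
})

test_that("fixed effects are recovered at realistic scale", {
  cohort <- generate_cohort(90, seed = 48)
  sp <- default_effect_specs()[["vel_amplitude"]]
  tab <- generate_trial_parameters(cohort, list(vel_amplitude = sp),
                                   n_trials = 18, seed = 49)
  fit <- fit_lmm(tab, "vel_amplitude")
  # grid points below the cohort minimum are flagged as extrapolation
  curves <- suppressWarnings(predict_condition_curves(fit))
  # fitted difference at the scale ends within 3 SEs of the truth
  for (p in c(5, 20)) {
    i <- which.min(abs(curves$grid - p))
    expect_lt(abs(curves$difference[i] - difference_function(sp, p)) /
                curves$difference_se[i], 3)
  }
  # variance components near their generative values (within 30%)
  expect_lt(abs(sqrt(fit$residual_variance) - sp$residual_sd) / sp$residual_sd,
            0.3)
  expect_lt(abs(sqrt(fit$random_intercept_variance) - sp$subject_sd) /
              sp$subject_sd, 0.3)
})

test_that("likelihood-ratio selection is sane and monotone under nesting", {
  tab <- sim_table(seed = 50)
  l <- lrt_poly_vs_linear(tab, "vel_amplitude")
  expect_gte(l$chi2, 0)
  expect_equal(l$df, 2)
  expect_gte(l$fit_quadratic$log_likelihood, l$fit_linear$log_likelihood - 1e-6)
  expect_true(l$selected %in% c("linear", "quadratic"))

  # a strong quadratic interaction forces the quadratic model
  cohort <- generate_cohort(40, seed = 51)
  sp <- effect_spec(baseline = 656, interaction_curve = c(0, -40, 3),
                    subject_sd = 70, residual_sd = 70, target_crossing = 16)
  tabq <- generate_trial_parameters(cohort, list(y = sp), n_trials = 8,
                                    seed = 52)
  lq <- lrt_poly_vs_linear(tabq, "y")
  expect_equal(lq$selected, "quadratic")
  expect_lt(lq$p, 0.001)
})

test_that("model validation rejects bad inputs", {
  tab <- sim_table(n_sub = 5, seed = 53)
  one_sub <- tab[tab$subject_id == tab$subject_id[1], ]
  expect_error(fit_lmm(one_sub, "vel_amplitude"), "2 subjects")
  wide <- cohort_table_wide(tab)
  wide$vel_amplitude <- 1
  expect_error(fit_lmm(wide, "vel_amplitude"), "constant")
  expect_error(fit_lmm(tab, "not_a_column"), "missing")
})
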