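test_that("null effects with zero noise give identical PRE and POST values", {
  cohort <- small_cohort(6)
  spec <- effect_spec(baseline = 100, puberty_curve = c(2, 0.1),
                      subject_sd = 0, residual_sd = 0)
  tab <- generate_trial_parameters(cohort, effects = list(p1 = spec),
                                   n_trials = 4, seed = 5)
  wide <- cohort_table_wide(tab)
  pre <- wide[wide$session == "PRE", ]
  post <- wide[wide$session == "POST", ]
  key <- function(d) d[order(d$subject_id, d$trial), "p1"]
  expect_equal(key(pre), key(post))
  # and the values are the deterministic fixed-effect means
  expect_equal(pre$p1, 100 + 2 * pre$puberty + 0.1 * pre$puberty^2)
})

test_that("a target crossing places an exact zero of the population difference", {
  for (cstar in c(7.5, 12, 16)) {
    spec <- effect_spec(session_main = 3, interaction_curve = c(0, -5, 0.1),
                        target_crossing = cstar)
    expect_equal(difference_function(spec, cstar), 0, tolerance = 1e-12)
  }
  # with a linear g the difference changes sign at c* and nowhere else in [5,20]
  spec <- effect_spec(interaction_curve = c(0, -4, 0), target_crossing = 16)
  grid <- seq(5, 20, by = 0.01)
  d <- difference_function(spec, grid)
  expect_true(all(d[grid < 15.99] > 0))
  expect_true(all(d[grid > 16.01] < 0))
  expect_lt(abs(grid[which.min(abs(d))] - 16), 0.011)
})

test_that("generator output is seed-deterministic and statistically calibrated", {
  cohort <- generate_cohort(90, seed = 1)
  specs <- one_param_specs()
  a <- generate_trial_parameters(cohort, specs, n_trials = 18, seed = 3)
  b <- generate_trial_parameters(cohort, specs, n_trials = 18, seed = 3)
  expect_identical(a, b)

  # subject x session cell means vs population means, standardised by the
  # analytic SD of a cell mean: sqrt(subject_sd^2 + residual_sd^2 / n_trials)
  sp <- specs[[1]]
  wide <- cohort_table_wide(a)
  cm <- aggregate(vel_amplitude ~ subject_id + session + puberty,
                  data = wide, FUN = mean)
  s <- ifelse(cm$session == "POST", 0.5, -0.5)
  pop <- sp$baseline + s * difference_function(sp, cm$puberty) +
    sp$puberty_curve[1] * cm$puberty + sp$puberty_curve[2] * cm$puberty^2
  se_cell <- sqrt(sp$subject_sd^2 + sp$residual_sd^2 / 18)
  z <- (cm$vel_amplitude - pop) / se_cell
  expect_gt(mean(abs(z) <= 3), 0.97)
  expect_lt(max(abs(z)), 5)
  # the within-subject POST-PRE mean difference cancels the random intercept:
  # its analytic SE is sqrt(2) * residual_sd / sqrt(n_trials)
  d_obs <- cm$vel_amplitude[cm$session == "POST"] -
    cm$vel_amplitude[cm$session == "PRE"]
  d_pop <- difference_function(sp, cm$puberty[cm$session == "POST"])
  zd <- (d_obs - d_pop) / (sqrt(2) * sp$residual_sd / sqrt(18))
  expect_gt(mean(abs(zd) <= 3), 0.95)
})

test_that("the shared vigour factor induces realistic cross-parameter structure", {
  cohort <- generate_cohort(60, seed = 2)
  tab <- generate_trial_parameters(cohort, n_trials = 6, seed = 4)
  wide <- cohort_table_wide(tab)
  mp <- pca_meta(wide)
  expect_gt(mp$explained_variance_fraction, 0.5)
  expect_lt(mp$explained_variance_fraction, 0.85)
  # amplitudes and latencies load with opposite signs on the first component
  expect_gt(mp$loadings[["vel_amplitude"]] * mp$loadings[["acc_amplitude"]], 0)
  expect_lt(mp$loadings[["vel_amplitude"]] * mp$loadings[["vel_latency"]], 0)
})

test_that("block generator contrasts FIRST/LAST and fills the block column", {
  cohort <- small_cohort(8)
  tab <- generate_block_parameters(cohort, one_param_specs(), n_trials = 3,
                                   seed = 6)
  expect_setequal(unique(tab$block), 1:4)
  expect_true(all(tab$session == "TOOL"))
  expect_equal(nrow(tab), 8 * 3 * 4)
})
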