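test_that("an injected linear difference crosses exactly where constructed", {
  # difference(p) = 2 * (p - 16), SE constant 0.5
  fit <- fake_fit(beta_s = 0, g_raw = c(-32, 2), se_s = 0.5)
  curves <- predict_condition_curves(fit)
  expect_equal(curves$difference, 2 * (curves$grid - 16), tolerance = 1e-8)
  expect_equal(curves$post_curve - curves$pre_curve, curves$difference)
  res <- crossing_and_equivalence(curves)
  expect_equal(res$crossing_point, 16, tolerance = 1e-6)
  expect_false(res$no_reversal)
  # crossing lies inside the interval of equivalence
  expect_true(res$equivalence_interval[1] <= res$crossing_point &&
                res$crossing_point <= res$equivalence_interval[2])
  # analytic endpoints: |2 (p - 16)| = 1.96 * 0.5  =>  16 -+ 0.49
  z <- qnorm(0.975)
  expect_lt(abs(res$equivalence_interval[1] - (16 - z * 0.5 / 2)), 0.011)
  expect_lt(abs(res$equivalence_interval[2] - (16 + z * 0.5 / 2)), 0.011)
})

test_that("pointwise tests behave at the null and at the 1.96 SE boundary", {
  fit <- fake_fit(beta_s = 0, g_raw = c(0, 0), se_s = 0.4)
  curves <- pointwise_difference_test(predict_condition_curves(fit))
  expect_true(all(abs(curves$pointwise_p - 1) < 1e-6))

  # a constant difference equal to 1.96 SE gives p close to 0.05 everywhere
  fit2 <- fake_fit(beta_s = qnorm(0.975) * 0.4, g_raw = c(0, 0), se_s = 0.4)
  curves2 <- pointwise_difference_test(predict_condition_curves(fit2))
  expect_equal(unique(round(curves2$pointwise_p, 4)), 0.05, tolerance = 1e-3)
})

test_that("parallel curves yield no crossing and an empty interval", {
  fit <- fake_fit(beta_s = 5, g_raw = c(0, 0), se_s = 0.1)  # constant, far from 0
  res <- crossing_and_equivalence(predict_condition_curves(fit))
  expect_true(res$no_reversal)
  expect_true(is.na(res$crossing_point))
  expect_true(all(is.na(res$equivalence_interval)))
  expect_true(!is.na(res$min_abs_z_point))
})

test_that("multiple sign changes return all roots with a primary crossing", {
  # difference(p) = -(p - 8)(p - 18) / 10: roots at 8 and 18
  fit <- fake_fit(beta_s = 0, g_raw = c(-14.4, 2.6, -0.1), se_s = 0.5)
  expect_message(res <- crossing_and_equivalence(
    predict_condition_curves(fit)), "2 crossings")
  expect_equal(sort(res$all_crossings), c(8, 18), tolerance = 1e-4)
  expect_true(res$crossing_point %in% res$all_crossings)
})

test_that("the interval is monotone in alpha and stable under grid refinement", {
  fit <- fake_fit(beta_s = 0, g_raw = c(-24, 1.5), se_s = 0.8)
  c1 <- predict_condition_curves(fit, step = 0.01)
  r05 <- crossing_and_equivalence(c1, alpha = 0.05)
  r01 <- crossing_and_equivalence(c1, alpha = 0.01)
  expect_lte(r01$equivalence_interval[1], r05$equivalence_interval[1])
  expect_gte(r01$equivalence_interval[2], r05$equivalence_interval[2])

  c2 <- predict_condition_curves(fit, step = 0.005)
  r_fine <- crossing_and_equivalence(c2, alpha = 0.05)
  expect_lt(abs(r_fine$crossing_point - r05$crossing_point), 0.01)
})

test_that("crossing recovery works on an estimated model", {
  cohort <- generate_cohort(90, seed = 71)
  tab <- generate_trial_parameters(cohort, one_param_specs(), n_trials = 18,
                                   seed = 72)
  fit <- fit_lmm(tab, "vel_amplitude")
  res <- crossing_and_equivalence(
    pointwise_difference_test(predict_condition_curves(fit)))
  expect_lt(abs(res$crossing_point - 16), 1.5)
  expect_true(res$equivalence_interval[1] <= res$crossing_point &&
                res$crossing_point <= res$equivalence_interval[2])
})

test_that("aggregation reduces crossing points as specified", {
  expect_equal(aggregate_crossings(c(12, 16, 20))$mean, 16)
  expect_equal(aggregate_crossings(c(12, 16, 20))$median, 16)
  one <- aggregate_crossings(c(14))
  expect_equal(one$mean, 14)
  expect_equal(one$median, 14)
  expect_warning(empty <- aggregate_crossings(numeric(0)), "no reversal")
  expect_true(empty$no_reversal)
  expect_true(is.na(empty$mean))
})

test_that("the crossing table has parameter rows plus the overall rows", {
  fit <- fake_fit(beta_s = 0, g_raw = c(-32, 2), se_s = 0.5)
  res <- crossing_and_equivalence(predict_condition_curves(fit))
  tab <- crossing_table(list(vel_amplitude = res, mga = res), res)
  expect_equal(tab$parameter,
               c("vel_amplitude", "mga", "Average", "Median", "Meta-parameter"))
  expect_equal(tab$crossing_point[1], 16, tolerance = 0.01)
  # display endpoints are integers rounded outward
  expect_true(all(tab$interval_lo[c(1, 2, 5)] ==
                    floor(tab$interval_lo_exact[c(1, 2, 5)] + 1e-9)))
})
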