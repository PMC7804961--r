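# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense-grid numerical differentiation for the
# minimum-jerk extrema, Gram-Schmidt for the polynomial basis, prcomp for the
# PCA scores.

# dense numerical oracle for a minimum-jerk reach: extrema of speed and of
# the derivative of speed, plus the 10 mm/s onset, from brute-force evaluation
minjerk_oracle <- function(D, T, dt = 1e-5, onset_threshold = 10) {
  tau <- seq(0, 1, by = dt / T)
  x <- D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  t <- tau * T
  v <- c(diff(x) / (dt), NA)
  v <- v[!is.na(v)]
  tv <- t[-length(t)] + dt / 2
  a <- diff(v) / dt
  ta <- tv[-length(tv)] + dt / 2
  i_on <- which(v >= onset_threshold)[1]
  i_vp <- which.max(v)
  i_acc <- which.max(a[ta < tv[i_vp]])
  dec_region <- which(ta > tv[i_vp])
  i_dec <- dec_region[which.min(a[dec_region])]
  list(onset = tv[i_on],
       vel_peak = max(v), vel_peak_time = tv[i_vp],
       acc_peak = max(a), acc_peak_time = ta[i_acc],
       dec_peak = abs(min(a)), dec_peak_time = ta[i_dec])
}

# brute-force Gram-Schmidt orthonormalisation of {x - mean, (x - mean)^2}
gram_schmidt_poly <- function(x, degree) {
  xc <- x - mean(x)
  cols <- list(xc)
  if (degree == 2) cols[[2]] <- xc^2
  out <- matrix(0, length(x), degree)
  for (j in seq_len(degree)) {
    v <- cols[[j]] - mean(cols[[j]])
    if (j > 1) for (k in 1:(j - 1)) v <- v - sum(v * out[, k]) * out[, k]
    out[, j] <- v / sqrt(sum(v^2))
  }
  out
}

# a bare kinematic_profile built from explicit series (unit-level fixtures)
make_profile <- function(times, speed, accel = NULL, aperture = NULL) {
  structure(list(sample_times = times,
                 tangential_velocity = speed,
                 tangential_acceleration = accel %||% rep(0, length(times)),
                 grip_aperture = aperture %||% rep(30, length(times)),
                 fs = 1 / median(diff(times))),
            class = "kinematic_profile")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# a hand-built kin_lmm with known coefficients (bypasses estimation):
# difference(p) = beta_s + g1 * B1(p) + g2 * B2(p) on the orthogonal basis
fake_fit <- function(beta_s, g_raw, knots = seq(5, 20, length.out = 50),
                     se_s = 0.1, degree = 2) {
  basis <- orthogonal_poly_basis(knots, degree = degree)
  # convert a raw-coefficient difference d(p) = c0 + c1 p (+ c2 p^2) into
  # coefficients on the orthogonal basis by least squares on the knots
  P <- cbind(1, basis$columns)
  d_knots <- g_raw[1] + g_raw[2] * knots +
    (if (length(g_raw) > 2) g_raw[3] * knots^2 else 0)
  cf <- solve(crossprod(P), crossprod(P, d_knots))
  nm <- c("(Intercept)", "s", paste0("P", 1:degree), paste0("sP", 1:degree))
  beta <- stats::setNames(numeric(length(nm)), nm)
  beta["s"] <- beta_s + cf[1]
  for (d in 1:degree) beta[paste0("sP", d)] <- cf[d + 1]
  V <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  V["s", "s"] <- se_s^2
  diag(V)[diag(V) == 0] <- 1e-12
  structure(list(beta = beta, vcov = V, basis = basis,
                 terms = list(condition = "s",
                              covariate = paste0("P", 1:degree),
                              interaction = paste0("sP", 1:degree)),
                 outcome = "synthetic", condition = "session",
                 condition_levels = c("PRE", "POST"),
                 covariate = "puberty", degree = degree,
                 converged = TRUE, singular = FALSE),
            class = "kin_lmm")
}

# small standard fixtures
small_cohort <- function(n = 20, seed = 11) generate_cohort(n, seed = seed)

one_param_specs <- function(..., parameter = "vel_amplitude") {
  specs <- default_effect_specs(...)
  specs[parameter]
}
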