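# A curve whose plateaus are exactly the baselines (piecewise ramp),
# for testing the baseline machinery in isolation.
ramp_curve <- function(folded = c(10, -0.01), unfolded = c(1, -0.002),
                       Ct = 50e-6) {
  tc <- seq(0, 90, by = 1)
  alpha <- ifelse(tc <= 30, 1, ifelse(tc >= 60, 0, (60 - tc) / 30))
  f <- folded[1] + folded[2] * tc
  u <- unfolded[1] + unfolded[2] * tc
  melting_curve(tc, alpha * f + (1 - alpha) * u, Ct = Ct)
}

test_that("baseline fitting recovers known plateau lines and flags degeneracies", {
  cv <- ramp_curve()
  bl <- fit_baselines(cv, low_window = c(0, 25), high_window = c(65, 90))
  expect_equal(unname(bl$folded), c(10, -0.01), tolerance = 1e-10)
  expect_equal(unname(bl$unfolded), c(1, -0.002), tolerance = 1e-10)
  expect_false(bl$low_confidence)

  # flat curve: no transition to resolve
  flat <- melting_curve(seq(0, 90, by = 1), rep(5, 91), Ct = 1e-4)
  expect_error(fit_baselines(flat), "no resolvable transition")

  # minimal 4-point windows are allowed but flagged
  bl4 <- fit_baselines(cv, low_window = c(0, 3), high_window = c(87, 90))
  expect_true(bl4$low_confidence)

  # a window outside the data range is named in the error
  expect_error(fit_baselines(cv, low_window = c(-40, -20),
                             high_window = c(65, 90)), "low baseline window")
  expect_error(fit_baselines(cv, low_window = c(0, 25),
                             high_window = c(95, 130)), "high baseline window")
  expect_error(fit_baselines(cv, low_window = c(0, 50),
                             high_window = c(40, 90)), "overlap")
})

test_that("signal-to-fraction conversion hits the endpoints and midpoint", {
  cv <- ramp_curve()
  bl <- fit_baselines(cv, low_window = c(0, 25), high_window = c(65, 90))
  frac <- signal_to_fraction(cv, bl)
  # on the folded plateau alpha = 1, on the unfolded plateau alpha = 0
  expect_equal(frac$alpha[cv$temperature_C <= 25],
               rep(1, sum(cv$temperature_C <= 25)), tolerance = 1e-9)
  expect_equal(frac$alpha[cv$temperature_C >= 65],
               rep(0, sum(cv$temperature_C >= 65)), tolerance = 1e-9)
  # the ramp construction crosses the exact baseline midpoint at T = 45
  expect_equal(frac$alpha[cv$temperature_C == 45], 0.5, tolerance = 1e-10)

  # generator curve at the cyclic-decamer parameters: alpha near 1/2 at
  # the reported Tm of 42 C (Ct = 50 uM); the generator's own baselines
  # isolate the conversion from baseline-estimation error
  cvg <- simulate_melting(ref_params(1), Ct = 50e-6)
  fg <- signal_to_fraction(cvg, default_baselines())
  a42 <- stats::approx(fg$temperature_C, fg$alpha, xout = 42.0)$y
  expect_lt(abs(a42 - 0.5), 0.01)
})

test_that("fraction-to-lnK inverts the mass balance", {
  tc <- seq(20, 58, by = 2)
  # alpha = 0.5 at Ct = 50 uM: K = 0.5/(2 * 5e-5 * 0.25) = 20000
  frac <- structure(
    data.frame(temperature_C = tc, alpha = rep(0.5, length(tc)),
               alpha_raw = rep(0.5, length(tc)),
               clipped = rep(FALSE, length(tc))),
    Ct = 50e-6, class = c("fraction_curve", "data.frame"))
  pts <- fraction_to_lnK(frac, molecularity = 2)
  expect_equal(pts$lnK, rep(log(20000), length(tc)), tolerance = 1e-12)

  # round trip: alpha from equilibrium_fraction maps back to the same lnK
  p <- ref_params(1)
  TK <- seq(300, 320, by = 1)
  a <- equilibrium_fraction(p, TK, Ct = 50e-6)
  frac2 <- structure(
    data.frame(temperature_C = TK - 273.15, alpha = a, alpha_raw = a,
               clipped = rep(FALSE, length(a))),
    Ct = 50e-6, class = c("fraction_curve", "data.frame"))
  pts2 <- fraction_to_lnK(frac2, molecularity = 2)
  expect_equal(pts2$lnK, vant_hoff_lnK(p, 1 / pts2$inv_T), tolerance = 1e-9)

  # molecularity 1: alpha = 0.5 means lnK = 0
  pts1 <- fraction_to_lnK(frac, molecularity = 1)
  expect_equal(pts1$lnK, rep(0, length(tc)), tolerance = 1e-12)

  # too few usable points
  frac$alpha[1:16] <- 0.99
  expect_error(fraction_to_lnK(frac), "insufficient transition sampling")
})

test_that("van't Hoff regression recovers generating parameters and maps errors", {
  p <- ref_params(1)
  TK <- seq(295, 325, length.out = 30)
  pts <- data.frame(inv_T = 1 / TK, lnK = vant_hoff_lnK(p, TK))
  est <- vant_hoff_fit(pts)
  expect_equal(est$params$dH, p$dH, tolerance = 1e-9)
  expect_equal(TdS(est$params, 298.15), -30.2, tolerance = 1e-9)
  expect_gt(est$r_squared, 0.999999)
  expect_lt(est$se_dH, 1e-8)

  # two exact points interpolate with zero residual and flagged SEs
  est2 <- vant_hoff_fit(pts[c(1, 30), ])
  expect_equal(est2$params$dH, p$dH, tolerance = 1e-9)
  expect_true(est2$se_undefined)
  expect_identical(est2$se_dH, 0)

  # singular design
  bad <- data.frame(inv_T = rep(1 / 300, 6), lnK = rnorm(6))
  expect_error(vant_hoff_fit(bad), "singular")
})

test_that("reported SEs are calibrated: 3-SE coverage of dH over seeded noise", {
  p <- ref_params(1)
  TK <- seq(295, 325, length.out = 30)
  lnK_true <- vant_hoff_lnK(p, TK)
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    est <- vant_hoff_fit(data.frame(inv_T = 1 / TK,
                                    lnK = lnK_true + rnorm(30, sd = 0.05)))
    if (abs(est$params$dH - p$dH) <= 3 * est$se_dH) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("error propagation uses the full covariance and matches Monte Carlo", {
  base <- list(params = thermo_params(-38, dS = -0.1), se_dH = 0, se_dS = 0,
               cov_dH_dS = 0, r_squared = 1, n = 30, molecularity = 2L,
               Ct = 50e-6)
  class(base) <- "thermo_estimate"

  # zero input SEs give zero propagated errors
  d0 <- derived_with_errors(base, Ct = 50e-6)$derived
  expect_identical(d0$se_dG, 0)
  expect_identical(d0$se_Tm, 0)

  # sigma(dH) = a alone propagates to sigma(dG) = a
  e1 <- base; e1$se_dH <- 0.37
  expect_equal(derived_with_errors(e1, Ct = 50e-6)$derived$se_dG, 0.37)

  # refuse to propagate without a covariance
  e2 <- base; e2$cov_dH_dS <- NA_real_
  expect_error(derived_with_errors(e2, Ct = 50e-6), "covariance")

  # Monte Carlo oracle on a realistic correlated (dH, dS) fit
  p <- ref_params(1)
  TK <- seq(295, 325, length.out = 30)
  set.seed(11)
  est <- vant_hoff_fit(data.frame(
    inv_T = 1 / TK, lnK = vant_hoff_lnK(p, TK) + rnorm(30, sd = 0.05)))
  est <- derived_with_errors(est, Ct = 50e-6)
  V <- matrix(c(est$se_dH^2, est$cov_dH_dS, est$cov_dH_dS, est$se_dS^2), 2)
  set.seed(12)
  z <- matrix(rnorm(2e5), ncol = 2) %*% chol(V)
  draws_dH <- est$params$dH + z[, 1]
  draws_dS <- est$params$dS + z[, 2]
  expect_equal(stats::sd(draws_dH - 298.15 * draws_dS), est$derived$se_dG,
               tolerance = 0.05)
  draws_Tm <- draws_dH / (draws_dS + R_kcal * log(50e-6)) - 273.15
  expect_equal(stats::sd(draws_Tm), est$derived$se_Tm, tolerance = 0.05)
  # derived central values agree with the model layer exactly
  expect_identical(est$derived$Tm_C,
                   melting_temperature(est$params, Ct = 50e-6))
  expect_identical(est$derived$dG, free_energy(est$params, 298.15))
})

test_that("full pipeline round-trips all reference parameter sets to <0.1%", {
  for (i in 1:3) {
    cv <- simulate_melting(ref_params(i), Ct = ref_rows$Ct[i])
    est <- fit_melting(cv)
    expect_lt(abs(est$params$dH - ref_rows$dH[i]) / abs(ref_rows$dH[i]), 1e-3)
    expect_lt(abs(TdS(est$params, 298.15) - ref_rows$TdS298[i]) /
                abs(ref_rows$TdS298[i]), 1e-3)
    expect_gt(est$r_squared, 0.999999)
    # model-free Tm agrees with the model Tm on noiseless data
    expect_equal(est$tm_observed_C,
                 melting_temperature(est$params, Ct = ref_rows$Ct[i]),
                 tolerance = 0.05)
  }
})

test_that("estimates are invariant to affine rescaling of the signal", {
  cv <- simulate_melting(ref_params(1), Ct = 50e-6, noise_sd = 0.15, seed = 33)
  est1 <- fit_melting(cv)
  cv2 <- melting_curve(cv$temperature_C, 3.7 * cv$signal - 12, Ct = 50e-6)
  est2 <- fit_melting(cv2, min_gap = 0.5 * 3.7)
  expect_equal(est2$params$dH, est1$params$dH, tolerance = 1e-6)
  expect_equal(est2$params$dS, est1$params$dS, tolerance = 1e-6)
  expect_equal(est2$derived$Tm_C, est1$derived$Tm_C, tolerance = 1e-6)
})

test_that("Tm-vs-concentration analysis recovers dH and spots unimolecular series", {
  p <- ref_params(1)
  Cts <- c(20e-6, 50e-6, 100e-6)
  series <- data.frame(Ct = Cts,
                       Tm_C = vapply(Cts, function(ct)
                         melting_temperature(p, Ct = ct), 0))
  fit <- fit_tm_vs_concentration(series)
  expect_false(fit$unimolecular)
  expect_lt(abs(fit$params$dH - p$dH), 0.1)
  # round trip: fitted params reproduce the Tm series through the model
  for (k in seq_along(Cts)) {
    expect_equal(melting_temperature(fit$params, Ct = Cts[k]),
                 series$Tm_C[k], tolerance = 1e-6)
  }
  # two points interpolate exactly
  fit2 <- fit_tm_vs_concentration(series[c(1, 3), ])
  expect_equal(fit2$params$dH, p$dH, tolerance = 1e-6)

  # the cyclic-decamer shift between 20 and 50 uM is 4-5 degrees
  dTm <- series$Tm_C[2] - series$Tm_C[1]
  expect_gte(dTm, 4); expect_lte(dTm, 5)

  # constant-Tm series is flagged unimolecular rather than fitted
  uni <- data.frame(Ct = Cts, Tm_C = rep(35, 3))
  ufit <- fit_tm_vs_concentration(uni)
  expect_true(ufit$unimolecular)
  expect_match(ufit$note, "unimolecular")

  expect_error(fit_tm_vs_concentration(data.frame(Ct = c(1e-4, 1e-4),
                                                  Tm_C = c(35, 36))),
               "singular")
})
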