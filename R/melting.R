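# Melting-curve analysis: baselines -> fraction folded -> lnK -> van't
# Hoff regression with error propagation, plus Tm-vs-concentration.

#' Construct a melting curve
#'
#' A melting curve is a temperature/signal series (CD or UV, monitored at
#' a fixed wavelength) annotated with the total strand concentration it
#' was recorded at, which the homodimer model needs to turn fractions into
#' equilibrium constants.
#'
#' @param temperature_C Strictly increasing temperatures, degrees Celsius.
#' @param signal Spectroscopic signal (e.g. CD ellipticity in mdeg) at
#'   each temperature.
#' @param Ct Total strand concentration, mol/L.
#' @param pH,wavelength_nm,buffer,heating_rate Optional acquisition
#'   metadata carried along (heating rate in degrees C per minute).
#' @return A data frame of class `melting_curve` with columns
#'   `temperature_C` and `signal` and attributes `Ct` and `meta`.
#' @export
melting_curve <- function(temperature_C, signal, Ct, pH = NA_real_,
                          wavelength_nm = 262, buffer = NA_character_,
                          heating_rate = 0.5) {
  temperature_C <- as.numeric(temperature_C)
  signal <- as.numeric(signal)
  if (length(temperature_C) != length(signal)) {
    stop("'temperature_C' and 'signal' must have the same length", call. = FALSE)
  }
  if (length(temperature_C) < 20L) {
    stop("a melting curve needs at least 20 points", call. = FALSE)
  }
  if (any(!is.finite(temperature_C)) || any(diff(temperature_C) <= 0)) {
    stop("'temperature_C' must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(signal))) stop("'signal' must be finite", call. = FALSE)
  if (!is.numeric(Ct) || length(Ct) != 1L || !is.finite(Ct) || Ct <= 0) {
    stop("'Ct' must be a positive molarity", call. = FALSE)
  }
  out <- data.frame(temperature_C = temperature_C, signal = signal)
  attr(out, "Ct") <- Ct
  attr(out, "meta") <- list(pH = pH, wavelength_nm = wavelength_nm,
                            buffer = buffer, heating_rate = heating_rate)
  class(out) <- c("melting_curve", "data.frame")
  out
}

baseline_eval <- function(coefs, temperature_C) {
  coefs[["intercept"]] + coefs[["slope"]] * temperature_C
}

new_baseline_pair <- function(folded, unfolded, low_window, high_window,
                              low_confidence, min_gap) {
  t_mid <- (low_window[2] + high_window[1]) / 2
  gap <- baseline_eval(folded, t_mid) - baseline_eval(unfolded, t_mid)
  structure(
    list(folded = folded, unfolded = unfolded,
         low_window = low_window, high_window = high_window,
         gap_at_midpoint = gap, low_confidence = low_confidence,
         min_gap = min_gap),
    class = "baseline_pair"
  )
}

#' Fit linear folded/unfolded baselines
#'
#' Least-squares lines through the low-temperature (folded) and
#' high-temperature (unfolded) plateaus of a melting curve. The sloping
#' linear baselines absorb the intrinsic temperature dependence of the
#' signal of each species, so the later fraction conversion is invariant
#' to any affine rescaling of the raw signal.
#'
#' @param curve A [melting_curve()].
#' @param low_window,high_window Temperature ranges `c(lo, hi)` in degrees
#'   Celsius over which to fit the folded and unfolded lines. Default:
#'   the first and last 15 percent of the temperature span.
#' @param min_gap Minimum separation (signal units) required between the
#'   two lines at the midpoint between the windows; below it the curve has
#'   no resolvable transition.
#' @return A `baseline_pair`: lists `folded` and `unfolded` each with
#'   `intercept` and `slope`, the windows used, the signal gap at the
#'   inter-window midpoint, and a `low_confidence` flag raised when either
#'   window holds only the minimal 4 points.
#' @export
fit_baselines <- function(curve, low_window = NULL, high_window = NULL,
                          min_gap = 0.5) {
  stopifnot(inherits(curve, "melting_curve"))
  tc <- curve$temperature_C
  span <- range(tc)
  if (is.null(low_window)) low_window <- c(span[1], span[1] + 0.15 * diff(span))
  if (is.null(high_window)) high_window <- c(span[2] - 0.15 * diff(span), span[2])
  for (w in list(low = low_window, high = high_window)) {
    if (length(w) != 2L || w[1] >= w[2]) {
      stop("baseline windows must be c(lo, hi) with lo < hi", call. = FALSE)
    }
  }
  if (low_window[2] >= high_window[1]) {
    stop("baseline windows must not overlap", call. = FALSE)
  }
  in_low <- tc >= low_window[1] & tc <= low_window[2]
  in_high <- tc >= high_window[1] & tc <= high_window[2]
  if (sum(in_low) < 4L) {
    stop(sprintf("low baseline window [%g, %g] C covers %d points (>= 4 required)",
                 low_window[1], low_window[2], sum(in_low)), call. = FALSE)
  }
  if (sum(in_high) < 4L) {
    stop(sprintf("high baseline window [%g, %g] C covers %d points (>= 4 required)",
                 high_window[1], high_window[2], sum(in_high)), call. = FALSE)
  }
  cf <- stats::coef(stats::lm(signal ~ temperature_C, data = curve,
                              subset = in_low))
  cu <- stats::coef(stats::lm(signal ~ temperature_C, data = curve,
                              subset = in_high))
  bl <- new_baseline_pair(
    folded = c(intercept = unname(cf[1]), slope = unname(cf[2])),
    unfolded = c(intercept = unname(cu[1]), slope = unname(cu[2])),
    low_window = low_window, high_window = high_window,
    low_confidence = (sum(in_low) == 4L || sum(in_high) == 4L),
    min_gap = min_gap
  )
  if (abs(bl$gap_at_midpoint) < min_gap) {
    stop("no resolvable transition: folded and unfolded baselines are not separated",
         call. = FALSE)
  }
  bl
}

#' @export
print.baseline_pair <- function(x, ...) {
  cat(sprintf(
    "Baselines (signal = intercept + slope * T_C):\n  folded:   %.6g + %.6g * T  (window %g-%g C)\n  unfolded: %.6g + %.6g * T  (window %g-%g C)\n  gap at midpoint: %.4g%s\n",
    x$folded[["intercept"]], x$folded[["slope"]],
    x$low_window[1], x$low_window[2],
    x$unfolded[["intercept"]], x$unfolded[["slope"]],
    x$high_window[1], x$high_window[2],
    x$gap_at_midpoint,
    if (isTRUE(x$low_confidence)) "  [low confidence: minimal window]" else ""
  ))
  invisible(x)
}

#' Convert a melting curve to fraction of structured strands
#'
#' alpha(T) = (s(T) - u(T)) / (f(T) - u(T)), where f and u are the folded
#' and unfolded baseline values. Values outside \[0, 1\] (noise in the
#' plateaus) are clipped; the pre-clip values are kept in `alpha_raw` and
#' clipped points are flagged.
#'
#' @param curve A [melting_curve()].
#' @param baselines A `baseline_pair` from [fit_baselines()].
#' @return A data frame of class `fraction_curve` with columns
#'   `temperature_C`, `alpha`, `alpha_raw`, `clipped`; attribute `Ct`.
#' @export
signal_to_fraction <- function(curve, baselines) {
  stopifnot(inherits(curve, "melting_curve"), inherits(baselines, "baseline_pair"))
  tc <- curve$temperature_C
  f <- baseline_eval(baselines$folded, tc)
  u <- baseline_eval(baselines$unfolded, tc)
  transition <- tc > baselines$low_window[2] & tc < baselines$high_window[1]
  if (any(abs(f - u)[transition] < baselines$min_gap)) {
    stop("baselines converge below the minimum signal gap inside the transition region",
         call. = FALSE)
  }
  alpha_raw <- (curve$signal - u) / (f - u)
  alpha <- pmin(1, pmax(0, alpha_raw))
  out <- data.frame(temperature_C = tc, alpha = alpha, alpha_raw = alpha_raw,
                    clipped = alpha != alpha_raw)
  attr(out, "Ct") <- attr(curve, "Ct")
  attr(out, "baselines") <- baselines
  class(out) <- c("fraction_curve", "data.frame")
  out
}

#' Per-temperature equilibrium constants from a fraction curve
#'
#' Inverts the mass balance at each retained point. For the homodimer,
#' lnK = ln(alpha / (2 * Ct * (1 - alpha)^2)); for molecularity 1,
#' lnK = ln(alpha / (1 - alpha)). Only points with alpha strictly inside
#' `alpha_window` contribute: lnK diverges at the plateaus, so points
#' there carry no usable information and amplify baseline error.
#'
#' @param frac A `fraction_curve` from [signal_to_fraction()].
#' @param molecularity 1 or 2.
#' @param alpha_window `c(lo, hi)` with 0 < lo < hi < 1; default
#'   `c(0.15, 0.85)`.
#' @return A data frame of class `vant_hoff_points` with columns `inv_T`
#'   (1/kelvin), `lnK`, `temperature_C`, `alpha`; attributes `n_points`,
#'   `alpha_window`, `molecularity`, `Ct`.
#' @export
fraction_to_lnK <- function(frac, molecularity = 2,
                            alpha_window = c(0.15, 0.85)) {
  stopifnot(inherits(frac, "fraction_curve"))
  molecularity <- check_molecularity(molecularity)
  if (!(length(alpha_window) == 2L && alpha_window[1] > 0 &&
        alpha_window[2] < 1 && alpha_window[1] < alpha_window[2])) {
    stop("'alpha_window' must be c(lo, hi) with 0 < lo < hi < 1", call. = FALSE)
  }
  keep <- !frac$clipped & frac$alpha > alpha_window[1] &
    frac$alpha < alpha_window[2]
  if (sum(keep) < 5L) {
    stop("insufficient transition sampling: fewer than 5 points inside the alpha window",
         call. = FALSE)
  }
  a <- frac$alpha[keep]
  Ct <- attr(frac, "Ct")
  lnK <- if (molecularity == 2L) {
    log(a / (2 * Ct * (1 - a)^2))
  } else {
    log(a / (1 - a))
  }
  out <- data.frame(inv_T = 1 / C_to_K(frac$temperature_C[keep]), lnK = lnK,
                    temperature_C = frac$temperature_C[keep], alpha = a)
  attr(out, "n_points") <- sum(keep)
  attr(out, "alpha_window") <- alpha_window
  attr(out, "molecularity") <- molecularity
  attr(out, "Ct") <- Ct
  class(out) <- c("vant_hoff_points", "data.frame")
  out
}

#' Van't Hoff regression of lnK on 1/T
#'
#' Ordinary least squares of lnK against 1/T: the slope is -dH/R and the
#' intercept dS/R under the temperature-independent dH, dS assumption.
#' Standard errors and the slope/intercept covariance are mapped onto
#' (dH, dS) so that every derived quantity can be propagated with the full
#' covariance.
#'
#' @param points A `vant_hoff_points` data frame (or any data frame with
#'   columns `inv_T` and `lnK`).
#' @return A `thermo_estimate`: `params` ([thermo_params()]), `se_dH`,
#'   `se_dS`, `cov_dH_dS`, `r_squared`, `n`, residual degrees of freedom
#'   and an `se_undefined` flag (raised for a two-point interpolating fit,
#'   whose SEs are reported as 0).
#' @export
vant_hoff_fit <- function(points) {
  stopifnot(is.data.frame(points), all(c("inv_T", "lnK") %in% names(points)))
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points for a van't Hoff fit", call. = FALSE)
  if (stats::sd(points$inv_T) == 0) {
    stop("singular design: all temperatures are equal", call. = FALSE)
  }
  fit <- stats::lm(lnK ~ inv_T, data = points)
  b <- stats::coef(fit)
  dH <- -b[[2]] * R_GAS
  dS <- b[[1]] * R_GAS
  se_undefined <- n == 2L
  if (se_undefined) {
    V <- matrix(0, 2, 2)
    r2 <- 1
  } else {
    V <- stats::vcov(fit)
    r2 <- summary(fit)$r.squared
  }
  structure(
    list(params = thermo_params(dH, dS = dS),
         se_dH = R_GAS * sqrt(V[2, 2]),
         se_dS = R_GAS * sqrt(V[1, 1]),
         cov_dH_dS = -R_GAS^2 * V[1, 2],
         r_squared = r2,
         n = n,
         df_residual = n - 2L,
         se_undefined = se_undefined,
         molecularity = attr(points, "molecularity"),
         Ct = attr(points, "Ct")),
    class = "thermo_estimate"
  )
}

#' Propagate fit uncertainty onto derived quantities
#'
#' Adds dG(T_ref), Tm(Ct) and T_ref*dS, each with a first-order (delta
#' method) standard error using the full (dH, dS) covariance of the
#' regression -- no independence assumption is made, and the call refuses
#' to proceed without a covariance:
#' \itemize{
#'   \item var(dG) = var(dH) + T^2 var(dS) - 2 T cov(dH, dS)
#'   \item Tm = dH / (dS + R ln Ct) (molecularity 2) or dH / dS, with
#'     gradient (1/D, -dH/D^2) in (dH, dS), D the denominator.
#' }
#' Central values are computed through [melting_temperature()] and
#' [free_energy()], so they agree with the model layer exactly.
#'
#' @param est A `thermo_estimate` from [vant_hoff_fit()].
#' @param Ct Total strand concentration, mol/L (molecularity 2).
#' @param T_ref Reference temperature, kelvin.
#' @param molecularity 1 or 2; defaults to the value carried by `est`.
#' @return `est` augmented with a `derived` list: `dG`, `se_dG`, `Tm_C`,
#'   `se_Tm`, `TdS`, `se_TdS`, `T_ref`, `Ct`.
#' @export
derived_with_errors <- function(est, Ct = est$Ct, T_ref = 298.15,
                                molecularity = NULL) {
  stopifnot(inherits(est, "thermo_estimate"))
  if (is.null(molecularity)) molecularity <- est$molecularity %||% 2L
  molecularity <- check_molecularity(molecularity)
  if (is.null(est$cov_dH_dS) || is.na(est$cov_dH_dS)) {
    stop("estimate carries no (dH, dS) covariance; refusing to propagate errors under an independence assumption",
         call. = FALSE)
  }
  p <- est$params
  dG <- free_energy(p, T_ref)
  var_dG <- est$se_dH^2 + T_ref^2 * est$se_dS^2 - 2 * T_ref * est$cov_dH_dS
  Tm_C <- melting_temperature(p, Ct = Ct, molecularity = molecularity)
  D <- if (molecularity == 2L) p$dS + R_GAS * log(Ct) else p$dS
  g <- c(1 / D, -p$dH / D^2) # dTm/d(dH), dTm/d(dS)
  var_Tm <- g[1]^2 * est$se_dH^2 + g[2]^2 * est$se_dS^2 +
    2 * g[1] * g[2] * est$cov_dH_dS
  est$derived <- list(
    T_ref = T_ref, Ct = Ct,
    dG = dG, se_dG = sqrt(max(var_dG, 0)),
    Tm_C = Tm_C, se_Tm = sqrt(max(var_Tm, 0)),
    TdS = TdS(p, T_ref), se_TdS = T_ref * est$se_dS
  )
  est
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.thermo_estimate <- function(x, ...) {
  p <- x$params
  cat("Two-state van't Hoff fit\n")
  cat(sprintf("  n = %d points, r^2 = %.7g\n", x$n, x$r_squared))
  cat(sprintf("  dH      = %8.2f +/- %.2f kcal/mol\n", p$dH, x$se_dH))
  if (!is.null(x$derived)) {
    d <- x$derived
    cat(sprintf("  T.dS%.0f  = %8.2f +/- %.2f kcal/mol\n",
                d$T_ref, d$TdS, d$se_TdS))
    cat(sprintf("  dG%.0f    = %8.2f +/- %.2f kcal/mol\n",
                d$T_ref, d$dG, d$se_dG))
    cat(sprintf("  Tm      = %8.1f +/- %.1f C at Ct = %.3g M\n",
                d$Tm_C, d$se_Tm, d$Ct))
  }
  if (isTRUE(x$se_undefined)) {
    cat("  (two-point interpolation: standard errors undefined, reported as 0)\n")
  }
  invisible(x)
}

#' Model-free melting temperature from a fraction curve
#'
#' The temperature at which the measured alpha crosses 0.5, by linear
#' interpolation between the bracketing points (alpha decreasing with
#' temperature). Complements the model Tm from [melting_temperature()].
#'
#' @param frac A `fraction_curve`.
#' @return Tm in degrees Celsius, or NA (with a warning) if alpha never
#'   crosses 0.5 within the curve.
#' @export
tm_observed <- function(frac) {
  stopifnot(inherits(frac, "fraction_curve"))
  a <- frac$alpha
  tc <- frac$temperature_C
  i <- which(a[-length(a)] >= 0.5 & a[-1] < 0.5)
  if (length(i) == 0L) {
    warning("fraction curve never crosses alpha = 0.5; no observed Tm")
    return(NA_real_)
  }
  i <- i[1]
  tc[i] + (0.5 - a[i]) * (tc[i + 1] - tc[i]) / (a[i + 1] - a[i])
}

#' Fit a melting curve end to end
#'
#' Full pipeline: baseline fit, fraction conversion, per-temperature lnK,
#' van't Hoff regression, and error propagation. By default the baselines
#' are refined iteratively: after each van't Hoff fit the model fraction
#' alpha(T) is used to correct the plateau signals for the residual
#' population of the other species ((1 - alpha) under the folded window,
#' alpha under the unfolded window) before refitting the lines over the
#' same windows. The folded plateau of a homodimer is never exactly pure
#' -- alpha < 1 at any finite concentration -- and this occupancy
#' correction removes the resulting baseline bias; on noiseless data the
#' iteration converges to the generating parameters. Set `refine = FALSE`
#' for the plain one-pass analysis.
#'
#' @param curve A [melting_curve()].
#' @param molecularity 1 or 2.
#' @param alpha_window Passed to [fraction_to_lnK()].
#' @param low_window,high_window,min_gap Passed to [fit_baselines()].
#' @param refine Iterate the occupancy-corrected baseline refit (default
#'   TRUE).
#' @param max_iter,tol Iteration cap and relative parameter-change
#'   convergence tolerance.
#' @param T_ref Reference temperature (kelvin) for derived quantities.
#' @return A `thermo_estimate` (see [vant_hoff_fit()],
#'   [derived_with_errors()]) additionally carrying `baselines`,
#'   `fraction`, `points`, `tm_observed_C` and `iterations`.
#' @export
fit_melting <- function(curve, molecularity = 2, alpha_window = c(0.15, 0.85),
                        low_window = NULL, high_window = NULL,
                        refine = TRUE, max_iter = 50L, tol = 1e-10,
                        min_gap = 0.5, T_ref = 298.15) {
  stopifnot(inherits(curve, "melting_curve"))
  molecularity <- check_molecularity(molecularity)
  bl <- fit_baselines(curve, low_window, high_window, min_gap)
  tc <- curve$temperature_C
  TK <- C_to_K(tc)
  Ct <- attr(curve, "Ct")
  in_low <- tc >= bl$low_window[1] & tc <= bl$low_window[2]
  in_high <- tc >= bl$high_window[1] & tc <= bl$high_window[2]
  prev <- c(NA_real_, NA_real_)
  iterations <- 0L
  repeat {
    frac <- signal_to_fraction(curve, bl)
    vhp <- fraction_to_lnK(frac, molecularity, alpha_window)
    est <- vant_hoff_fit(vhp)
    p <- est$params
    iterations <- iterations + 1L
    if (!refine || iterations >= max_iter) break
    if (all(is.finite(prev)) &&
        max(abs(c(p$dH, p$dS) - prev) / pmax(abs(prev), 1e-12)) < tol) break
    prev <- c(p$dH, p$dS)
    am <- equilibrium_fraction(p, TK, Ct = Ct, molecularity = molecularity)
    fh <- baseline_eval(bl$folded, tc)
    uh <- baseline_eval(bl$unfolded, tc)
    # occupancy-corrected plateau signals, refit over the same windows
    a_lo <- pmax(am[in_low], 1e-6)
    a_hi <- pmin(am[in_high], 1 - 1e-6)
    s_f <- (curve$signal[in_low] - (1 - a_lo) * uh[in_low]) / a_lo
    s_u <- (curve$signal[in_high] - a_hi * fh[in_high]) / (1 - a_hi)
    cf <- stats::coef(stats::lm(s_f ~ tc[in_low]))
    cu <- stats::coef(stats::lm(s_u ~ tc[in_high]))
    bl <- new_baseline_pair(
      folded = c(intercept = unname(cf[1]), slope = unname(cf[2])),
      unfolded = c(intercept = unname(cu[1]), slope = unname(cu[2])),
      low_window = bl$low_window, high_window = bl$high_window,
      low_confidence = bl$low_confidence, min_gap = bl$min_gap
    )
  }
  est <- derived_with_errors(est, Ct = Ct, T_ref = T_ref,
                             molecularity = molecularity)
  est$baselines <- bl
  est$fraction <- frac
  est$points <- vhp
  est$tm_observed_C <- tm_observed(frac)
  est$iterations <- iterations
  est
}

#' Enthalpy and entropy from the concentration dependence of Tm
#'
#' For a homodimer, 1/Tm (in kelvin) is linear in ln Ct:
#' 1/Tm = dS/dH + (R/dH) * ln Ct. An ordinary least-squares line through
#' (ln Ct, 1/Tm) therefore yields dH = R / slope and dS = intercept * dH,
#' a second, independent route to the transition thermodynamics. With two
#' concentrations the line interpolates exactly. A series whose Tm does
#' not move with concentration is flagged as unimolecular instead of
#' being forced through the dimer formula.
#'
#' @param series Data frame with columns `Ct` (mol/L) and `Tm_C` (degrees
#'   Celsius); at least two distinct concentrations.
#' @return A `tm_conc_fit`: `params` ([thermo_params()], NULL when
#'   unimolecular), `slope`, `intercept`, `se_dH`, `r_squared`,
#'   `unimolecular` flag and `n`.
#' @export
fit_tm_vs_concentration <- function(series) {
  stopifnot(is.data.frame(series), all(c("Ct", "Tm_C") %in% names(series)))
  if (any(series$Ct <= 0)) stop("'Ct' must be positive", call. = FALSE)
  n <- nrow(series)
  if (n < 2L || length(unique(series$Ct)) < 2L) {
    stop("singular fit: need at least 2 distinct concentrations", call. = FALSE)
  }
  Tm_K <- C_to_K(series$Tm_C)
  x <- log(series$Ct)
  y <- 1 / Tm_K
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)
  slope <- b[[2]]
  intercept <- b[[1]]
  if (diff(range(Tm_K)) < 1e-3) {
    return(structure(
      list(params = NULL, slope = slope, intercept = intercept,
           se_dH = NA_real_, r_squared = NA_real_, unimolecular = TRUE,
           note = "no concentration dependence: unimolecular", n = n),
      class = "tm_conc_fit"
    ))
  }
  dH <- R_GAS / slope
  dS <- intercept * dH
  # direct formulas rather than summary.lm(), which warns on the exact
  # (zero-residual) fits that noiseless or two-point series produce
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  se_slope <- if (n > 2L) sqrt(rss / (n - 2) / sum((x - mean(x))^2)) else 0
  structure(
    list(params = thermo_params(dH, dS = dS), slope = slope,
         intercept = intercept,
         se_dH = abs(R_GAS / slope^2) * se_slope,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         unimolecular = FALSE, n = n),
    class = "tm_conc_fit"
  )
}

#' @export
print.tm_conc_fit <- function(x, ...) {
  cat("Tm-vs-concentration analysis (1/Tm vs ln Ct)\n")
  if (isTRUE(x$unimolecular)) {
    cat("  ", x$note, "\n", sep = "")
  } else {
    cat(sprintf("  dH = %.2f +/- %.2f kcal/mol (n = %d, r^2 = %.6g)\n",
                x$params$dH, x$se_dH, x$n, x$r_squared))
    cat(sprintf("  T.dS298 = %.2f kcal/mol\n", TdS(x$params, 298.15)))
  }
  invisible(x)
}
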