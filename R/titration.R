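# pH-titration analysis: Hill sigmoid fit of the acid-driven
# folding/unfolding transition; the midpoint is the structure's apparent
# pKa.

#' Construct a pH-titration curve
#'
#' Signal (CD ellipticity at a fixed wavelength) recorded as the pH of a
#' sample is raised, e.g. by stepwise NaOH addition to an acetate-buffered
#' sample. For an acid-stabilized structure the signal decays from a
#' structured plateau at low pH to an unstructured plateau at high pH.
#'
#' @param pH Strictly increasing pH series, at least 8 points.
#' @param signal Spectroscopic signal at each pH.
#' @param temperature_C,buffer Optional metadata.
#' @return A data frame of class `titration_curve` with columns `pH`,
#'   `signal` and a `meta` attribute.
#' @export
titration_curve <- function(pH, signal, temperature_C = NA_real_,
                            buffer = NA_character_) {
  pH <- as.numeric(pH)
  signal <- as.numeric(signal)
  if (length(pH) != length(signal)) {
    stop("'pH' and 'signal' must have the same length", call. = FALSE)
  }
  if (length(pH) < 8L) {
    stop("a titration curve needs at least 8 points", call. = FALSE)
  }
  if (any(!is.finite(pH)) || any(diff(pH) <= 0)) {
    stop("'pH' must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(signal))) stop("'signal' must be finite", call. = FALSE)
  out <- data.frame(pH = pH, signal = signal)
  attr(out, "meta") <- list(temperature_C = temperature_C, buffer = buffer)
  class(out) <- c("titration_curve", "data.frame")
  out
}

# Hill occupancy: fraction structured at a given pH
hill_theta <- function(pH, pKa_app, hill) {
  1 / (1 + 10^(hill * (pH - pKa_app)))
}

#' Fit a pH titration to a Hill sigmoid
#'
#' Nonlinear least squares of
#' `s(pH) = plateau_high + (plateau_low - plateau_high) * theta(pH)` with
#' `theta(pH) = 1 / (1 + 10^(hill * (pH - pKa_app)))`. `theta` is the
#' fraction of structured species, equal to 1/2 at `pH = pKa_app`: the
#' fitted midpoint is the apparent pKa of the structure as a whole (an
#' aggregate of the underlying cytosine protonation equilibria, not a
#' microscopic residue pKa). `plateau_low` is the signal of the fully
#' structured (low-pH) limit and `plateau_high` that of the unstructured
#' limit.
#'
#' @param curve A [titration_curve()].
#' @param fix_hill Optional number: fix the Hill coefficient instead of
#'   fitting it.
#' @return A `titration_fit`: `pKa_app`, `hill`, `plateau_low`,
#'   `plateau_high`, their standard errors (`se_*`; `se_hill` is 0 when
#'   fixed), `hill_fixed`, residual standard deviation `sigma`,
#'   `extrapolated` flag (midpoint outside the sampled pH range), and the
#'   underlying `nls` fit.
#' @export
fit_titration <- function(curve, fix_hill = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  s <- curve$signal
  pH <- curve$pH
  amp <- diff(range(s))
  if (amp <= 1e-10 * max(1, abs(mean(s)))) {
    stop("no transition detected: signal is flat across the pH range",
         call. = FALSE)
  }
  k <- min(3L, length(s))
  p_low0 <- mean(utils::head(s, k))
  p_high0 <- mean(utils::tail(s, k))
  s_mid <- (p_low0 + p_high0) / 2
  pKa0 <- pH[which.min(abs(s - s_mid))]
  dat <- data.frame(pH = pH, s = s)
  fit <- tryCatch({
    if (is.null(fix_hill)) {
      minpack.lm::nlsLM(
        s ~ p_high + (p_low - p_high) / (1 + 10^(hill * (pH - pKa))),
        data = dat,
        start = list(p_low = p_low0, p_high = p_high0, pKa = pKa0, hill = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      stopifnot(is.numeric(fix_hill), length(fix_hill) == 1L, fix_hill != 0)
      minpack.lm::nlsLM(
        s ~ p_high + (p_low - p_high) / (1 + 10^(fix_hill * (pH - pKa))),
        data = dat,
        start = list(p_low = p_low0, p_high = p_high0, pKa = pKa0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    }
  }, error = function(e) {
    stop(sprintf(
      "titration fit did not converge: %s (signal range %.4g, starting midpoint %.2f)",
      conditionMessage(e), amp, pKa0), call. = FALSE)
  })
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  hill <- if (is.null(fix_hill)) cf[["hill"]] else fix_hill
  se_hill <- if (is.null(fix_hill)) se[["hill"]] else 0
  if (abs(cf[["p_low"]] - cf[["p_high"]]) <= 1e-10 * max(1, abs(mean(s)))) {
    stop("no transition detected: fitted plateaus coincide", call. = FALSE)
  }
  structure(
    list(pKa_app = cf[["pKa"]], hill = hill,
         plateau_low = cf[["p_low"]], plateau_high = cf[["p_high"]],
         se_pKa = se[["pKa"]], se_hill = se_hill,
         se_plateau_low = se[["p_low"]], se_plateau_high = se[["p_high"]],
         hill_fixed = !is.null(fix_hill),
         sigma = summary(fit)$sigma,
         extrapolated = cf[["pKa"]] < min(pH) || cf[["pKa"]] > max(pH),
         fit = fit),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("pH-titration fit (Hill sigmoid)\n")
  cat(sprintf("  apparent pKa = %.3f +/- %.3f%s\n", x$pKa_app, x$se_pKa,
              if (x$extrapolated) "  [extrapolated beyond sampled range]" else ""))
  cat(sprintf("  Hill coefficient = %.3f +/- %.3f%s\n", x$hill, x$se_hill,
              if (x$hill_fixed) "  (fixed)" else ""))
  cat(sprintf("  plateaus: structured %.4g, unstructured %.4g (residual sd %.3g)\n",
              x$plateau_low, x$plateau_high, x$sigma))
  invisible(x)
}

#' Normalize a titration curve to fraction structured
#'
#' theta = (s - plateau_high) / (plateau_low - plateau_high) using the
#' fitted plateaus; clipped to \[0, 1\] with pre-clip values retained.
#'
#' @param curve A [titration_curve()].
#' @param fit A `titration_fit` from [fit_titration()].
#' @return A data frame with columns `pH`, `theta`, `theta_raw`,
#'   `clipped`.
#' @export
normalize_titration <- function(curve, fit) {
  stopifnot(inherits(curve, "titration_curve"), inherits(fit, "titration_fit"))
  den <- fit$plateau_low - fit$plateau_high
  if (abs(den) <= 1e-10 * max(1, abs(fit$plateau_low))) {
    stop("degenerate plateaus: cannot normalize", call. = FALSE)
  }
  theta_raw <- (curve$signal - fit$plateau_high) / den
  theta <- pmin(1, pmax(0, theta_raw))
  data.frame(pH = curve$pH, theta = theta, theta_raw = theta_raw,
             clipped = theta != theta_raw)
}
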