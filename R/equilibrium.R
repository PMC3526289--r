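# Closed-form two-state equilibrium model: unimolecular folding (2-state
# hairpin/dumbbell) and homodimerization 2M <=> D, the model used for
# dimeric quadruplex/i-motif melting.

#' Gas constant in kcal units
#'
#' `R_GAS` is the molar gas constant, 1.9872e-3 kcal mol^-1 K^-1. All
#' energies in this package are kcal mol^-1 and all internal temperatures
#' kelvin, so this is the only physical constant the model needs.
#'
#' @format A length-one numeric.
#' @export
R_GAS <- 1.9872e-3

# degrees Celsius <-> kelvin; all user-facing temperatures are Celsius,
# everything internal is kelvin
C_to_K <- function(x) x + 273.15
K_to_C <- function(x) x - 273.15

#' Van't Hoff parameters of a two-state transition
#'
#' Bundles the standard enthalpy and entropy change of folding/association.
#' For the acid-stabilized dimers this package was written around, both are
#' negative (association is enthalpy-driven and entropically opposed).
#' The entropy can be given either directly (`dS`, kcal mol^-1 K^-1) or as
#' the more commonly tabulated product T*dS at a reference temperature
#' (`TdS298`, kcal mol^-1).
#'
#' @param dH Enthalpy change, kcal mol^-1.
#' @param dS Entropy change, kcal mol^-1 K^-1. Supply exactly one of `dS`
#'   and `TdS298`.
#' @param TdS298 Entropy term T*dS evaluated at `T_ref`, kcal mol^-1.
#' @param T_ref Reference temperature in kelvin used to interpret
#'   `TdS298`; default 298.15 K (25 degrees C).
#' @return An object of class `thermo_params` with fields `dH`, `dS` and
#'   `T_ref`.
#' @seealso [TdS()], [vant_hoff_lnK()], [melting_temperature()],
#'   [free_energy()]
#' @examples
#' p <- thermo_params(dH = -38.1, TdS298 = -30.2)
#' free_energy(p)          # -7.9 kcal/mol at 298.15 K
#' melting_temperature(p, Ct = 50e-6)
#' @export
thermo_params <- function(dH, dS = NULL, TdS298 = NULL, T_ref = 298.15) {
  if (is.null(dS) == is.null(TdS298)) {
    stop("supply exactly one of 'dS' or 'TdS298'", call. = FALSE)
  }
  if (is.null(dS)) dS <- TdS298 / T_ref
  if (!is.numeric(dH) || length(dH) != 1L || !is.finite(dH)) {
    stop("'dH' must be a single finite number (kcal/mol)", call. = FALSE)
  }
  if (!is.numeric(dS) || length(dS) != 1L || !is.finite(dS)) {
    stop("'dS' must be a single finite number (kcal/mol/K)", call. = FALSE)
  }
  structure(list(dH = dH, dS = dS, T_ref = T_ref), class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "Two-state van't Hoff parameters:\n  dH  = %.4g kcal/mol\n  dS  = %.4g kcal/mol/K  (T.dS at %.2f K = %.4g kcal/mol)\n",
    x$dH, x$dS, x$T_ref, TdS(x)
  ))
  invisible(x)
}

#' Entropy term T*dS at a reference temperature
#'
#' Accessor reporting the product T_ref * dS in kcal mol^-1, the form in
#' which transition entropies are usually tabulated alongside dH and dG.
#'
#' @param params A [thermo_params()] object.
#' @param T_ref Temperature in kelvin; defaults to the object's own
#'   reference temperature.
#' @return T_ref * dS in kcal mol^-1.
#' @export
TdS <- function(params, T_ref = params$T_ref) {
  stopifnot(inherits(params, "thermo_params"), T_ref > 0)
  T_ref * params$dS
}

check_molecularity <- function(molecularity) {
  if (!(length(molecularity) == 1L && molecularity %in% c(1, 2))) {
    stop("'molecularity' must be 1 (unimolecular) or 2 (homodimer)",
         call. = FALSE)
  }
  as.integer(molecularity)
}

#' Van't Hoff equilibrium constant (natural log)
#'
#' Evaluates lnK(T) = dS/R - (dH/R) * 1/T, the integrated van't Hoff
#' expression with temperature-independent dH and dS. For a
#' homodimerization K carries units of M^-1 (the standard state is 1 M),
#' so lnK is reported as a plain number.
#'
#' @param params A [thermo_params()] object.
#' @param T_K Temperature(s) in kelvin; must be positive.
#' @return lnK, same length as `T_K`.
#' @export
vant_hoff_lnK <- function(params, T_K) {
  stopifnot(inherits(params, "thermo_params"))
  if (!is.numeric(T_K) || any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  params$dS / R_GAS - (params$dH / R_GAS) / T_K
}

#' Equilibrium fraction of structured strands
#'
#' Molar fraction alpha of strands engaged in the structured species at
#' temperature `T_K`. For a homodimer 2M <=> D with total strand
#' concentration Ct (so \[D\] = alpha*Ct/2 and \[M\] = (1-alpha)*Ct), alpha
#' is the unique root in \[0, 1\] of the mass balance
#' K = alpha / (2 * Ct * (1 - alpha)^2). For a unimolecular transition,
#' alpha = K / (1 + K) and Ct is ignored.
#'
#' The dimer root is evaluated in the cancellation-free form
#' alpha = 4q / (4q + 1 + sqrt(8q + 1)) with q = K * Ct, which is accurate
#' from q -> 0 through q -> Inf.
#'
#' @param params A [thermo_params()] object.
#' @param T_K Temperature(s), kelvin.
#' @param Ct Total strand concentration, mol/L. Required (and positive)
#'   when `molecularity = 2`.
#' @param molecularity 1 or 2.
#' @return alpha in \[0, 1\], same length as `T_K`.
#' @export
equilibrium_fraction <- function(params, T_K, Ct = NULL, molecularity = 2) {
  molecularity <- check_molecularity(molecularity)
  lnK <- vant_hoff_lnK(params, T_K)
  if (molecularity == 1L) {
    return(stats::plogis(lnK))
  }
  if (is.null(Ct) || !is.numeric(Ct) || length(Ct) != 1L || !is.finite(Ct) ||
      Ct <= 0) {
    stop("total strand concentration 'Ct' must be a positive molarity for a bimolecular transition",
         call. = FALSE)
  }
  lnq <- lnK + log(Ct)
  q <- exp(lnq)
  alpha <- ifelse(is.finite(q), 4 * q / (4 * q + 1 + sqrt(8 * q + 1)), NA_real_)
  big <- !is.finite(q)
  if (any(big)) {
    # q overflowed: alpha -> 1 - 1/sqrt(2q), itself indistinguishable from 1
    alpha[big] <- 1 - exp(-0.5 * (lnq[big] + log(2)))
  }
  alpha
}

#' Melting temperature of a two-state transition
#'
#' Temperature at which half the strands are structured. For the
#' homodimer, alpha(Tm) = 1/2 is equivalent to K(Tm) * Ct = 1, giving the
#' closed form Tm = dH / (dS + R * ln Ct); the concentration dependence of
#' Tm is the classic signature of a multimolecular transition. For
#' molecularity 1, Tm = dH / dS independent of concentration.
#'
#' @inheritParams equilibrium_fraction
#' @param Ct Total strand concentration, mol/L (molecularity 2 only).
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(params, Ct = NULL, molecularity = 2) {
  molecularity <- check_molecularity(molecularity)
  stopifnot(inherits(params, "thermo_params"))
  if (params$dH == 0) {
    stop("dH must be non-zero to define a melting temperature", call. = FALSE)
  }
  if (molecularity == 2L) {
    if (is.null(Ct) || !is.numeric(Ct) || length(Ct) != 1L || Ct <= 0) {
      stop("'Ct' must be a positive molarity for molecularity 2", call. = FALSE)
    }
    den <- params$dS + R_GAS * log(Ct)
  } else {
    den <- params$dS
  }
  if (den == 0) {
    stop("transition outside physical range (no finite Tm)", call. = FALSE)
  }
  Tm_K <- params$dH / den
  if (!is.finite(Tm_K) || Tm_K <= 0 || Tm_K > 500) {
    stop("transition outside physical range (Tm not in (0, 500] K)",
         call. = FALSE)
  }
  K_to_C(Tm_K)
}

#' Standard free energy change at a reference temperature
#'
#' dG(T_ref) = dH - T_ref * dS, kcal mol^-1. Equals -R * T_ref * lnK(T_ref)
#' by construction.
#'
#' @param params A [thermo_params()] object.
#' @param T_ref Temperature in kelvin, default 298.15.
#' @return dG in kcal mol^-1.
#' @export
free_energy <- function(params, T_ref = 298.15) {
  stopifnot(inherits(params, "thermo_params"))
  if (!is.numeric(T_ref) || any(T_ref <= 0)) {
    stop("'T_ref' must be positive (kelvin)", call. = FALSE)
  }
  params$dH - T_ref * params$dS
}
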