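# Synthetic melting and titration curves: the generator is the exact
# mirror of the analysis (two-state homodimer fractions, linear sloping
# baselines, additive Gaussian noise) and stands in for CD data that are
# published only as figures.

#' Reference dimerization thermodynamics for three mini i-motif sequences
#'
#' Published van't Hoff parameters (pH 4.5, sodium acetate buffer) for
#' the dimerization of three oligonucleotides that fold into minimal
#' i-motif quadruplexes capped by minor-groove G:T:G:T tetrads: the
#' cyclic decamer d<pTCGTTTCGTT>, its linear analog d(TCGTTTCGT) and the
#' shorter octamer d(TCGTTCGT). These parameter sets drive the package's
#' canonical fixtures and worked examples. `Ct` is the total strand
#' concentration of the reported melting experiment; `Tm_C` and `dG298`
#' are the reported melting temperature and free energy, reproducible
#' from `dH`/`TdS298` through [melting_temperature()] and
#' [free_energy()]. The octamer entry was measured in Mg-containing
#' buffer at higher strand concentration and its parameters are apparent
#' values; the linear nonamer populates two co-existing dimers, so its
#' two-state parameters are likewise apparent.
#'
#' @return A data frame with one row per sequence: `label`, `sequence`,
#'   `dH`, `TdS298` (kcal/mol), `Ct` (mol/L), `Tm_C` (degrees Celsius),
#'   `dG298` (kcal/mol).
#' @examples
#' ref <- reference_dimer_params()
#' p <- thermo_params(ref$dH[1], TdS298 = ref$TdS298[1])
#' melting_temperature(p, Ct = ref$Ct[1])
#' @export
reference_dimer_params <- function() {
  data.frame(
    label = c("cyclic_decamer", "linear_nonamer", "linear_octamer"),
    sequence = c("d<pTCGTTTCGTT>", "d(TCGTTTCGT)", "d(TCGTTCGT)"),
    dH = c(-38.1, -44.7, -42.8),
    TdS298 = c(-30.2, -38.4, -38.0),
    Ct = c(50e-6, 100e-6, 0.66e-3),
    Tm_C = c(42.0, 30.6, 28.4),
    dG298 = c(-7.9, -6.3, -4.8),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic baselines
#'
#' Fixed, arbitrary folded/unfolded baselines used by the generator:
#' folded signal 10 - 0.01 T, unfolded 1 - 0.002 T (signal units, T in
#' degrees Celsius), i.e. an amplitude of roughly 9 units with gently
#' sloping plateaus, the qualitative shape of a CD melting curve. Real
#' instrument baselines are unknown; since every fitted quantity is
#' invariant to affine transformations of the signal, their exact values
#' are immaterial.
#'
#' @return A `baseline_pair` usable by [simulate_melting()].
#' @export
default_baselines <- function() {
  new_baseline_pair(
    folded = c(intercept = 10, slope = -0.01),
    unfolded = c(intercept = 1, slope = -0.002),
    low_window = c(0, 13.5), high_window = c(76.5, 90),
    low_confidence = FALSE, min_gap = 0.5
  )
}

#' Derive a per-curve sub-seed from a global seed
#'
#' Splitting rule for reproducible multi-curve simulations: sub-seed i is
#' `(seed + 7919 * i) mod (2^31 - 1)` (7919 is the 1000th prime). Element
#' i of a simulated series is therefore reproducible on its own.
#'
#' @param seed Global integer seed.
#' @param i Element index (1-based).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

#' Simulate a melting curve
#'
#' Generates `s(T) = alpha(T) f(T) + (1 - alpha(T)) u(T) + e`, with alpha
#' from the two-state model ([equilibrium_fraction()]), f/u the linear
#' baselines and e iid Gaussian noise. At `T = Tm` the noiseless signal
#' is exactly the mean of the two baseline values. The same seed always
#' reproduces the same curve.
#'
#' @param params A [thermo_params()] object.
#' @param Ct Total strand concentration, mol/L.
#' @param molecularity 1 or 2.
#' @param baselines A `baseline_pair`; default [default_baselines()].
#' @param T_grid Temperatures in degrees Celsius; default 0 to 90 in
#'   steps of 0.5 (a 0.5 C/min scan sampled each minute).
#' @param noise_sd Gaussian noise standard deviation, signal units.
#' @param seed Optional integer seed (set only when noise is drawn).
#' @param pH,buffer Metadata recorded on the curve.
#' @return A [melting_curve()] whose `generator` attribute records the
#'   generating parameters, seed and a `grid_warning` flag (raised, with
#'   an R warning, when alpha does not span beyond \[0.15, 0.85\] inside
#'   the grid).
#' @export
simulate_melting <- function(params, Ct, molecularity = 2,
                             baselines = default_baselines(),
                             T_grid = seq(0, 90, by = 0.5),
                             noise_sd = 0, seed = NULL,
                             pH = 4.5, buffer = "20 mM AcONa, 200 mM NaCl") {
  stopifnot(inherits(params, "thermo_params"),
            inherits(baselines, "baseline_pair"))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be non-negative", call. = FALSE)
  }
  molecularity <- check_molecularity(molecularity)
  alpha <- equilibrium_fraction(params, C_to_K(T_grid), Ct = Ct,
                                molecularity = molecularity)
  grid_warning <- min(alpha) > 0.15 || max(alpha) < 0.85
  if (grid_warning) {
    warning("temperature grid does not span the transition (alpha stays inside [0.15, 0.85] limits)")
  }
  f <- baseline_eval(baselines$folded, T_grid)
  u <- baseline_eval(baselines$unfolded, T_grid)
  s <- alpha * f + (1 - alpha) * u
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + stats::rnorm(length(s), sd = noise_sd)
  }
  curve <- melting_curve(T_grid, s, Ct = Ct, pH = pH, buffer = buffer)
  attr(curve, "generator") <- list(
    dH = params$dH, dS = params$dS, molecularity = molecularity, Ct = Ct,
    baselines = baselines[c("folded", "unfolded")],
    noise_sd = noise_sd, seed = seed, grid_warning = grid_warning
  )
  curve
}

#' Simulate melting curves across a concentration series
#'
#' One curve per concentration, sharing parameters, baselines and grid;
#' curve i draws its noise with sub-seed [derive_seed()]`(seed, i)` so
#' the series is reproducible element-wise.
#'
#' @inheritParams simulate_melting
#' @param Ct_list Numeric vector of at least two total strand
#'   concentrations, mol/L.
#' @param seed Global seed; each curve uses a derived sub-seed.
#' @return A named list of [melting_curve()] objects (names `Ct=<value>`).
#' @export
simulate_concentration_series <- function(params, Ct_list, molecularity = 2,
                                          baselines = default_baselines(),
                                          T_grid = seq(0, 90, by = 0.5),
                                          noise_sd = 0, seed = NULL) {
  if (length(Ct_list) < 2L) {
    stop("need at least 2 concentrations", call. = FALSE)
  }
  out <- lapply(seq_along(Ct_list), function(i) {
    simulate_melting(params, Ct = Ct_list[i], molecularity = molecularity,
                     baselines = baselines, T_grid = T_grid,
                     noise_sd = noise_sd,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, i))
  })
  names(out) <- sprintf("Ct=%g", Ct_list)
  out
}

#' Simulate a pH titration
#'
#' Hill sigmoid between two plateaus plus Gaussian noise, mirroring
#' [fit_titration()]. The default midpoint of 5.9 with Hill coefficient 2
#' reflects an acid-stabilized dimer held by two hemi-protonated C:C+
#' base pairs.
#'
#' @param pKa_app Transition midpoint pH.
#' @param hill Hill coefficient.
#' @param plateau_low,plateau_high Signal of the structured (low-pH) and
#'   unstructured (high-pH) limits.
#' @param pH_grid pH values; a warning is raised if the grid does not
#'   span `pKa_app` +/- 1.5.
#' @param noise_sd Gaussian noise sd, signal units.
#' @param seed Optional integer seed.
#' @param temperature_C,buffer Metadata.
#' @return A [titration_curve()] with a `generator` attribute.
#' @export
simulate_titration <- function(pKa_app = 5.9, hill = 2, plateau_low = 10,
                               plateau_high = 1,
                               pH_grid = seq(4, 8, by = 0.1),
                               noise_sd = 0, seed = NULL, temperature_C = 5,
                               buffer = "20 mM AcONa, 200 mM NaCl") {
  if (min(pH_grid) > pKa_app - 1.5 || max(pH_grid) < pKa_app + 1.5) {
    warning("pH grid does not span pKa_app +/- 1.5; plateaus may be poorly determined")
  }
  theta <- hill_theta(pH_grid, pKa_app, hill)
  s <- plateau_high + (plateau_low - plateau_high) * theta
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + stats::rnorm(length(s), sd = noise_sd)
  }
  curve <- titration_curve(pH_grid, s, temperature_C = temperature_C,
                           buffer = buffer)
  attr(curve, "generator") <- list(pKa_app = pKa_app, hill = hill,
                                   plateau_low = plateau_low,
                                   plateau_high = plateau_high,
                                   noise_sd = noise_sd, seed = seed)
  curve
}

#' Write the canonical fixture set
#'
#' Generates the package's reference fixtures: one melting curve per
#' [reference_dimer_params()] row at its reported concentration, a
#' 20/50 uM concentration pair for the cyclic decamer, and one pH
#' titration (midpoint 5.9, Hill coefficient 2) -- each in a noiseless
#' and a noisy (fixed sub-seed) variant, 12 CSV files in total, plus a
#' JSON manifest recording parameters, seeds and paths.
#'
#' @param dir Output directory (created if needed).
#' @param seed Global seed; per-file sub-seeds via [derive_seed()].
#' @param noise_sd Noise level of the noisy variants, signal units
#'   (default 0.15, i.e. about 1.7 percent of the default amplitude).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
make_fixture_set <- function(dir, seed = 101, noise_sd = 0.15) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- reference_dimer_params()
  manifest <- list(seed = seed, noise_sd = noise_sd, files = list())
  idx <- 0L
  add_melt <- function(name, params_row, Ct) {
    for (noisy in c(FALSE, TRUE)) {
      idx <<- idx + 1L
      sub_seed <- derive_seed(seed, idx)
      p <- thermo_params(params_row$dH, TdS298 = params_row$TdS298)
      curve <- simulate_melting(p, Ct = Ct,
                                noise_sd = if (noisy) noise_sd else 0,
                                seed = if (noisy) sub_seed else NULL)
      file <- file.path(dir, sprintf("melt_%s_%s.csv", name,
                                     if (noisy) "noisy" else "noiseless"))
      write_melting_csv(curve, file)
      manifest$files[[length(manifest$files) + 1L]] <<- list(
        path = basename(file), kind = "melting", label = name,
        dH = params_row$dH, TdS298 = params_row$TdS298, Ct = Ct,
        noise_sd = if (noisy) noise_sd else 0,
        seed = if (noisy) sub_seed else NA
      )
    }
  }
  for (i in seq_len(nrow(ref))) {
    add_melt(ref$label[i], ref[i, ], ref$Ct[i])
  }
  # concentration pair for the cyclic decamer
  for (Ct in c(20e-6, 50e-6)) {
    add_melt(sprintf("cyclic_decamer_ct%guM", Ct * 1e6), ref[1, ], Ct)
  }
  for (noisy in c(FALSE, TRUE)) {
    idx <- idx + 1L
    sub_seed <- derive_seed(seed, idx)
    curve <- simulate_titration(pKa_app = 5.9, hill = 2,
                                noise_sd = if (noisy) noise_sd else 0,
                                seed = if (noisy) sub_seed else NULL)
    file <- file.path(dir, sprintf("titration_%s.csv",
                                   if (noisy) "noisy" else "noiseless"))
    write_titration_csv(curve, file)
    manifest$files[[length(manifest$files) + 1L]] <- list(
      path = basename(file), kind = "titration", label = "titration",
      pKa_app = 5.9, hill = 2,
      noise_sd = if (noisy) noise_sd else 0,
      seed = if (noisy) sub_seed else NA
    )
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
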