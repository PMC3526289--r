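# Reference dimerization parameters used across the tests (same values
# as reference_dimer_params(), kept literal here so tests do not depend
# on the function they also check).
ref_rows <- data.frame(
  label = c("cyclic_decamer", "linear_nonamer", "linear_octamer"),
  dH = c(-38.1, -44.7, -42.8),
  TdS298 = c(-30.2, -38.4, -38.0),
  Ct = c(50e-6, 100e-6, 0.66e-3),
  Tm_C = c(42.0, 30.6, 28.4),
  dG298 = c(-7.9, -6.3, -4.8)
)

R_kcal <- 1.9872e-3

ref_params <- function(i) thermo_params(ref_rows$dH[i], TdS298 = ref_rows$TdS298[i])

# Independent oracle: bisection on the homodimer mass balance
# 2q a^2 - (4q + 1) a + 2q = 0, q = K * Ct; g is decreasing on [0, 1].
bisect_alpha <- function(q, tol = 1e-13) {
  g <- function(a) 2 * q * a^2 - (4 * q + 1) * a + 2 * q
  lo <- 0
  hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
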