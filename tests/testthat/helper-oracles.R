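# Independent oracles, written as plain standalone arithmetic so they do
# not share code paths with the package internals they check.

# Scalar Bethe stopping oracle (eV/Angstrom) for a bare list of elements:
# n in atoms/cm^3, Zt atomic numbers, I_eV mean excitation energies.
oracle_bethe <- function(E_MeV, Z1, A1, n, Zt, I_eV) {
  mu <- 931.49410
  mec2 <- 510998.95
  gamma <- 1 + E_MeV / (A1 * mu)
  beta2 <- 1 - 1 / gamma^2
  zeff <- Z1 * (1 - exp(-125 * sqrt(beta2) / Z1^(2 / 3)))
  total <- 0
  for (i in seq_along(n)) {
    L <- log(2 * mec2 * beta2 * gamma^2 / I_eV[i]) - beta2
    total <- total + 0.307075 * zeff^2 / beta2 *
      (n[i] / 6.02214076e23) * Zt[i] * L
  }
  total * 0.01
}

# ZBL universal reduced nuclear stopping, scalar.
oracle_zbl_universal <- function(eps) {
  if (eps > 30) return(log(eps) / (2 * eps))
  log(1 + 1.1383 * eps) /
    (2 * (eps + 0.01321 * eps^0.21226 + 0.19593 * sqrt(eps)))
}

# Brute-force loop implementations of the straggle estimators.
oracle_sigma_long <- function(x) {
  n <- length(x)
  rp <- sum(x) / n
  s2 <- 0
  for (xi in x) s2 <- s2 + xi^2
  sqrt(s2 / n - rp^2)
}

oracle_sigma_lat <- function(y, z) {
  n <- length(y)
  s <- 0
  for (i in seq_len(n)) s <- s + ((abs(y[i]) + abs(z[i])) / 2)^2
  sqrt(s / n)
}
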