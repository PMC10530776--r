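# Stopping-power physics for light ions in compound materials:
# relativistic Bethe electronic stopping with Barkas-type effective charge
# and Bragg additivity, ZBL universal nuclear stopping, Bohr energy-loss
# straggling, and the CSDA range integral.

MEC2_EV <- 510998.95       # electron rest energy, eV
MU_MEV <- 931.49410        # atomic mass unit, MeV
E2_EVA <- 14.3996          # e^2 in eV * Angstrom (Gaussian units)
BETHE_K <- 0.307075        # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
AVOGADRO <- 6.02214076e23

# Validated kinetic-energy window for the helium-oriented Bethe kernel.
ENERGY_MIN_MEV <- 0.1
ENERGY_MAX_MEV <- 500
# Below 2 MeV/u the Bethe logarithm degrades; stopping is continued there
# with a velocity-proportional power law matched at the join energy.
BETHE_JOIN_MEV_PER_U <- 2

#' Define a projectile
#'
#' @param energy Kinetic energy in MeV (may be a vector).
#' @param Z Projectile atomic number (default 2, helium).
#' @param A Projectile mass in amu (default 4.002602, helium-4).
#' @return Object of class `ip_projectile`.
#' @examples
#' helium(354)
#' @export
projectile <- function(energy, Z = 2, A = 4.002602) {
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("projectile energy must be positive and finite")
  stopifnot(Z >= 1, A > 0)
  structure(list(energy = energy, Z = Z, A = A), class = "ip_projectile")
}

#' @rdname projectile
#' @export
helium <- function(energy) projectile(energy, Z = 2, A = 4.002602)

.check_energy_window <- function(energy) {
  if (any(energy < ENERGY_MIN_MEV) || any(energy > ENERGY_MAX_MEV))
    stop("projectile energy outside the validated range ",
         ENERGY_MIN_MEV, "-", ENERGY_MAX_MEV, " MeV")
}

# Relativistic kinematics per nucleon. Returns beta^2 and beta^2 gamma^2.
.kinematics <- function(energy_MeV, A) {
  gamma <- 1 + energy_MeV / (A * MU_MEV)
  beta2 <- 1 - 1 / gamma^2
  list(gamma = gamma, beta2 = beta2, b2g2 = beta2 * gamma^2)
}

# Barkas-type effective projectile charge.
.z_eff <- function(Z1, beta) {
  Z1 * (1 - exp(-125 * beta / Z1^(2 / 3)))
}

# Bethe electronic stopping, eV/Angstrom, for number densities n (atoms/cm^3)
# of elements with atomic numbers Zt and mean excitation energies I (eV).
# Vectorized over energy.
.bethe_eV_per_A <- function(energy, Z1, A1, n_cm3, Zt, I_eV) {
  kin <- .kinematics(energy, A1)
  zeff <- .z_eff(Z1, sqrt(kin$beta2))
  L <- outer(2 * MEC2_EV * kin$b2g2, I_eV, function(x, i) log(x / i)) -
    kin$beta2
  L[L < 0.05] <- 0.05  # guard: keep stopping positive near the join
  s_mev_cm <- BETHE_K * zeff^2 / kin$beta2 *
    as.vector(L %*% (n_cm3 / AVOGADRO * Zt))
  s_mev_cm * 0.01  # MeV/cm -> eV/Angstrom
}

# Electronic stopping with the low-energy power-law continuation.
.electronic_stopping_nAb <- function(energy, Z1, A1, n_cm3, Zt, I_eV) {
  e_join <- BETHE_JOIN_MEV_PER_U * A1
  lo <- energy < e_join
  out <- numeric(length(energy))
  if (any(!lo))
    out[!lo] <- .bethe_eV_per_A(energy[!lo], Z1, A1, n_cm3, Zt, I_eV)
  if (any(lo)) {
    s_join <- .bethe_eV_per_A(e_join, Z1, A1, n_cm3, Zt, I_eV)
    out[lo] <- s_join * (energy[lo] / e_join)^0.45
  }
  out
}

.material_n <- function(material, basis = "mass") {
  number_densities(material, basis = basis)
}

#' Electronic stopping power in a material
#'
#' Relativistic Bethe stopping with a Barkas-type effective projectile
#' charge, elemental mean excitation energies and Bragg additivity over the
#' material's elements. Below 2 MeV/u the Bethe expression is continued
#' with a velocity-proportional power law matched at the join. Number
#' densities are taken on the mass-density basis by default (see
#' [number_densities()]).
#'
#' @param projectile An [projectile()] object; its `energy` may be a vector.
#' @param material An [material()] object.
#' @param basis Number-density basis, `"mass"` (default) or `"atomic"`.
#' @return Electronic stopping in eV/Angstrom, one value per energy.
#' @examples
#' w <- material("water", c("H", "O"), c(2, 1), mass_density = 1)
#' electronic_stopping(helium(c(100, 350)), w)
#' @export
electronic_stopping <- function(projectile, material,
                                basis = c("mass", "atomic")) {
  stopifnot(inherits(projectile, "ip_projectile"),
            inherits(material, "ip_material"))
  basis <- match.arg(basis)
  .check_energy_window(projectile$energy)
  n <- .material_n(material, basis)
  el <- material$elements
  .electronic_stopping_nAb(projectile$energy, projectile$Z, projectile$A,
                           n, el$Z, el$I_eV)
}

# ZBL universal reduced nuclear stopping.
.zbl_sn_reduced <- function(eps) {
  out <- numeric(length(eps))
  hi <- eps > 30
  out[hi] <- log(eps[hi]) / (2 * eps[hi])
  lo <- !hi
  out[lo] <- log(1 + 1.1383 * eps[lo]) /
    (2 * (eps[lo] + 0.01321 * eps[lo]^0.21226 + 0.19593 * sqrt(eps[lo])))
  out
}

# ZBL reduced energy for projectile (Z1, M1) on target (Z2, M2), E in keV.
.zbl_eps <- function(E_keV, Z1, M1, Z2, M2) {
  32.53 * M2 * E_keV / (Z1 * Z2 * (M1 + M2) * (Z1^0.23 + Z2^0.23))
}

# ZBL nuclear stopping cross-section, eV cm^2 per target atom.
.zbl_sn_cm2 <- function(E_MeV, Z1, M1, Z2, M2) {
  eps <- .zbl_eps(E_MeV * 1e3, Z1, M1, Z2, M2)
  8.462e-15 * Z1 * Z2 * M1 * .zbl_sn_reduced(eps) /
    ((M1 + M2) * (Z1^0.23 + Z2^0.23))
}

#' Nuclear stopping power in a material
#'
#' Screened-Coulomb nuclear stopping using the ZBL universal function,
#' summed over the material's elements. At therapy energies this is
#' negligible relative to electronic stopping but it is carried for
#' completeness in range integrals and exported tables.
#'
#' @inheritParams electronic_stopping
#' @return Nuclear stopping in eV/Angstrom, one value per energy.
#' @export
nuclear_stopping <- function(projectile, material,
                             basis = c("mass", "atomic")) {
  stopifnot(inherits(projectile, "ip_projectile"),
            inherits(material, "ip_material"))
  basis <- match.arg(basis)
  .check_energy_window(projectile$energy)
  n <- .material_n(material, basis)
  el <- material$elements
  s <- numeric(length(projectile$energy))
  for (i in seq_len(nrow(el))) {
    s <- s + n[i] * .zbl_sn_cm2(projectile$energy, projectile$Z,
                                projectile$A, el$Z[i], el$A[i])
  }
  s / 1e8  # eV/cm -> eV/Angstrom
}

#' Bohr energy-loss straggling variance per unit path
#'
#' Free-electron Bohr straggling with a first-order relativistic
#' correction, scaled by the material's electron density.
#'
#' @inheritParams electronic_stopping
#' @return Straggling variance in eV^2/Angstrom, one value per energy.
#' @export
straggling_variance <- function(projectile, material,
                                basis = c("mass", "atomic")) {
  stopifnot(inherits(projectile, "ip_projectile"),
            inherits(material, "ip_material"))
  basis <- match.arg(basis)
  .check_energy_window(projectile$energy)
  n <- .material_n(material, basis)
  el <- material$elements
  ne_A3 <- sum(n * el$Z) * 1e-24  # electrons per Angstrom^3
  kin <- .kinematics(projectile$energy, projectile$A)
  zeff <- .z_eff(projectile$Z, sqrt(kin$beta2))
  rel <- (1 - kin$beta2 / 2) / (1 - kin$beta2)
  4 * pi * E2_EVA^2 * zeff^2 * ne_A3 * rel
}

#' CSDA range in a material
#'
#' Continuous-slowing-down range: the integral of 1/(S_e + S_n) from a low
#' energy cutoff up to the beam energy, on a fine logarithmic grid.
#'
#' @inheritParams electronic_stopping
#' @param cutoff_MeV Lower integration limit (default 0.1 MeV).
#' @param n_grid Number of grid points for the integration (default 4000).
#' @return Range in mm, one value per energy; monotonically increasing.
#' @export
csda_range <- function(projectile, material, basis = c("mass", "atomic"),
                       cutoff_MeV = ENERGY_MIN_MEV, n_grid = 4000) {
  stopifnot(inherits(projectile, "ip_projectile"),
            inherits(material, "ip_material"))
  basis <- match.arg(basis)
  .check_energy_window(projectile$energy)
  e_max <- max(projectile$energy)
  grid <- exp(seq(log(cutoff_MeV), log(e_max), length.out = n_grid))
  s <- electronic_stopping(projectile(grid, projectile$Z, projectile$A),
                           material, basis = basis) +
    nuclear_stopping(projectile(grid, projectile$Z, projectile$A),
                     material, basis = basis)
  inv <- 1e6 / s                      # (eV per MeV) / (eV/A) = A per MeV
  cum <- c(0, cumsum(diff(grid) * (inv[-1] + inv[-length(inv)]) / 2))
  stats::approx(grid, cum, xout = projectile$energy, rule = 2)$y / 1e7  # mm
}

#' Tabulate stopping quantities on an energy grid
#'
#' @inheritParams electronic_stopping
#' @param energies Energy grid in MeV (default: 200 log-spaced points over
#'   the validated window).
#' @return Data frame with columns `energy_MeV`, `S_e_eV_per_A`,
#'   `S_n_eV_per_A`, `straggling_eV2_per_A`, `range_mm`.
#' @export
stopping_table <- function(material, energies = NULL,
                           projectile = helium(100),
                           basis = c("mass", "atomic")) {
  basis <- match.arg(basis)
  if (is.null(energies))
    energies <- exp(seq(log(ENERGY_MIN_MEV), log(ENERGY_MAX_MEV),
                        length.out = 200))
  p <- projectile(energies, projectile$Z, projectile$A)
  data.frame(
    energy_MeV = energies,
    S_e_eV_per_A = electronic_stopping(p, material, basis = basis),
    S_n_eV_per_A = nuclear_stopping(p, material, basis = basis),
    straggling_eV2_per_A = straggling_variance(p, material, basis = basis),
    range_mm = csda_range(p, material, basis = basis)
  )
}

#' Export a stopping table as CSV
#'
#' @param material An [material()] object.
#' @param path Output file path.
#' @param ... Passed to [stopping_table()].
#' @export
export_stopping_csv <- function(material, path, ...) {
  utils::write.csv(stopping_table(material, ...), path, row.names = FALSE)
  invisible(path)
}

# --- recoil-atom electronic/nuclear crossover -------------------------------

# Lindhard-Scharff reduced electronic-stopping coefficient k for projectile
# (Z1, A1) in target (Z2, A2).
.lindhard_k <- function(Z1, A1, Z2, A2) {
  0.0793 * Z1^(2 / 3) * sqrt(Z2) * (A1 + A2)^1.5 /
    ((Z1^(2 / 3) + Z2^(2 / 3))^0.75 * A1^1.5 * sqrt(A2))
}

.recoil_cutoff_cache <- new.env(parent = emptyenv())

#' Electronic-stopping cutoff energy for a recoiling atom
#'
#' Returns the energy at which the electronic stopping of a recoiling atom
#' of the given element (moving among like atoms) equals its nuclear
#' stopping: Lindhard-Scharff electronic stopping versus the ZBL universal
#' nuclear stopping, solved in reduced units. Used as the default
#' Kinchin-Pease cutoff `E_c` per element.
#'
#' @param symbol Chemical symbol.
#' @return Cutoff energy in eV.
#' @examples
#' recoil_cutoff_energy("O")
#' @export
recoil_cutoff_energy <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1)
  if (!is.null(.recoil_cutoff_cache[[symbol]]))
    return(.recoil_cutoff_cache[[symbol]])
  info <- element_info(symbol)
  k <- .lindhard_k(info$Z, info$A, info$Z, info$A)
  f <- function(eps) k * sqrt(eps) - .zbl_sn_reduced(eps)
  eps_c <- stats::uniroot(f, c(1e-2, 1e4), tol = 1e-10)$root
  # reduced -> keV for the self-ion pair, then eV
  e_keV <- eps_c * info$Z^2 * (2 * info$A) * (2 * info$Z^0.23) /
    (32.53 * info$A)
  out <- e_keV * 1e3
  .recoil_cutoff_cache[[symbol]] <- out
  out
}
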