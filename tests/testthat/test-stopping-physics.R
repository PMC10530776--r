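test_that("electronic stopping behaves like Bethe theory", {
  w <- water_material()
  # Bethe-region monotonicity
  s <- electronic_stopping(helium(c(100, 350)), w)
  expect_gt(s[1], s[2])
  # density scaling: doubling all number densities doubles S_e
  w2 <- material("dense-water", c("H", "O"), c(2, 1),
                 atomic_density = 2 * 10.02, mass_density = 2)
  expect_equal(electronic_stopping(helium(200), w2),
               2 * electronic_stopping(helium(200), w), tolerance = 1e-12)
  # independent oracle at 88.5 MeV/u (354.1 MeV for helium-4)
  n <- number_densities(w, basis = "mass")
  info <- element_info(c("H", "O"))
  expect_equal(
    electronic_stopping(helium(88.5 * 4.002602), w),
    unname(oracle_bethe(88.5 * 4.002602, 2, 4.002602, n, info$Z, info$I_eV)),
    tolerance = 0.05)
  # validated window enforced
  expect_error(electronic_stopping(helium(0.05), w), "0.1-500")
  expect_error(csda_range(helium(600), w), "0.1-500")
})

test_that("stopping is additive over elemental partial densities", {
  w <- water_material()
  nd <- number_densities(w, basis = "atomic")
  mk <- function(sym, n_cm3) {
    a <- element_info(sym)$A
    material(sym, sym, 1, atomic_density = n_cm3 / 1e22,
             mass_density = n_cm3 * a * 1.66053907e-24)
  }
  sum_parts <- electronic_stopping(helium(150), mk("H", nd["H"]),
                                   basis = "atomic") +
    electronic_stopping(helium(150), mk("O", nd["O"]), basis = "atomic")
  expect_equal(electronic_stopping(helium(150), w, basis = "atomic"),
               sum_parts, tolerance = 1e-9)
})

test_that("nuclear stopping follows the ZBL universal function", {
  w <- water_material()
  sn <- nuclear_stopping(helium(350), w)
  se <- electronic_stopping(helium(350), w)
  expect_lt(sn / se, 1e-3)
  # monotonic decrease above the nuclear-stopping maximum
  sn_scan <- nuclear_stopping(helium(c(1, 10, 100, 350)), w)
  expect_true(all(diff(sn_scan) < 0))

  # two single-element targets at equal reduced energy: the S_n ratio is
  # the ratio of prefactors (the universal function cancels)
  mkpure <- function(sym) {
    a <- element_info(sym)$A
    material(sym, sym, 1, atomic_density = 5,
             mass_density = 5e22 * a * 1.66053907e-24)
  }
  carbon <- mkpure("C"); oxygen <- mkpure("O")
  zc <- element_info("C"); zo <- element_info("O")
  eps_of <- function(E_MeV, Zt, At)
    32.53 * At * E_MeV * 1e3 /
      (2 * Zt * (4.002602 + At) * (2^0.23 + Zt^0.23))
  e_c <- 5                                   # MeV in carbon
  eps <- eps_of(e_c, zc$Z, zc$A)
  e_o <- e_c * eps_of(1, zo$Z, zo$A)^-1 * eps_of(1, zc$Z, zc$A)  # match eps
  expect_equal(eps_of(e_o, zo$Z, zo$A), eps, tolerance = 1e-9)
  pref <- function(Zt, At)
    2 * Zt * 4.002602 / ((4.002602 + At) * (2^0.23 + Zt^0.23))
  expect_equal(
    unname(nuclear_stopping(helium(e_c), carbon) /
             nuclear_stopping(helium(e_o), oxygen)),
    pref(zc$Z, zc$A) / pref(zo$Z, zo$A),
    tolerance = 1e-6)
})

test_that("CSDA range integrates the reciprocal stopping power", {
  w <- water_material()
  r <- csda_range(helium(c(354, 376)), w)
  expect_gt(r[2], r[1])
  # double mass density halves the range
  w2 <- material("dense-water", c("H", "O"), c(2, 1),
                 atomic_density = 2 * 10.02, mass_density = 2)
  expect_equal(csda_range(helium(354), w2), r[1] / 2, tolerance = 1e-6)
  # independent fine-grid trapezoid integration oracle
  grid <- exp(seq(log(0.1), log(354), length.out = 40000))
  s <- electronic_stopping(helium(grid), w) + nuclear_stopping(helium(grid), w)
  inv <- 1e6 / s
  oracle_mm <- sum(diff(grid) * (inv[-1] + inv[-length(inv)]) / 2) / 1e7
  expect_equal(r[1], oracle_mm, tolerance = 0.01)
})

test_that("straggling variance is Bohr-like", {
  w <- water_material()
  v <- straggling_variance(helium(c(50, 354)), w)
  expect_true(all(v > 0))
  # linear in electron density: double density doubles the variance
  w2 <- material("dense-water", c("H", "O"), c(2, 1),
                 atomic_density = 2 * 10.02, mass_density = 2)
  expect_equal(straggling_variance(helium(354), w2), 2 * v[2],
               tolerance = 1e-12)
})

test_that("stopping tables satisfy the declared invariants", {
  tab <- stopping_table(water_material(),
                        energies = exp(seq(log(5), log(400), length.out = 60)))
  expect_true(all(tab$S_e_eV_per_A > 0))
  expect_true(all(tab$S_n_eV_per_A >= 0))
  expect_true(all(diff(tab$range_mm) > 0))
  bethe <- tab$energy_MeV > 2 * 4.003      # above the 2 MeV/u Bethe join
  expect_true(all(diff(tab$S_e_eV_per_A[bethe]) < 0))
  expect_true(all(tab$S_n_eV_per_A / tab$S_e_eV_per_A < 1e-3 | !bethe))
  p <- withr::local_tempfile(fileext = ".csv")
  export_stopping_csv(water_material(), p)
  expect_true(file.exists(p))
})

test_that("recoil electronic cutoffs sit at the keV scale", {
  ec <- vapply(c("H", "C", "O", "Ca"), recoil_cutoff_energy, numeric(1))
  expect_true(all(ec > 100))
  expect_true(all(ec < 5e6))
  expect_true(all(diff(ec[c("C", "O", "Ca")]) > 0))  # grows with Z
})
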