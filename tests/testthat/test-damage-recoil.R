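test_that("Kinchin-Pease closed form reproduces the piecewise bands", {
  m <- kp_model(E_d = 25, E_c = 30e3)
  expect_equal(kp_displacements(0.5 * 25, m), 0)
  expect_equal(kp_displacements(1.5 * 25, m), 1)
  expect_equal(kp_displacements(10e3, m), 200)     # T / (2 E_d)
  expect_equal(kp_displacements(100e3, m), 600)    # saturation E_c / (2 E_d)
  expect_error(kp_displacements(-1, m), "non-negative")
  expect_error(kp_model(E_d = 50, E_c = 25), "E_d < E_c")

  # non-decreasing, continuous except the unit jump at E_d
  tt <- sort(c(seq(0, 40e3, length.out = 4001), 25 - 1e-9, 25,
               50 - 1e-9, 50, 30e3 - 1e-9, 30e3))
  v <- kp_displacements(tt, m)
  expect_true(all(diff(v) >= -1e-12))
  jumps <- diff(v)[diff(tt) < 1e-6]
  expect_true(all(jumps <= 1 + 1e-9))

  # default cutoff derived per element
  mo <- kp_model(element = "O")
  expect_gt(mo$E_c, mo$E_d)
  expect_equal(mo$E_c, recoil_cutoff_energy("O"))
})

test_that("NRT counts apply the 0.8 efficiency above 2.5 E_d", {
  m <- nrt_model(E_d = 25)
  expect_equal(nrt_displacements(0.5 * 25, m), 0)
  expect_equal(nrt_displacements(2 * 25, m), 1)
  expect_equal(nrt_displacements(2500, m), 40)     # 0.8 * 2500 / 50
  expect_equal(nrt_displacements(2.5 * 25, m), 1)  # continuous band edge
  expect_error(nrt_displacements(-5, m), "non-negative")

  # NRT never exceeds the ideal Kinchin-Pease count below the cutoff
  kp <- kp_model(E_d = 25, E_c = 30e3)
  ev <- seq(0, 30e3 - 1, length.out = 2000)
  expect_true(all(nrt_displacements(ev, m) <= kp_displacements(ev, kp) + 1e-12))
})

test_that("the stochastic cascade converges to the Kinchin-Pease mean", {
  # below threshold: every trial is zero
  o0 <- cascade_oracle(10, E_d = 25, n_trials = 200, seed = 3)
  expect_equal(as.numeric(o0), 0)
  expect_true(all(attr(o0, "trials") == 0))

  # T = 100 E_d converges to T / (2 E_d) = 50 within 5%
  o <- cascade_oracle(100 * 25, E_d = 25, n_trials = 1e4, seed = 11)
  expect_lt(abs(as.numeric(o) - 50) / 50, 0.05)

  # trial counts have finite spread and the mean stabilises with trials
  trials <- attr(o, "trials")
  expect_true(is.finite(var(trials)) && var(trials) > 0)
  half <- mean(trials[1:5000])
  se <- sd(trials) / sqrt(5000)
  expect_lt(abs(half - mean(trials)), 4 * se + 1e-9)

  # oracle equivalence across the K-P linear band
  for (mult in c(10, 40)) {
    om <- cascade_oracle(mult * 25, E_d = 25, n_trials = 1e4, seed = 7)
    expect_lt(abs(as.numeric(om) - mult / 2) / (mult / 2), 0.05)
  }
})

test_that("recoil tallies proportion energy between elements", {
  kp <- kp_model(25, 30e3)
  empty <- tally_recoils(data.frame(depth_mm = numeric(0),
                                    element = character(0),
                                    T_eV = numeric(0)),
                         path_length_A = 1e8, n_ions = 10, kp = kp)
  expect_equal(empty$total_recoil, 0)
  expect_length(empty$contribution_pct, 0)

  ev <- data.frame(depth_mm = c(1, 2), element = c("H", "O"),
                   T_eV = c(75, 25))
  t2 <- tally_recoils(ev, path_length_A = 1e8, n_ions = 1, kp = kp)
  expect_equal(unname(t2$contribution_pct), c(75, 25))
  expect_equal(t2$total_recoil, 100 / 1e8)
  expect_equal(unname(t2$displacements["H"]),
               kp_displacements(75, kp))

  # percentages sum to 100 on random event sets
  set.seed(99)
  ev3 <- data.frame(depth_mm = runif(500),
                    element = sample(c("H", "C", "O", "F"), 500, TRUE),
                    T_eV = rexp(500, 1 / 300))
  t3 <- tally_recoils(ev3, 1e9, 100, kp)
  expect_equal(sum(t3$contribution_pct), 100, tolerance = 1e-9)
  expect_error(tally_recoils(ev, 0, 1, kp))
})

test_that("phantom recoil tables only contain elements present", {
  study <- reference_water_sim()
  ev <- study$recoil_events
  expect_true(all(ev$element %in% c("H", "O")))
  tl <- tally_recoils(ev, path_length_A = 90 * 1e7,
                      n_ions = study$provenance$n_ions,
                      kp = list(H = kp_model(element = "H"),
                                O = kp_model(element = "O")))
  expect_true(all(names(tl$contribution_pct) %in% c("H", "O")))
  expect_equal(sum(tl$contribution_pct), 100, tolerance = 0.1)
  expect_true(all(tl$displacements >= 0))
})
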