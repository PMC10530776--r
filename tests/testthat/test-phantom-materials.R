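test_that("builtin fixtures carry the published layer table", {
  tis <- builtin_phantom("tissue")
  bio <- builtin_phantom("biomaterial")
  expect_length(tis$layers, 10)
  expect_length(bio$layers, 10)
  expect_equal(vapply(tis$layers, function(l) l$material$name, character(1)),
               c("skin", "parotid gland", "SMAS", "masseter muscle",
                 "buccal fat", "mucosa", "saliva", "gum", "cortical bone",
                 "cancellous bone"))

  # PMMA fractions renormalized from percentages
  pmma <- bio$layers[[1]]$material
  expect_equal(pmma$name, "PMMA")
  expect_equal(pmma$elements$fraction,
               c(53.3, 33.3, 13.3) / 99.9, tolerance = 1e-12)

  # saliva row: water at 10.02e22 atoms/cm^3 and 1 g/cm^3
  sal <- tis$layers[[7]]$material
  expect_equal(sal$elements$symbol, c("H", "O"))
  expect_equal(sal$atomic_density, 10.02)
  expect_equal(sal$mass_density, 1)

  # layers 9 and 10 of the biomaterial variant are Teflon
  for (i in 9:10) {
    tef <- bio$layers[[i]]$material
    expect_equal(tef$name, "Teflon")
    expect_equal(tef$mass_density, 2.2)
    expect_equal(tef$atomic_density, 7.95)
  }

  # every fixture material: normalized fractions sum to 1; all symbols
  # resolve to element constants
  for (ph in list(tis, bio)) {
    expect_equal(ph$total_depth,
                 sum(vapply(ph$layers, function(l) l$thickness_mm,
                            numeric(1))))
    for (l in ph$layers) {
      expect_equal(sum(l$material$elements$fraction), 1, tolerance = 1e-9)
      expect_silent(element_info(l$material$elements$symbol))
    }
  }
  expect_error(builtin_phantom("bone"), "tissue, biomaterial")
})

test_that("number densities split by fraction on both bases", {
  w <- water_material()
  nd <- number_densities(w)
  expect_equal(unname(nd["H"]), 10.02e22 * 2 / 3, tolerance = 1e-9)
  expect_equal(unname(nd["O"]), 10.02e22 * 1 / 3, tolerance = 1e-9)
  expect_equal(sum(nd), w$atomic_density * 1e22, tolerance = 1e-6)

  # single-element material gets the full atomic density
  c1 <- material("carbon", "C", 1, atomic_density = 11.3, mass_density = 2.25)
  expect_equal(unname(number_densities(c1)), 11.3e22)

  # PMMA split: fractions times total (hand multiplication)
  pmma <- builtin_phantom("biomaterial")$layers[[1]]$material
  nd <- number_densities(pmma)
  expect_equal(unname(nd),
               8.57e22 * c(53.3, 33.3, 13.3) / 99.9, tolerance = 1e-9)

  # mass basis reproduces the mass density exactly and, for internally
  # consistent rows (PMMA, saliva), agrees with the atomic basis to ~1%
  for (m in list(pmma, water_material())) {
    ndm <- number_densities(m, basis = "mass")
    amu <- 1.66053907e-24
    expect_equal(sum(ndm * m$elements$A) * amu, m$mass_density,
                 tolerance = 1e-9)
    expect_equal(unname(ndm), unname(number_densities(m, basis = "atomic")),
                 tolerance = 0.02)
  }
})

test_that("material construction rejects degenerate inputs", {
  expect_error(material("m", c("H", "Xx"), c(1, 1), mass_density = 1), "Xx")
  expect_error(material("m", c("H", "O"), c(0, 0), mass_density = 1),
               "all zero")
  expect_error(material("m", c("H", "O"), c(-1, 2), mass_density = 1),
               "non-negative")
  expect_error(material("m", "H", 1, mass_density = -2), "mass_density")
  expect_error(phantom_layer(water_material(), -5), "thickness")
  expect_error(phantom("p", list()), "empty layer list")
})

test_that("phantom configs round-trip through YAML", {
  cfg <- "
name: test-slab
layers:
- material: water
  elements: {H: 66.6, O: 33.3}
  atomic_density_1e22: 10.02
  mass_density: 1.0
  thickness_mm: 50
"
  ph <- load_phantom(cfg)
  expect_s3_class(ph, "ip_phantom")
  expect_equal(ph$total_depth, 50)

  # over-100 percentages are renormalized to unit sum
  cfg2 <- "
layers:
- material: odd
  elements: {H: 60.5, O: 50.0}
  mass_density: 1.0
  thickness_mm: 10
"
  ph2 <- load_phantom(cfg2)
  expect_equal(sum(ph2$layers[[1]]$material$elements$fraction), 1,
               tolerance = 1e-12)

  expect_error(load_phantom("name: x\nlayers: []\n"), "empty layer list")

  # save -> load preserves every numeric field
  tis <- builtin_phantom("tissue")
  path <- withr::local_tempfile(fileext = ".yaml")
  save_phantom(tis, path)
  back <- load_phantom(path)
  expect_equal(back$total_depth, tis$total_depth, tolerance = 1e-9)
  for (i in seq_along(tis$layers)) {
    a <- tis$layers[[i]]$material
    b <- back$layers[[i]]$material
    expect_equal(b$elements$fraction, a$elements$fraction, tolerance = 1e-9)
    expect_equal(b$atomic_density, a$atomic_density, tolerance = 1e-9)
    expect_equal(b$mass_density, a$mass_density, tolerance = 1e-9)
  }

  csv <- withr::local_tempfile(fileext = ".csv")
  export_phantom_csv(tis, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$thickness_mm,
               vapply(tis$layers, function(l) l$thickness_mm, numeric(1)))
})
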