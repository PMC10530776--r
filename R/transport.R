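# Condensed-history Monte Carlo transport of an ion ensemble through a
# plane-parallel phantom.
#
# Per step: deterministic Bethe energy loss, Gaussian Bohr straggling,
# Highland small-angle multiple scattering, and nuclear elastic collisions.
# Collisions are split at `recoil_split` eV: transfers above the split are
# sampled discretely from the unscreened Rutherford 1/T^2 spectrum
# (Poisson event counts, categorical element choice, inverse-CDF transfer
# sampling); the sub-split continuum is deposited deterministically as a
# restricted nuclear stopping, per element. Ions terminate below the
# low-energy cutoff (residual energy deposited locally into the recoil
# channel) or on leaving the phantom (transmitted).

MM_TO_A <- 1e7  # Angstrom per mm

#' Beam specification
#'
#' @param energy Beam kinetic energy in MeV.
#' @param n_ions Number of primary ions (default 1e5, the study ensemble).
#' @param seed Integer RNG seed; recorded in all outputs.
#' @param projectile Projectile species (default helium-4 at `energy`).
#' @return Object of class `ip_beam`.
#' @export
beam_spec <- function(energy, n_ions = 1e5, seed = 1,
                      projectile = helium(energy)) {
  stopifnot(length(energy) == 1, is.finite(energy))
  if (n_ions < 1) stop("n_ions must be >= 1")
  .check_energy_window(energy)
  structure(list(energy = energy, n_ions = as.integer(n_ions),
                 seed = as.integer(seed), projectile = projectile),
            class = "ip_beam")
}

#' Transport configuration
#'
#' @param step_fraction Maximum fractional energy loss per step
#'   (default 0.01, must lie in (0, 0.05]).
#' @param n_depth_bins Number of uniform depth bins over the phantom
#'   (default 400, minimum 10).
#' @param recoil_threshold Minimum tallied recoil energy in eV (default 10).
#' @param low_energy_cutoff Transport cutoff in MeV (default 0.1); ions
#'   below it stop and deposit their residual energy locally.
#' @param recoil_split Boundary (eV) between the deterministically
#'   deposited recoil continuum and discretely sampled collisions
#'   (default 1000 eV).
#' @param max_step_mm Maximum step length in mm; defaults to one depth bin.
#' @return Object of class `ip_config`.
#' @export
transport_config <- function(step_fraction = 0.01, n_depth_bins = 400,
                             recoil_threshold = 10, low_energy_cutoff = 0.1,
                             recoil_split = 1000, max_step_mm = NULL) {
  if (!(step_fraction > 0 && step_fraction <= 0.05))
    stop("step_fraction must lie in (0, 0.05]")
  if (n_depth_bins < 10) stop("n_depth_bins must be >= 10")
  stopifnot(recoil_threshold > 0, recoil_split > recoil_threshold,
            low_energy_cutoff > 0)
  structure(list(step_fraction = step_fraction,
                 n_depth_bins = as.integer(n_depth_bins),
                 recoil_threshold = recoil_threshold,
                 low_energy_cutoff = low_energy_cutoff,
                 recoil_split = recoil_split,
                 max_step_mm = max_step_mm),
            class = "ip_config")
}

# Precompute per-layer interpolation tables shared by all steps.
# All interpolation is linear in log10(E) vs log10(value) on a common grid,
# so lookups reduce to matrix indexing without per-layer loops.
.phantom_tables <- function(phantom, proj, config) {
  layers <- phantom$layers
  nl <- length(layers)
  e_grid <- 10^seq(log10(ENERGY_MIN_MEV), log10(ENERGY_MAX_MEV),
                   length.out = 320)
  ne <- length(e_grid)
  syms <- phantom_elements(phantom)
  nsym <- length(syms)
  lse <- lsg <- llam <- lsc <- matrix(0, ne, nl)
  wcont <- wdisc <- gmat <- matrix(0, nl, nsym,
                                   dimnames = list(NULL, syms))
  x0_mm <- numeric(nl)
  thr <- config$recoil_threshold
  split <- config$recoil_split
  M1 <- proj$A; Z1 <- proj$Z
  e_eV <- e_grid * 1e6
  for (j in seq_len(nl)) {
    mat <- layers[[j]]$material
    el <- mat$elements
    n_cm3 <- number_densities(mat, basis = "mass")
    n_A3 <- n_cm3 * 1e-24
    p <- projectile(e_grid, Z1, M1)
    se <- electronic_stopping(p, mat, basis = "mass")
    sg <- straggling_variance(p, mat, basis = "mass")
    # Rutherford collision kernel per element: C(E) = (pi b^2 / 4) * Tmax,
    # with b the collision diameter in the CM frame and Tmax = gamma_kin E.
    lam <- sc <- numeric(ne)
    for (i in seq_len(nrow(el))) {
      M2 <- el$A[i]
      gkin <- 4 * M1 * M2 / (M1 + M2)^2
      e_cm <- e_eV * M2 / (M1 + M2)
      b <- Z1 * el$Z[i] * E2_EVA / e_cm               # Angstrom
      Cfac <- pi * b^2 / 4 * gkin * e_eV              # eV * A^2
      tmax <- gkin * e_eV
      lam_i <- n_A3[i] * Cfac * pmax(1 / split - 1 / tmax, 0)
      sc_i <- n_A3[i] * Cfac * log(pmin(split, tmax) / thr)
      lam <- lam + lam_i
      sc <- sc + sc_i
      sym <- el$symbol[i]
      # the per-element share of both channels is energy independent
      wdisc[j, sym] <- n_A3[i] * (Z1 * el$Z[i] * (M1 + M2) / M2)^2 * gkin
      wcont[j, sym] <- wdisc[j, sym]
      gmat[j, sym] <- gkin
    }
    wdisc[j, ] <- wdisc[j, ] / sum(wdisc[j, ])
    wcont[j, ] <- wcont[j, ] / sum(wcont[j, ])
    lse[, j] <- log10(se)
    lsg[, j] <- log10(sg)
    llam[, j] <- log10(pmax(lam, 1e-300))
    lsc[, j] <- log10(pmax(sc, 1e-300))
    # radiation length (mm) for Highland scattering
    wmass <- el$fraction * el$A / sum(el$fraction * el$A)
    x0_g <- 1 / sum(wmass / .element_x0(el$Z, el$A))
    x0_mm[j] <- x0_g / mat$mass_density * 10
  }
  list(le_grid = log10(e_grid), dle = diff(log10(e_grid))[1],
       lse = lse, lsg = lsg, llam = llam, lsc = lsc,
       wcont = wcont, wdisc = wdisc, gmat = gmat, x0_mm = x0_mm,
       syms = syms)
}

# Vectorized table lookup: value[i] = 10^interp(tab[, layer[i]], logE[i]).
.lookup <- function(tabmat, tabs, le, li) {
  pos <- (le - tabs$le_grid[1]) / tabs$dle
  i0 <- pmin(pmax(floor(pos), 0), length(tabs$le_grid) - 2)
  fr <- pos - i0
  ne <- length(tabs$le_grid)
  base <- i0 + 1 + ne * (li - 1)
  10^((1 - fr) * tabmat[base] + fr * tabmat[base + 1])
}

#' Run a Monte Carlo simulation
#'
#' Transports `beam$n_ions` independent ions through the phantom and
#' aggregates depth-binned ionization and per-element recoil tallies
#' (eV/Angstrom per ion), per-ion endpoints, discrete recoil events and an
#' energy-conservation audit. Identical seed and inputs give identical
#' output.
#'
#' @param beam An [beam_spec()].
#' @param phantom An [phantom()] / [builtin_phantom()].
#' @param config An [transport_config()].
#' @return Object of class `ip_simulation` with components `depth_dose`
#'   (data frame: `depth_mm`, `ionization`, `recoil_total` and one column
#'   per element), `tracks` (per-ion endpoints: `ion_id`, `x_mm`, `y_mm`,
#'   `z_mm`, `stopped`, `exit_energy_MeV`, `recoil_eV`), `recoil_events`
#'   (discrete events: `depth_mm`, `element`, `T_eV`), `recoil_continuum`
#'   (named per-element energy sums, eV), `energy_audit` and `provenance`.
#' @examples
#' \donttest{
#' ph <- builtin_phantom("tissue")
#' sim <- run_simulation(beam_spec(354, n_ions = 500, seed = 7), ph)
#' }
#' @export
run_simulation <- function(beam, phantom, config = transport_config()) {
  stopifnot(inherits(beam, "ip_beam"), inherits(phantom, "ip_phantom"),
            inherits(config, "ip_config"))
  if (beam$n_ions < 1) stop("n_ions must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(beam$seed)

  proj <- beam$projectile
  tabs <- .phantom_tables(phantom, proj, config)
  nl <- length(phantom$layers)
  nsym <- length(tabs$syms)
  depth <- phantom$total_depth
  nb <- config$n_depth_bins
  hw <- depth / nb
  max_step <- if (is.null(config$max_step_mm)) hw else config$max_step_mm
  bounds <- cumsum(vapply(phantom$layers, function(l) l$thickness_mm,
                          numeric(1)))
  cutoff_eV <- config$low_energy_cutoff * 1e6
  split <- config$recoil_split
  M1c2 <- proj$A * MU_MEV  # MeV

  N <- beam$n_ions
  E <- rep(beam$energy * 1e6, N)  # eV
  x <- y <- z <- numeric(N)
  uy <- uz <- numeric(N)
  alive <- rep(TRUE, N)
  stopped <- logical(N)
  exit_E <- rep(NA_real_, N)
  recoil_ion <- numeric(N)

  ionization <- numeric(nb)
  # continuum + residual recoil energy by (depth bin, layer); element
  # attribution is applied once at the end via the constant weight matrix
  rec_bin_layer <- matrix(0, nb, nl)
  rec_bin_disc <- matrix(0, nb, nsym, dimnames = list(NULL, tabs$syms))
  ev_depth <- list(); ev_elem <- list(); ev_T <- list(); ev_k <- 0

  add_by <- function(acc, idx, val) {
    rs <- rowsum(val, idx, reorder = FALSE)
    acc[as.integer(rownames(rs))] <- acc[as.integer(rownames(rs))] + rs[, 1]
    acc
  }

  iter <- 0
  while (any(alive)) {
    iter <- iter + 1
    if (iter > 2e5) stop("internal error: transport failed to terminate")
    ia <- which(alive)
    Ei <- E[ia]
    if (any(!is.finite(Ei))) stop("internal error: non-finite ion energy")
    li <- findInterval(x[ia], bounds) + 1L
    li[li > nl] <- nl
    le <- log10(Ei) - 6  # log10 MeV
    se <- .lookup(tabs$lse, tabs, le, li)        # eV/A
    sg <- .lookup(tabs$lsg, tabs, le, li)        # eV^2/A
    lam <- .lookup(tabs$llam, tabs, le, li)      # events/A
    sc <- .lookup(tabs$lsc, tabs, le, li)        # eV/A

    uyi <- uy[ia]; uzi <- uz[ia]
    ux <- sqrt(pmax(1 - uyi^2 - uzi^2, 0.25))
    ds <- pmin(config$step_fraction * Ei / (se * MM_TO_A), max_step)  # mm
    db <- (bounds[li] - x[ia]) / ux
    crossing <- db < ds
    ds[crossing] <- db[crossing] + 1e-6
    dsA <- ds * MM_TO_A

    # electronic loss with Bohr straggling
    dE_ion <- se * dsA + stats::rnorm(length(ia)) * sqrt(sg * dsA)
    dE_ion <- pmin(pmax(dE_ion, 0), Ei)

    # sub-split recoil continuum (deterministic)
    dE_cont <- sc * dsA

    # discrete nuclear collisions above the split
    dE_disc <- numeric(length(ia))
    k <- stats::rpois(length(ia), lam * dsA)
    hot <- which(k > 0)
    if (length(hot)) {
      rows <- rep(hot, k[hot])                 # index into ia
      lrow <- li[rows]
      W <- tabs$wdisc[lrow, , drop = FALSE]
      cw <- W
      if (nsym > 1) for (jj in 2:nsym) cw[, jj] <- cw[, jj] + cw[, jj - 1]
      u <- stats::runif(length(rows)) * cw[, nsym]
      elx <- max.col(cw >= u, ties.method = "first")
      tmax <- tabs$gmat[cbind(lrow, elx)] * E[ia[rows]]
      uu <- stats::runif(length(rows))
      Tval <- split / (1 - uu * (1 - split / tmax))
      rs <- rowsum(Tval, rows, reorder = FALSE)
      dE_disc[as.integer(rownames(rs))] <- rs[, 1]
    }

    # keep total loss within the available energy (protects the audit when
    # a near-maximal transfer coincides with a full condensed step)
    tot_rec <- dE_cont + dE_disc
    over <- tot_rec > 0.999 * (Ei - dE_ion)
    if (any(over)) {
      f <- pmax(0.999 * (Ei[over] - dE_ion[over]), 0) / tot_rec[over]
      dE_cont[over] <- dE_cont[over] * f
      dE_disc[over] <- dE_disc[over] * f
      if (length(hot)) {
        fi <- rep(1, length(ia)); fi[over] <- f
        Tval <- Tval * fi[rows]
      }
    }

    # deposit: ionization and continuum at the step midpoint
    xm <- x[ia] + 0.5 * ds * ux
    bin <- pmin(pmax(ceiling(xm / hw), 1L), nb)
    ionization <- add_by(ionization, bin, dE_ion)
    keyc <- bin + nb * (li - 1L)
    rsc <- rowsum(dE_cont, keyc, reorder = FALSE)
    kk <- as.integer(rownames(rsc))
    rec_bin_layer[kk] <- rec_bin_layer[kk] + rsc[, 1]
    if (length(hot)) {
      ev_k <- ev_k + 1
      dep <- xm[rows]
      ev_depth[[ev_k]] <- dep
      ev_elem[[ev_k]] <- tabs$syms[elx]
      ev_T[[ev_k]] <- Tval
      bine <- pmin(pmax(ceiling(dep / hw), 1L), nb)
      keyd <- bine + nb * (elx - 1L)
      rsd <- rowsum(Tval, keyd, reorder = FALSE)
      kk <- as.integer(rownames(rsd))
      rec_bin_disc[kk] <- rec_bin_disc[kk] + rsd[, 1]
    }
    recoil_ion[ia] <- recoil_ion[ia] + dE_cont + dE_disc

    # advance
    E[ia] <- Ei - (dE_ion + dE_cont + dE_disc)
    x[ia] <- x[ia] + ds * ux
    y[ia] <- y[ia] + ds * uyi
    z[ia] <- z[ia] + ds * uzi

    # Highland multiple scattering (plane-angle accumulation)
    Emev <- Ei * 1e-6
    pc <- sqrt(Emev * (Emev + 2 * M1c2))
    beta <- pc / (Emev + M1c2)
    lf <- pmax(1 + 0.038 * log(ds * proj$Z^2 /
                                 (tabs$x0_mm[li] * beta^2)), 0.25)
    th0 <- 13.6 / (beta * pc) * proj$Z * sqrt(ds / tabs$x0_mm[li]) * lf
    uy[ia] <- uyi + stats::rnorm(length(ia)) * th0
    uz[ia] <- uzi + stats::rnorm(length(ia)) * th0

    # terminations
    out <- x[ia] >= depth
    dead <- E[ia] <= cutoff_eV & !out
    if (any(dead)) {
      id <- ia[dead]
      stopped[id] <- TRUE
      alive[id] <- FALSE
      res <- pmax(E[id], 0)
      binr <- pmin(pmax(ceiling(x[id] / hw), 1L), nb)
      keyr <- binr + nb * (li[dead] - 1L)
      rsr <- rowsum(res, keyr, reorder = FALSE)
      kk <- as.integer(rownames(rsr))
      rec_bin_layer[kk] <- rec_bin_layer[kk] + rsr[, 1]
      recoil_ion[id] <- recoil_ion[id] + res
      E[id] <- 0
    }
    if (any(out)) {
      id <- ia[out]
      alive[id] <- FALSE
      exit_E[id] <- E[id] * 1e-6
    }
  }

  # element attribution of the continuum/residual channel
  rec_bin_elem <- rec_bin_layer %*% tabs$wcont + rec_bin_disc
  cont_elem <- colSums(rec_bin_layer %*% tabs$wcont)

  norm <- N * hw * MM_TO_A  # per ion, per Angstrom
  dd <- data.frame(depth_mm = (seq_len(nb) - 0.5) * hw,
                   ionization = ionization / norm,
                   recoil_total = rowSums(rec_bin_elem) / norm)
  for (s in tabs$syms) dd[[paste0("recoil_", s)]] <- rec_bin_elem[, s] / norm

  events <- if (ev_k > 0) {
    data.frame(depth_mm = unlist(ev_depth), element = unlist(ev_elem),
               T_eV = unlist(ev_T), stringsAsFactors = FALSE)
  } else {
    data.frame(depth_mm = numeric(0), element = character(0),
               T_eV = numeric(0), stringsAsFactors = FALSE)
  }

  audit <- list(
    beam_eV = N * beam$energy * 1e6,
    ionization_eV = sum(ionization),
    recoil_eV = sum(rec_bin_layer) + sum(rec_bin_disc),
    transmitted_eV = sum(exit_E, na.rm = TRUE) * 1e6
  )
  audit$discrepancy <- abs(audit$beam_eV - audit$ionization_eV -
                             audit$recoil_eV - audit$transmitted_eV) /
    audit$beam_eV

  structure(list(
    depth_dose = dd,
    tracks = data.frame(ion_id = seq_len(N), x_mm = x, y_mm = y, z_mm = z,
                        stopped = stopped,
                        exit_energy_MeV = exit_E,
                        recoil_eV = recoil_ion),
    recoil_events = events,
    recoil_continuum = stats::setNames(as.numeric(cont_elem), tabs$syms),
    energy_audit = audit,
    provenance = list(seed = beam$seed, energy_MeV = beam$energy,
                      n_ions = N, phantom = phantom$name,
                      phantom_hash = phantom_hash(phantom),
                      total_depth_mm = depth,
                      config = unclass(config),
                      package = as.character(utils::packageVersion("ionphantom")))
  ), class = "ip_simulation")
}

#' @export
print.ip_simulation <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<ip_simulation> %s, %g MeV, %d ions (seed %d)\n",
              p$phantom, p$energy_MeV, p$n_ions, p$seed))
  cat(sprintf("  stopped %d / transmitted %d; energy audit discrepancy %.3g%%\n",
              sum(x$tracks$stopped), sum(!x$tracks$stopped),
              100 * x$energy_audit$discrepancy))
  invisible(x)
}

#' Default therapy-energy scan
#'
#' @return The 12-point scan 354, 356, ..., 376 MeV.
#' @export
default_energy_scan <- function() seq(354, 376, by = 2)

#' Run a simulation per beam energy
#'
#' Repeats [run_simulation()] over an energy list with per-energy seeds
#' derived deterministically from the master seed (`seed + 1000 * (i - 1)`,
#' kept below 2^31), so a single-energy scan is identical to a direct
#' [run_simulation()] call.
#'
#' @param energies Energies in MeV (default [default_energy_scan()]).
#' @param phantom An `ip_phantom`.
#' @param beam Template [beam_spec()]; its energy is replaced per scan
#'   point.
#' @param config An [transport_config()].
#' @return Object of class `ip_scan`: a list of `ip_simulation`s named by
#'   energy.
#' @export
energy_scan <- function(energies = default_energy_scan(), phantom,
                        beam = beam_spec(energies[1]),
                        config = transport_config()) {
  if (length(energies) == 0) stop("energy list must be non-empty")
  .check_energy_window(energies)
  sims <- lapply(seq_along(energies), function(i) {
    seed_i <- (beam$seed + 1000 * (i - 1)) %% 2147483647
    run_simulation(beam_spec(energies[i], n_ions = beam$n_ions,
                             seed = seed_i), phantom, config)
  })
  names(sims) <- as.character(energies)
  structure(sims, class = "ip_scan", energies = energies)
}
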