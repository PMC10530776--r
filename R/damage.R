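# Displacement-damage models: Kinchin-Pease closed form, its stochastic
# hard-sphere cascade oracle, the NRT model, and per-element recoil tallies.

#' Kinchin-Pease model parameters
#'
#' @param E_d Threshold displacement energy in eV (default 25 eV).
#' @param E_c Electronic-stopping cutoff energy in eV. If `element` is
#'   given and `E_c` is `NULL`, the cutoff is computed once per element via
#'   [recoil_cutoff_energy()] and cached.
#' @param element Optional chemical symbol used to derive `E_c`.
#' @return Object of class `ip_kp_model` with fields `E_d` and `E_c`.
#' @examples
#' kp_model(25, 30000)
#' kp_model(element = "O")
#' @export
kp_model <- function(E_d = 25, E_c = NULL, element = NULL) {
  if (is.null(E_c)) {
    if (is.null(element))
      stop("either E_c or element must be supplied")
    E_c <- recoil_cutoff_energy(element)
  }
  if (!(is.finite(E_d) && is.finite(E_c) && E_d > 0 && E_c > E_d))
    stop("require 0 < E_d < E_c (got E_d = ", E_d, ", E_c = ", E_c, ")")
  structure(list(E_d = E_d, E_c = E_c), class = "ip_kp_model")
}

#' Kinchin-Pease displacement count
#'
#' The closed-form expected number of displaced atoms produced by a primary
#' knock-on atom (PKA) of energy `T`: 0 below the displacement threshold
#' `E_d`, exactly 1 between `E_d` and `2 E_d`, `T / (2 E_d)` up to the
#' electronic cutoff `E_c`, and saturated at `E_c / (2 E_d)` above it.
#'
#' @param T PKA energy in eV (vectorized).
#' @param model An [kp_model()].
#' @return Expected displacement count, same length as `T`.
#' @examples
#' m <- kp_model(25, 30000)
#' kp_displacements(c(10, 30, 10000, 1e5), m)
#' @export
kp_displacements <- function(T, model) {
  stopifnot(inherits(model, "ip_kp_model"))
  if (any(!is.finite(T)) || any(T < 0))
    stop("PKA energy T must be non-negative")
  E_d <- model$E_d
  E_c <- model$E_c
  out <- numeric(length(T))
  out[T >= E_d & T < 2 * E_d] <- 1
  mid <- T >= 2 * E_d & T < E_c
  out[mid] <- T[mid] / (2 * E_d)
  out[T >= E_c] <- E_c / (2 * E_d)
  out
}

#' NRT model parameters
#'
#' @param E_d Threshold displacement energy in eV (default 25 eV).
#' @param efficiency Displacement efficiency factor (default 0.8).
#' @return Object of class `ip_nrt_model`.
#' @export
nrt_model <- function(E_d = 25, efficiency = 0.8) {
  stopifnot(is.finite(E_d), E_d > 0, is.finite(efficiency), efficiency > 0)
  structure(list(E_d = E_d, efficiency = efficiency),
            class = "ip_nrt_model")
}

#' NRT displacement count
#'
#' Norgett-Robinson-Torrens refinement of the Kinchin-Pease count: 0 below
#' `E_d`, 1 between `E_d` and `2.5 E_d`, and
#' `efficiency * E_v / (2 E_d)` at and above `2.5 E_d` (continuous at the
#' band edge for the standard efficiency of 0.8).
#'
#' @param E_v Damage energy in eV (vectorized).
#' @param model An [nrt_model()].
#' @return Displacement count, same length as `E_v`.
#' @export
nrt_displacements <- function(E_v, model) {
  stopifnot(inherits(model, "ip_nrt_model"))
  if (any(!is.finite(E_v)) || any(E_v < 0))
    stop("damage energy E_v must be non-negative")
  E_d <- model$E_d
  out <- numeric(length(E_v))
  out[E_v >= E_d & E_v < 2.5 * E_d] <- 1
  hi <- E_v >= 2.5 * E_d
  out[hi] <- model$efficiency * E_v[hi] / (2 * E_d)
  out
}

#' Stochastic hard-sphere cascade oracle
#'
#' Direct simulation of the binary collision cascade underlying the
#' Kinchin-Pease closed form: each moving atom of energy `W >= 2 E_d`
#' splits its energy uniformly with a struck atom (`eps ~ U(0, W)`,
#' hard-sphere like-atom collision), atoms with `E_d <= W < 2 E_d` count as
#' one displacement, atoms below `E_d` are absorbed. The trial mean
#' converges to `T / (2 E_d)` for `2 E_d <= T < E_c`. Intended as a
#' test-time oracle, not a production tally.
#'
#' @param T PKA energy in eV (scalar).
#' @param E_d Threshold displacement energy in eV.
#' @param n_trials Number of independent cascades to average.
#' @param seed RNG seed.
#' @return Mean displacement count over trials, with the per-trial counts
#'   attached as attribute `"trials"`.
#' @examples
#' cascade_oracle(2500, 25, n_trials = 2000, seed = 1)
#' @export
cascade_oracle <- function(T, E_d, n_trials = 1e4, seed = 1) {
  stopifnot(length(T) == 1, is.finite(T), T > 0, E_d > 0, n_trials >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  counts <- integer(n_trials)
  w <- rep(T, n_trials)
  id <- seq_len(n_trials)
  repeat {
    done <- w < 2 * E_d
    if (any(done)) {
      displaced <- done & (w >= E_d)
      if (any(displaced))
        counts <- counts + tabulate(id[displaced], nbins = n_trials)
      w <- w[!done]
      id <- id[!done]
    }
    if (length(w) == 0) break
    eps <- stats::runif(length(w)) * w
    w <- c(w - eps, eps)
    id <- c(id, id)
  }
  structure(mean(counts), trials = counts)
}

#' Tally recoil events into a per-element summary
#'
#' Aggregates primary-recoil events into the total recoil energy density
#' (eV per Angstrom per ion), the percentage contribution of each element
#' to the total recoil energy, and Kinchin-Pease displacement sums.
#'
#' @param events Data frame with columns `depth_mm`, `element`, `T_eV`
#'   (one row per recoil event); may have zero rows.
#' @param path_length_A Tally path length in Angstrom (> 0), typically the
#'   phantom depth.
#' @param n_ions Number of beam ions the events came from (>= 1).
#' @param kp A single [kp_model()] applied to every element, or a named
#'   list of models keyed by element symbol.
#' @return Object of class `ip_recoil_tally`: `total_recoil`
#'   (eV/(Angstrom ion)), `contribution_pct` (named, sums to 100 when the
#'   total is positive), `displacements` (named Kinchin-Pease sums) and
#'   `energy_eV` (named recoil energy sums).
#' @examples
#' ev <- data.frame(depth_mm = c(1, 2), element = c("H", "O"),
#'                  T_eV = c(75, 25))
#' tally_recoils(ev, path_length_A = 1e8, n_ions = 10, kp = kp_model(25, 3e4))
#' @export
tally_recoils <- function(events, path_length_A, n_ions, kp) {
  stopifnot(is.finite(path_length_A), path_length_A > 0, n_ions >= 1)
  if (is.null(events) || nrow(events) == 0) {
    return(structure(list(total_recoil = 0,
                          contribution_pct = numeric(0),
                          displacements = numeric(0),
                          energy_eV = numeric(0)),
                     class = "ip_recoil_tally"))
  }
  stopifnot(all(c("element", "T_eV") %in% names(events)))
  if (any(events$T_eV < 0)) stop("recoil energies must be non-negative")
  e_sum <- tapply(events$T_eV, events$element, sum)
  e_sum <- e_sum[order(match(names(e_sum), .element_table$symbol))]
  total <- sum(e_sum)
  kp_for <- function(sym) {
    if (inherits(kp, "ip_kp_model")) kp
    else if (is.list(kp) && !is.null(kp[[sym]])) kp[[sym]]
    else stop("no Kinchin-Pease model supplied for element ", sym)
  }
  disp <- vapply(names(e_sum), function(sym) {
    sel <- events$element == sym
    sum(kp_displacements(events$T_eV[sel], kp_for(sym)))
  }, numeric(1))
  structure(list(
    total_recoil = total / (path_length_A * n_ions),
    contribution_pct = stats::setNames(100 * as.numeric(e_sum) / total,
                                       names(e_sum)),
    displacements = disp,
    energy_eV = stats::setNames(as.numeric(e_sum), names(e_sum))
  ), class = "ip_recoil_tally")
}

#' @export
print.ip_recoil_tally <- function(x, ...) {
  cat(sprintf("<ip_recoil_tally> total %.4g eV/(Angstrom ion)\n",
              x$total_recoil))
  if (length(x$contribution_pct)) {
    cat("  contributions (%):\n")
    print(round(x$contribution_pct, 2))
  }
  invisible(x)
}

# Expected Kinchin-Pease displacements per unit recoil energy for the
# sub-split recoil continuum: with a 1/T^2 transfer spectrum restricted to
# [thr, split], the ratio of E[nu(T)] to E[T] is energy-independent.
# Used to convert continuum energy tallies into displacement counts.
.kp_continuum_ratio <- function(E_d, thr, split) {
  stopifnot(split > thr, thr > 0)
  lo1 <- max(thr, E_d); hi1 <- min(split, 2 * E_d)
  num <- 0
  if (hi1 > lo1) num <- num + (1 / lo1 - 1 / hi1)            # nu = 1 band
  lo2 <- max(thr, 2 * E_d)
  if (split > lo2) num <- num + log(split / lo2) / (2 * E_d) # nu = T/2Ed
  den <- log(split / thr)                                    # E[T] factor
  num / den
}
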