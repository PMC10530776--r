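# Materials, layers and phantoms: compound compositions, densities and
# ordered slab geometry.

AMU_G <- 1.66053907e-24  # atomic mass unit in grams

#' Define a compound material
#'
#' A material is a set of elements with relative atomic fractions plus two
#' densities: the tabulated atomic density (in the customary unit of
#' 10^22 atoms/cm^3) and the mass density (g/cm^3). Fractions are
#' renormalized to sum to one; they may be entered as percentages.
#'
#' The two densities are stored independently because published phantom
#' tables sometimes carry mutually inconsistent values (see
#' [number_densities()] for how the package resolves this for the physics).
#'
#' @param name Label for the material.
#' @param symbols Character vector of element symbols.
#' @param fractions Numeric vector of atomic fractions (or percentages);
#'   renormalized to sum to 1.
#' @param atomic_density Atomic density in 10^22 atoms/cm^3. May be `NA`,
#'   in which case it is derived from `mass_density` and the composition.
#' @param mass_density Mass density in g/cm^3.
#' @return An object of class `ip_material`.
#' @examples
#' water <- material("water", c("H", "O"), c(2, 1),
#'                   atomic_density = 10.02, mass_density = 1.0)
#' @export
material <- function(name, symbols, fractions, atomic_density = NA_real_,
                     mass_density) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(symbols) != length(fractions))
    stop("symbols and fractions must have the same length")
  if (length(symbols) == 0)
    stop("a material needs at least one element")
  if (any(!is.finite(fractions)) || any(fractions < 0))
    stop("element fractions must be finite and non-negative")
  s <- sum(fractions)
  if (s <= 0)
    stop("element fractions are all zero in material '", name, "'")
  info <- element_info(symbols)
  if (anyDuplicated(symbols))
    stop("duplicated element symbol in material '", name, "'")
  if (!is.finite(mass_density) || mass_density <= 0)
    stop("mass_density must be > 0 (got ", mass_density, ")")
  frac <- fractions / s
  mean_A <- sum(frac * info$A)
  if (is.na(atomic_density)) {
    atomic_density <- mass_density / (mean_A * AMU_G) / 1e22
  }
  if (!is.finite(atomic_density) || atomic_density <= 0)
    stop("atomic_density must be > 0 (got ", atomic_density, ")")
  structure(list(
    name = name,
    elements = data.frame(symbol = info$symbol, Z = info$Z, A = info$A,
                          I_eV = info$I_eV, fraction = frac,
                          stringsAsFactors = FALSE),
    atomic_density = atomic_density,  # 10^22 atoms/cm^3
    mass_density = mass_density       # g/cm^3
  ), class = "ip_material")
}

#' @export
print.ip_material <- function(x, ...) {
  cat("<ip_material> ", x$name, "\n", sep = "")
  cat(sprintf("  atomic density %.4g x10^22 atoms/cm^3, mass density %.4g g/cm^3\n",
              x$atomic_density, x$mass_density))
  comp <- paste(sprintf("%s %.3f", x$elements$symbol, x$elements$fraction),
                collapse = ", ")
  cat("  atomic fractions:", comp, "\n")
  invisible(x)
}

#' Per-element number densities of a material
#'
#' Splits a material's total number density into per-element densities
#' (atoms/cm^3). Two bases are available:
#'
#' * `"atomic"`: the tabulated atomic density times the normalized atomic
#'   fraction (the printed-table reading; the per-element values sum to the
#'   tabulated atomic density).
#' * `"mass"`: the total number density is re-derived from the mass density
#'   and the mean atomic mass, then split by atomic fraction. This is the
#'   basis used by the transport physics, because for some published tissue
#'   rows the tabulated composition and atomic density jointly imply
#'   impossible electron densities (Z/A > 1), while the mass density is
#'   always physically usable.
#'
#' @param material An [material()] object.
#' @param basis `"atomic"` (default) or `"mass"`.
#' @return Named numeric vector of atoms/cm^3 per element.
#' @export
number_densities <- function(material, basis = c("atomic", "mass")) {
  stopifnot(inherits(material, "ip_material"))
  basis <- match.arg(basis)
  el <- material$elements
  n_tot <- switch(basis,
    atomic = material$atomic_density * 1e22,
    mass = material$mass_density / (sum(el$fraction * el$A) * AMU_G)
  )
  stats::setNames(n_tot * el$fraction, el$symbol)
}

#' Create a phantom layer
#'
#' @param material An [material()] object.
#' @param thickness_mm Slab thickness in mm (> 0).
#' @return An object of class `ip_layer`.
#' @export
phantom_layer <- function(material, thickness_mm) {
  stopifnot(inherits(material, "ip_material"))
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    stop("layer thickness must be > 0 mm (got ", thickness_mm, ")")
  structure(list(material = material, thickness_mm = thickness_mm),
            class = "ip_layer")
}

#' Assemble a plane-parallel phantom
#'
#' Layers are ordered from the beam entry surface inward; the beam travels
#' along +x from depth 0.
#'
#' @param name Label for the phantom.
#' @param layers List of [phantom_layer()] objects (entry surface first).
#' @return An object of class `ip_phantom` with derived `total_depth` (mm).
#' @export
phantom <- function(name, layers) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.list(layers) || length(layers) == 0)
    stop("a phantom needs at least one layer (empty layer list)")
  ok <- vapply(layers, inherits, logical(1), what = "ip_layer")
  if (!all(ok)) stop("all layers must be ip_layer objects")
  thick <- vapply(layers, function(l) l$thickness_mm, numeric(1))
  structure(list(
    name = name,
    layers = layers,
    total_depth = sum(thick)
  ), class = "ip_phantom")
}

#' @export
print.ip_phantom <- function(x, ...) {
  cat("<ip_phantom> ", x$name, ": ", length(x$layers), " layers, ",
      sprintf("%.3g", x$total_depth), " mm total depth\n", sep = "")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Tabulate a phantom's layers
#'
#' @param x An `ip_phantom`.
#' @param ... Unused.
#' @return Data frame with one row per layer: index, material name,
#'   thickness, densities and a composition string.
#' @export
as.data.frame.ip_phantom <- function(x, ...) {
  data.frame(
    index = seq_along(x$layers),
    name = vapply(x$layers, function(l) l$material$name, character(1)),
    thickness_mm = vapply(x$layers, function(l) l$thickness_mm, numeric(1)),
    mass_density = vapply(x$layers, function(l) l$material$mass_density,
                          numeric(1)),
    atomic_density_1e22 = vapply(x$layers,
                                 function(l) l$material$atomic_density,
                                 numeric(1)),
    composition = vapply(x$layers, function(l) {
      el <- l$material$elements
      paste(sprintf("%s:%.4g", el$symbol, 100 * el$fraction), collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

# Elements present anywhere in a phantom, in table order.
phantom_elements <- function(phantom) {
  syms <- unique(unlist(lapply(phantom$layers,
                               function(l) l$material$elements$symbol)))
  syms[order(match(syms, .element_table$symbol))]
}

# Cheap deterministic fingerprint of the numeric content of a phantom,
# recorded in output provenance headers.
phantom_hash <- function(phantom) {
  txt <- paste(
    phantom$name,
    paste(vapply(phantom$layers, function(l) {
      el <- l$material$elements
      paste(l$material$name, l$thickness_mm, l$material$atomic_density,
            l$material$mass_density,
            paste(el$symbol, signif(el$fraction, 12), collapse = ","))
    }, character(1)), collapse = ";"),
    sep = "|")
  ints <- utf8ToInt(txt)
  h <- 0
  for (i in ints) h <- (h * 31 + i) %% 2147483647
  sprintf("%08x", h)
}
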