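# Elemental constants used throughout the package.
#
# A: standard atomic weight of the natural isotopic mixture (amu).
# I_eV: mean excitation energy for the Bethe formula (ICRU-style elemental
#   values; compounds are handled by Bragg additivity over elements).
# The table covers every element appearing in the shipped mandible fixtures.
.element_table <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "Na", "Mg", "P", "S", "Cl",
             "K", "Ca", "Fe"),
  Z = c(1L, 6L, 7L, 8L, 9L, 11L, 12L, 15L, 16L, 17L, 19L, 20L, 26L),
  A = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305, 30.974,
        32.06, 35.45, 39.098, 40.078, 55.845),
  I_eV = c(19.2, 78.0, 82.0, 95.0, 115.0, 149.0, 156.0, 173.0, 180.0,
           174.0, 190.0, 191.0, 286.0),
  stringsAsFactors = FALSE
)

#' Look up elemental constants
#'
#' Returns atomic number, standard atomic weight and mean excitation energy
#' for one or more chemical symbols.
#'
#' @param symbols Character vector of chemical symbols (e.g. `c("H", "O")`).
#' @return A data frame with columns `symbol`, `Z`, `A` (amu) and `I_eV`.
#' @examples
#' element_info(c("H", "Ca"))
#' @export
element_info <- function(symbols) {
  stopifnot(is.character(symbols), length(symbols) >= 1)
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    bad <- symbols[is.na(idx)]
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         ". Known symbols: ", paste(.element_table$symbol, collapse = ", "))
  }
  out <- .element_table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Radiation length of a pure element, Tsai/PDG approximation (g/cm^2).
.element_x0 <- function(Z, A) {
  716.408 * A / (Z * (Z + 1) * log(287 / sqrt(Z)))
}
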