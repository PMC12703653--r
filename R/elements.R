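# Element property tables used throughout: covalent radii for bond-length
# sanity checks and embedding, van der Waals radii for clash pruning, and
# atomic masses for inertia tensors. Values are the usual consensus numbers
# (Cordero covalent radii, Bondi vdW radii, IUPAC standard weights).

.ELEMENTS <- local({
  df <- data.frame(
    symbol = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
    covalent = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02, 1.20, 1.39),
    vdw = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
    mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 30.974, 32.06, 35.45, 79.904, 126.904),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$symbol
  df
})

.elem_lookup <- function(symbols, what, default) {
  sym <- normalize_element(symbols)
  out <- .ELEMENTS[sym, what]
  out[is.na(out)] <- default
  out
}

#' @importFrom stats setNames
NULL

#' Normalize element symbols to canonical capitalisation
#' @param symbols character vector of element symbols (any case)
#' @return character vector ("C", "Cl", ...)
#' @keywords internal
normalize_element <- function(symbols) {
  s <- tolower(trimws(as.character(symbols)))
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

covalent_radius <- function(symbols) .elem_lookup(symbols, "covalent", 0.77)
vdw_radius <- function(symbols) .elem_lookup(symbols, "vdw", 1.70)
atomic_mass <- function(symbols) .elem_lookup(symbols, "mass", 12.0)
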