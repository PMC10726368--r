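#' Element reference data
#'
#' Per-species constants used throughout the pipeline: the period (principal
#' quantum number of the valence shell), the covalent radius entering the
#' Pauling bond order and the core-valence bond-length correction, and the
#' mass of the most abundant isotope for the inertia tensor.
#'
#' Covalent radii are the Cordero et al. (2008) values, with the generic
#' carbon radius (0.76 A); masses are most-abundant-isotope masses
#' (1H, 12C, 14N, 16O, 32S) so that computed rotational constants refer to
#' the parent isotopologue. Both can be overridden per call in the functions
#' that consume them, but the defaults are pinned: the one-parameter
#' correction formula is method-independent only through a fixed radii set.
#'
#' @param radii Optional named numeric vector of covalent radii (A) that
#'   overrides the defaults for the named symbols, e.g.
#'   `c(C = 0.73)` to use the sp2 carbon radius.
#' @return A tibble with one row per supported element and columns
#'   `symbol`, `atomic_number`, `principal_quantum_number`,
#'   `covalent_radius` (A) and `mass` (amu).
#' @examples
#' element_data()
#' element_data(radii = c(C = 0.73))
#' @export
element_data <- function(radii = NULL) {
  tbl <- tibble::tibble(
    symbol = c("H", "C", "N", "O", "S"),
    atomic_number = c(1L, 6L, 7L, 8L, 16L),
    principal_quantum_number = c(1L, 2L, 2L, 2L, 3L),
    covalent_radius = c(0.31, 0.76, 0.71, 0.66, 1.05),
    mass = c(1.00782503207, 12.0, 14.0030740048, 15.9949146196, 31.97207100)
  )
  if (!is.null(radii)) {
    if (is.null(names(radii)) || any(!nzchar(names(radii)))) {
      stop("`radii` must be a named vector of element symbols", call. = FALSE)
    }
    unknown <- setdiff(names(radii), tbl$symbol)
    if (length(unknown) > 0) {
      stop("unsupported element(s) in `radii`: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    idx <- match(names(radii), tbl$symbol)
    tbl$covalent_radius[idx] <- unname(radii)
  }
  tbl
}

#' Look up one element
#'
#' Case-normalizes the symbol and returns its reference record. Lookup is
#' total for the supported set (H, C, N, O, S) and fails loudly otherwise:
#' a silent fallback radius would corrupt both bond perception and the
#' bond-length corrections.
#'
#' @param symbol Chemical symbol, any case (`"c"`, `"C"`).
#' @inheritParams element_data
#' @return A one-row tibble (see [element_data()]).
#' @examples
#' lookup_element("C")$covalent_radius
#' @export
lookup_element <- function(symbol, radii = NULL) {
  stopifnot(length(symbol) == 1L)
  tbl <- element_data(radii)
  sym <- normalize_symbol(symbol)
  row <- tbl[tbl$symbol == sym, ]
  if (nrow(row) == 0L) {
    stop("unsupported element symbol: '", symbol, "' (supported: ",
         paste(tbl$symbol, collapse = ", "), ")", call. = FALSE)
  }
  row
}

# "c" -> "C", "cl" -> "Cl"
normalize_symbol <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

# Vectorized property access for internal use; errors on the first
# unsupported symbol it meets.
element_property <- function(symbols, property, radii = NULL) {
  tbl <- element_data(radii)
  syms <- vapply(symbols, normalize_symbol, character(1), USE.NAMES = FALSE)
  idx <- match(syms, tbl$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unsupported element symbol: '", bad[[1]], "'", call. = FALSE)
  }
  tbl[[property]][idx]
}
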