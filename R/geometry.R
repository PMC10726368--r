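#' Construct a molecular geometry
#'
#' A geometry is an ordered tibble of atoms with Cartesian coordinates in
#' Angstrom: columns `element`, `x`, `y`, `z`. Atom order is meaningful
#' (bonds and internal coordinates refer to row indices), so every function
#' in the package preserves it.
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Numeric coordinate vectors (A).
#' @param label Free-text label carried through as the XYZ comment line.
#' @param degenerate Set `TRUE` to skip the coincident-atom check (only
#'   useful for deliberately pathological test inputs).
#' @return A tibble of class `molecular_geometry`.
#' @examples
#' geometry(c("O", "H", "H"),
#'          x = c(0, 0.7586, -0.7586),
#'          y = c(0.3930, -0.1965, -0.1965),
#'          z = c(0, 0, 0), label = "water")
#' @export
geometry <- function(element, x, y, z, label = "", degenerate = FALSE) {
  g <- tibble::tibble(element = as.character(element),
                      x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  validate_geometry(g, degenerate = degenerate)
  attr(g, "label") <- as.character(label)[1]
  class(g) <- c("molecular_geometry", class(g))
  g
}

#' Coerce a data frame to a molecular geometry
#'
#' @param data A data frame with columns `element`, `x`, `y`, `z`.
#' @inheritParams geometry
#' @return A `molecular_geometry` tibble.
#' @export
as_geometry <- function(data, label = geometry_label(data), degenerate = FALSE) {
  need <- c("element", "x", "y", "z")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("geometry data frame lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  geometry(data$element, data$x, data$y, data$z,
           label = if (is.null(label)) "" else label, degenerate = degenerate)
}

validate_geometry <- function(g, degenerate = FALSE) {
  if (nrow(g) > 0 && !all(is.finite(c(g$x, g$y, g$z)))) {
    stop("geometry contains non-finite coordinates", call. = FALSE)
  }
  element_property(g$element, "symbol")  # errors on unknown symbols
  if (!degenerate && nrow(g) > 1) {
    d <- as.matrix(stats::dist(coords_matrix(g)))
    diag(d) <- Inf
    if (any(d <= 0.1)) {
      pair <- which(d <= 0.1, arr.ind = TRUE)[1, ]
      stop("atoms ", pair[1], " and ", pair[2],
           " are closer than 0.1 A; flag `degenerate = TRUE` if intended",
           call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.molecular_geometry <- function(x, ...) {
  lab <- geometry_label(x)
  cat("# molecular geometry: ", nrow(x), " atom(s)",
      if (nzchar(lab)) paste0(" -- ", lab), "\n", sep = "")
  NextMethod()
}

geometry_label <- function(g) {
  lab <- attr(g, "label", exact = TRUE)
  if (is.null(lab)) "" else lab
}

# n x 3 coordinate matrix
coords_matrix <- function(g) {
  cbind(x = g$x, y = g$y, z = g$z)
}

# Rebuild a geometry from a coordinate matrix, keeping elements and label.
set_coords <- function(g, xyz) {
  g$x <- xyz[, 1]
  g$y <- xyz[, 2]
  g$z <- xyz[, 3]
  g
}
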