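#' Pauling bond order
#'
#' The bond order of an atom pair is an exponential function of how much
#' the interatomic distance falls short of the covalent-radius sum:
#' \deqn{P_{ij} = \exp[(r_i^{cov} + r_j^{cov} - r_{ij}) / b]}
#' with the decay constant b = 0.3 A. P = 1 at the covalent-radius sum and
#' P = 0.3 (the bonding threshold) about 0.35 A beyond it; orders near 1, 2
#' and 3 correspond to single, double and triple bonds.
#'
#' @param r_ij Interatomic distance(s), A. Must be positive.
#' @param el_i,el_j Element symbols (vectorized).
#' @param decay Exponential decay constant b, A.
#' @param radii Optional covalent-radius overrides, see [element_data()].
#' @return Numeric bond order(s), strictly positive and strictly
#'   decreasing in `r_ij`.
#' @examples
#' pauling_bond_order(1.52, "C", "C")  # ~1: single bond
#' pauling_bond_order(1.34, "C", "C")  # ~1.8: double-bond region
#' @export
pauling_bond_order <- function(r_ij, el_i, el_j, decay = 0.3, radii = NULL) {
  if (any(!is.finite(r_ij)) || any(r_ij <= 0)) {
    stop("interatomic distance must be positive and finite", call. = FALSE)
  }
  rsum <- element_property(el_i, "covalent_radius", radii) +
    element_property(el_j, "covalent_radius", radii)
  exp((rsum - r_ij) / decay)
}

#' Perceive bonds from a geometry
#'
#' All unordered atom pairs whose Pauling bond order exceeds the threshold
#' (default 0.3) are bonded. The perception is purely geometric: it is
#' exactly invariant under rigid rotation/translation and, up to index
#' relabeling, under atom reordering. Nonbonded close contacts (e.g.
#' H...H pairs around 1.8 A) fall below the threshold naturally.
#'
#' A connectivity override can force or forbid specific pairs, mirroring
#' a whitespace-separated "i j" pair file (1-based indices).
#'
#' @param geom A [geometry()].
#' @param threshold Minimum Pauling order for a pair to count as bonded.
#' @param force,forbid Optional two-column matrices/data frames of 1-based
#'   atom index pairs to add to / remove from the perceived set.
#' @inheritParams pauling_bond_order
#' @return A tibble of bonds with columns `i`, `j` (i < j), `length` (A)
#'   and `order` (Pauling bond order); zero rows if nothing is bonded.
#' @export
perceive_bonds <- function(geom, threshold = 0.3, decay = 0.3, radii = NULL,
                           force = NULL, forbid = NULL) {
  geom <- as_geometry(geom)
  n <- nrow(geom)
  if (n < 1) stop("geometry must contain at least one atom", call. = FALSE)
  empty <- tibble::tibble(i = integer(), j = integer(),
                          length = numeric(), order = numeric())
  if (n == 1) return(apply_overrides(empty, geom, force, forbid, decay, radii))
  pairs <- utils::combn(n, 2)
  xyz <- coords_matrix(geom)
  d <- sqrt(rowSums((xyz[pairs[1, ], , drop = FALSE] -
                       xyz[pairs[2, ], , drop = FALSE])^2))
  p <- pauling_bond_order(d, geom$element[pairs[1, ]], geom$element[pairs[2, ]],
                          decay = decay, radii = radii)
  keep <- p > threshold
  bonds <- tibble::tibble(i = pairs[1, keep], j = pairs[2, keep],
                          length = d[keep], order = p[keep])
  apply_overrides(bonds, geom, force, forbid, decay, radii)
}

apply_overrides <- function(bonds, geom, force, forbid, decay, radii) {
  canon <- function(m) {
    m <- as.matrix(m)[, 1:2, drop = FALSE]
    cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  }
  if (!is.null(forbid) && nrow(as.matrix(forbid)) > 0 && nrow(bonds) > 0) {
    f <- canon(forbid)
    drop <- paste(bonds$i, bonds$j) %in% paste(f[, 1], f[, 2])
    bonds <- bonds[!drop, ]
  }
  if (!is.null(force) && nrow(as.matrix(force)) > 0) {
    f <- canon(force)
    xyz <- coords_matrix(geom)
    new <- !(paste(f[, 1], f[, 2]) %in% paste(bonds$i, bonds$j))
    for (r in which(new)) {
      i <- f[r, 1]; j <- f[r, 2]
      len <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      bonds <- dplyr::bind_rows(bonds, tibble::tibble(
        i = as.integer(i), j = as.integer(j), length = len,
        order = pauling_bond_order(len, geom$element[i], geom$element[j],
                                   decay = decay, radii = radii)))
    }
  }
  dplyr::arrange(bonds, .data$i, .data$j)
}

#' Build the redundant internal-coordinate set
#'
#' From a bond list, generates every valence angle defined by a pair of
#' bonds sharing a central atom, and evaluates all current values from the
#' geometry. The set is redundant by construction (e.g. all six ring bonds
#' plus all ring angles of benzene) -- deliberately so, since nonredundant
#' Z-matrix coordinates handle rings poorly. Dihedrals are not included:
#' the refit penalty constrains bonds and angles only, leaving torsions
#' free to relax.
#'
#' Near-linear angles (> 179.9 deg) are flagged in the `near_linear`
#' column but retained.
#'
#' @param geom A [geometry()].
#' @param bonds Bond tibble from [perceive_bonds()]; perceived from `geom`
#'   if omitted.
#' @return An object of class `internal_coords`: a list with tibbles
#'   `bonds` (`i`, `j`, `length`, `order`) and `angles`
#'   (`i`, `j`, `k`, `value` in degrees, `near_linear`), where `j` is the
#'   central atom.
#' @export
build_internals <- function(geom, bonds = NULL) {
  geom <- as_geometry(geom)
  if (is.null(bonds)) bonds <- perceive_bonds(geom)
  xyz <- coords_matrix(geom)
  angles <- tibble::tibble(i = integer(), j = integer(), k = integer(),
                           value = numeric(), near_linear = logical())
  if (nrow(bonds) > 1) {
    rows <- list()
    for (centre in sort(unique(c(bonds$i, bonds$j)))) {
      nb <- sort(c(bonds$j[bonds$i == centre], bonds$i[bonds$j == centre]))
      if (length(nb) < 2) next
      prs <- utils::combn(nb, 2)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        i = prs[1, ], j = centre, k = prs[2, ])
    }
    if (length(rows) > 0) {
      angles <- dplyr::bind_rows(rows)
      angles$value <- vapply(seq_len(nrow(angles)), function(r) {
        angle_value(xyz, angles$i[r], angles$j[r], angles$k[r])
      }, numeric(1))
      angles$near_linear <- angles$value > 179.9
    }
  }
  structure(list(bonds = bonds, angles = angles, n_atoms = nrow(geom)),
            class = "internal_coords")
}

#' @export
print.internal_coords <- function(x, ...) {
  cat("# redundant internal coordinates: ", nrow(x$bonds), " bond(s), ",
      nrow(x$angles), " angle(s) over ", x$n_atoms, " atom(s)\n", sep = "")
  invisible(x)
}

# Angle i-j-k (j central) in degrees.
angle_value <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]
  v <- xyz[k, ] - xyz[j, ]
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Cartesian derivatives of an internal coordinate
#'
#' Wilson-formula derivatives of one bond length or valence angle with
#' respect to every atomic Cartesian coordinate (a row of the Wilson
#' B-matrix, reshaped to per-atom 3-vectors). Bond derivatives are unit
#' vectors along the bond; angle derivatives follow the standard
#' bend formulas and are returned in degrees per Angstrom by default, the
#' same angular unit the refit penalty uses.
#'
#' The derivative vectors over all atoms sum to zero (translation
#' invariance); atoms not participating in the coordinate get zero rows.
#'
#' @param geom A [geometry()].
#' @param coordinate A one-row slice of the `bonds` or `angles` tibble of
#'   [build_internals()] (any list/data frame with fields `i`, `j` and,
#'   for an angle, `k`).
#' @param angle_unit `"degrees"` (default) or `"radians"` for angle
#'   derivatives.
#' @return An n x 3 numeric matrix of per-atom derivative vectors.
#' @export
internal_derivatives <- function(geom, coordinate, angle_unit = c("degrees", "radians")) {
  angle_unit <- match.arg(angle_unit)
  geom <- as_geometry(geom, degenerate = TRUE)
  xyz <- coords_matrix(geom)
  out <- matrix(0, nrow(geom), 3)
  i <- coordinate$i[1]
  j <- coordinate$j[1]
  has_k <- "k" %in% names(coordinate) && length(coordinate$k) > 0 &&
    !is.na(coordinate$k[1])
  if (!has_k) {
    v <- xyz[j, ] - xyz[i, ]
    r <- sqrt(sum(v^2))
    if (r == 0) stop("coincident atoms in bond coordinate", call. = FALSE)
    u <- v / r
    out[j, ] <- u
    out[i, ] <- -u
  } else {
    k <- coordinate$k[1]
    d <- angle_derivative(xyz, i, j, k)
    scale <- if (angle_unit == "degrees") 180 / pi else 1
    out[i, ] <- d$di * scale
    out[j, ] <- d$dj * scale
    out[k, ] <- d$dk * scale
  }
  out
}

# Wilson bend derivatives (radians per Angstrom) for angle i-j-k, j central.
angle_derivative <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]
  v <- xyz[k, ] - xyz[j, ]
  ru <- sqrt(sum(u^2))
  rv <- sqrt(sum(v^2))
  u <- u / ru
  v <- v / rv
  cosang <- max(-1, min(1, sum(u * v)))
  sinang <- sqrt(1 - cosang^2)
  if (sinang < 1e-10) {
    stop("degenerate internal coordinate: angle ", i, "-", j, "-", k,
         " is collinear", call. = FALSE)
  }
  di <- (cosang * u - v) / (ru * sinang)
  dk <- (cosang * v - u) / (rv * sinang)
  list(di = di, dj = -(di + dk), dk = dk)
}
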