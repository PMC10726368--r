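# Conversion constant B [MHz] = KAPPA / I [amu A^2]:
# h / (8 pi^2) in MHz amu A^2, from CODATA h and amu, frozen to 10
# significant digits for reproducibility across platforms.
KAPPA_MHZ_AMU_A2 <- 505379.0091

# Electron-to-proton mass ratio (CODATA).
ELECTRON_PROTON_MASS_RATIO <- 5.44617021e-4

#' Equilibrium rotational constants of a geometry
#'
#' Rigid-rotor constants from the principal moments of inertia: the
#' geometry is shifted to its center of mass, the inertia tensor
#' diagonalized, and each constant computed as B = kappa / I with
#' kappa = h / (8 pi^2) = 505379.0091 MHz amu A^2. Constants are labeled
#' a, b, c in descending order (A >= B >= C). For a linear molecule the
#' a-axis moment vanishes and `B_MHz` is reported as `Inf` for that row.
#'
#' Masses default to most-abundant-isotope values from [element_data()];
#' supply `masses` per atom for isotopologue studies.
#'
#' @param geom A [geometry()] with at least two atoms.
#' @param masses Optional numeric vector of per-atom masses (amu),
#'   same length and order as the atoms.
#' @param degeneracy_tol Two constants closer than this (MHz) are treated
#'   as degenerate and ordered deterministically by the |z| component of
#'   their principal axes.
#' @return A tibble with columns `axis` (`"a"`, `"b"`, `"c"`), `B_MHz` and
#'   `inertia_amuA2`, plus attributes `planarity_defect`
#'   (1/C - 1/A - 1/B, MHz^-1; ~0 for planar rigid bodies) and
#'   `inertia_defect` (I_c - I_a - I_b, amu A^2).
#' @examples
#' hcl_like <- geometry(c("H", "H"), c(0, 1), c(0, 0), c(0, 0))
#' rotational_constants(hcl_like)
#' @export
rotational_constants <- function(geom, masses = NULL, degeneracy_tol = 1e-6) {
  geom <- as_geometry(geom)
  n <- nrow(geom)
  if (n < 2) {
    stop("rotational constants are undefined for a monoatomic geometry",
         call. = FALSE)
  }
  m <- masses %||% element_property(geom$element, "mass")
  if (length(m) != n || any(!is.finite(m)) || any(m <= 0)) {
    stop("`masses` must be ", n, " positive finite values", call. = FALSE)
  }
  xyz <- coords_matrix(geom)
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  r2 <- rowSums(r^2)
  inertia <- diag(c(sum(m * (r2 - r[, 1]^2)),
                    sum(m * (r2 - r[, 2]^2)),
                    sum(m * (r2 - r[, 3]^2))))
  inertia[1, 2] <- inertia[2, 1] <- -sum(m * r[, 1] * r[, 2])
  inertia[1, 3] <- inertia[3, 1] <- -sum(m * r[, 1] * r[, 3])
  inertia[2, 3] <- inertia[3, 2] <- -sum(m * r[, 2] * r[, 3])
  eig <- eigen(inertia, symmetric = TRUE)
  moments <- sort(eig$values)  # ascending I -> descending B
  axes <- eig$vectors[, order(eig$values), drop = FALSE]
  b <- ifelse(moments < 1e-10, Inf, KAPPA_MHZ_AMU_A2 / moments)
  # deterministic tie-break for degenerate tops: within a degenerate
  # group, order by descending |z| of the principal axis
  fin <- is.finite(b)
  if (sum(fin) >= 2) {
    grp <- cumsum(c(1, abs(diff(b[fin])) > degeneracy_tol))
    ord <- order(grp, -abs(axes[3, fin]))
    b[fin] <- b[fin][ord]
    axes[, fin] <- axes[, fin][, ord, drop = FALSE]
    moments[fin] <- moments[fin][ord]
  }
  out <- tibble::tibble(axis = c("a", "b", "c"), B_MHz = b,
                        inertia_amuA2 = moments)
  A <- out$B_MHz[1]; B <- out$B_MHz[2]; C <- out$B_MHz[3]
  attr(out, "planarity_defect") <- 1 / C - 1 / A - 1 / B
  attr(out, "inertia_defect") <- moments[3] - moments[1] - moments[2]
  attr(out, "principal_axes") <- axes
  out
}

#' Vibrational correction to a rotational constant
#'
#' Ground-state constants differ from equilibrium ones by vibrational
#' averaging; to second order in vibrational perturbation theory,
#' \deqn{\Delta B_{vib} = -\tfrac{1}{2} \sum_r \alpha_r}
#' over the vibration-rotation interaction constants of one inertial axis.
#' The alpha constants are inputs (from an anharmonic force-field
#' calculation or from tables); this package does not compute them.
#'
#' @param alphas Numeric vector of alpha constants for one axis, MHz.
#' @return Delta B_vib in MHz; `0` with a warning for an empty input.
#' @examples
#' vibrational_shift(c(2, 4))  # -3
#' @export
vibrational_shift <- function(alphas) {
  if (length(alphas) == 0) {
    warning("empty alpha list; vibrational shift set to 0", call. = FALSE)
    return(0)
  }
  if (any(!is.finite(alphas))) {
    stop("alpha constants must be finite", call. = FALSE)
  }
  -0.5 * sum(alphas)
}

#' Electronic correction to a rotational constant
#'
#' Rotation of the electron cloud slightly rescales each constant through
#' the rotational g-tensor:
#' \deqn{\Delta B_{el} = \frac{m}{M_p} g_{ii} B_i}
#' with g in nuclear magnetons and m/M_p = 5.44617e-4 the
#' electron-to-proton mass ratio. The shift is linear in both arguments
#' and bounded by ~5.4e-4 |g| B, well under 0.1% of B for typical |g| < 1.
#'
#' @param B Rotational constant(s), MHz.
#' @param g Corresponding diagonal g-tensor element(s), dimensionless.
#' @return Delta B_el in MHz.
#' @examples
#' electronic_shift(6067.4, -0.09)
#' @export
electronic_shift <- function(B, g) {
  if (any(!is.finite(B)) || any(!is.finite(g))) {
    stop("inputs to electronic_shift must be finite", call. = FALSE)
  }
  ELECTRON_PROTON_MASS_RATIO * g * B
}

#' Assemble ground-state rotational constants from components
#'
#' \deqn{B_0 = B_{eq} + \Delta B_{CVB} + \Delta B_{VB} + \Delta B_{vib}}
#' The electronic term, when present, is retained for reporting but never
#' folded into `b0` (benchmark totals exclude it). Missing components are
#' an error -- a silently assumed zero would bias every downstream
#' statistic.
#'
#' @param data A data frame with numeric columns `b_eq`, `delta_cvb`,
#'   `delta_vb`, `delta_vib` (MHz); `delta_el` and any identifier columns
#'   pass through.
#' @return The input tibble with a `b0` column (replaced if present).
#' @examples
#' assemble_ground_state(tibble::tibble(
#'   b_eq = 6067.4, delta_cvb = 25.3, delta_vb = -5.1, delta_vib = -44.7))
#' @export
assemble_ground_state <- function(data) {
  need <- c("b_eq", "delta_cvb", "delta_vb", "delta_vib")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("missing component column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    if (anyNA(data[[col]])) {
      stop("component column '", col, "' contains missing values", call. = FALSE)
    }
  }
  data <- tibble::as_tibble(data)
  data$b0 <- data$b_eq + data$delta_cvb + data$delta_vb + data$delta_vib
  data
}
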