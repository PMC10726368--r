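#' Core-valence bond-length correction
#'
#' One-parameter estimate of the bond contraction caused by core-valence
#' electron correlation, which valence-only (frozen-core quality) DFT
#' optimizations miss:
#' \deqn{\Delta r_{CVB} = -k \sqrt{n_{ij} - 1}\,(r_i^{cov} + r_j^{cov})}
#' where \eqn{n_{ij} = n_i n_j} is the product of the principal quantum
#' numbers and k = 0.0011. Built from covalent radii only -- not from the
#' actual bond length -- so the estimate is method-independent, and it
#' vanishes identically for bonds between first-period atoms
#' (\eqn{n_{ij} = 1}), which have no core to correlate.
#'
#' Typical magnitudes are a few mA: -0.0012 (C-H), -0.0027 (C-O),
#' -0.0028 (C-N), -0.0029 (C-C). The correction is always <= 0.
#'
#' @param el_i,el_j Element symbols (vectorized, symmetric in order).
#' @param k Correction strength, dimensionless (default 0.0011).
#' @inheritParams element_data
#' @return Length correction(s) in A (non-positive).
#' @examples
#' delta_r_cvb("C", "H")
#' delta_r_cvb("H", "H")  # exactly zero
#' @export
delta_r_cvb <- function(el_i, el_j, k = 0.0011, radii = NULL) {
  n_ij <- element_property(el_i, "principal_quantum_number", radii) *
    element_property(el_j, "principal_quantum_number", radii)
  rsum <- element_property(el_i, "covalent_radius", radii) +
    element_property(el_j, "covalent_radius", radii)
  -k * sqrt(n_ij - 1) * rsum
}

#' Valence bond-length correction for multiple CC bonds
#'
#' Small positive lengthening that compensates the slight overestimation of
#' conjugation typical of double-hybrid DFT, applied only to carbon-carbon
#' bonds (a Kronecker delta on the element pair) and growing with bond
#' multiplicity:
#' \deqn{\Delta r_{VB} = c\,\delta_{CC}\,(P_{ij} - 1)}
#' with c = 0.0018 and \eqn{P_{ij}} the Pauling bond order computed from
#' the input geometry. The term vanishes for single bonds
#' (\eqn{P \approx 1}) and its precise value is insensitive to whether an
#' aromatic bond has order 1.4 or 1.6 -- the corrections are all on the mA
#' scale.
#'
#' @param order Pauling bond order(s) of the bond(s).
#' @param el_i,el_j Element symbols (vectorized).
#' @param coef Correction strength c in A per unit bond order.
#' @return Length correction(s) in A (zero unless both atoms are carbon).
#' @examples
#' delta_r_vb(1.5, "C", "C")  # aromatic bond
#' delta_r_vb(2.8, "C", "N")  # non-CC: exactly zero
#' @export
delta_r_vb <- function(order, el_i, el_j, coef = 0.0018) {
  is_cc <- element_property(el_i, "symbol") == "C" &
    element_property(el_j, "symbol") == "C"
  ifelse(is_cc, coef * (order - 1), 0)
}

#' Corrected target lengths for every bond
#'
#' Applies both bond-length corrections to each perceived bond:
#' \deqn{r^{target} = r + \Delta r_{CVB} + \Delta r_{VB}}
#' Valence angles receive no correction -- core-valence effects on angles
#' are negligible, so the refit holds them at their input values.
#'
#' @param geom A [geometry()].
#' @param internals An [build_internals()] set; built from `geom` if
#'   omitted. The angle list passes through untouched.
#' @param k Core-valence strength, see [delta_r_cvb()].
#' @param vb_coef Valence strength, see [delta_r_vb()].
#' @inheritParams element_data
#' @return A tibble with one row per bond: `i`, `j`, `el_i`, `el_j`,
#'   `length`, `order`, `n_product` (product of principal quantum
#'   numbers), `delta_cvb`, `delta_vb`, `target_length` (all lengths A).
#' @examples
#' h2 <- geometry(c("H", "H"), c(0, 0.74), c(0, 0), c(0, 0))
#' corrected_bond_targets(h2)  # both corrections vanish
#' @export
corrected_bond_targets <- function(geom, internals = NULL, k = 0.0011,
                                   vb_coef = 0.0018, radii = NULL) {
  geom <- as_geometry(geom)
  if (is.null(internals)) internals <- build_internals(geom)
  b <- internals$bonds
  el_i <- geom$element[b$i]
  el_j <- geom$element[b$j]
  out <- tibble::tibble(
    i = b$i, j = b$j, el_i = el_i, el_j = el_j,
    length = b$length, order = b$order,
    n_product = as.integer(
      element_property(el_i, "principal_quantum_number") *
        element_property(el_j, "principal_quantum_number")),
    delta_cvb = delta_r_cvb(el_i, el_j, k = k, radii = radii),
    delta_vb = delta_r_vb(b$order, el_i, el_j, coef = vb_coef)
  )
  out$target_length <- out$length + out$delta_cvb + out$delta_vb
  out
}
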