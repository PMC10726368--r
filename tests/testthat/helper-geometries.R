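# Small programmatic fixtures shared across the test files.

water_geom <- function(r = 0.9572, ang = 104.52) {
  half <- ang / 2 * pi / 180
  geometry(c("O", "H", "H"),
           x = c(0, r * sin(half), -r * sin(half)),
           y = c(0, -r * cos(half), -r * cos(half)),
           z = c(0, 0, 0), label = "water")
}

methane_geom <- function(r = 1.09) {
  d <- r / sqrt(3)
  geometry(c("C", "H", "H", "H", "H"),
           x = c(0, d, d, -d, -d),
           y = c(0, d, -d, d, -d),
           z = c(0, d, -d, -d, d), label = "methane")
}

# Random non-clashing cluster built as a jittered chain; deterministic in
# the seed passed in.
random_cluster <- function(n, seed, elements = c("H", "C", "N", "O", "S"),
                           min_sep = 0.8) {
  set.seed(seed)
  repeat {
    xyz <- matrix(0, n, 3)
    for (i in seq_len(n)[-1]) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      xyz[i, ] <- xyz[i - 1, ] + dir * stats::runif(1, 1.1, 1.6)
    }
    d <- stats::dist(xyz)
    if (min(d) > min_sep) break
  }
  geometry(sample(elements, n, replace = TRUE),
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
           label = paste0("random cluster n=", n))
}

# Central finite differences of one internal coordinate's value with
# respect to every Cartesian coordinate.
fd_internal_derivative <- function(geom, coordinate, step = 1e-6,
                                   angle_unit = "degrees") {
  xyz <- cbind(geom$x, geom$y, geom$z)
  value_of <- function(m) {
    if (!("k" %in% names(coordinate)) || length(coordinate$k) == 0 ||
        is.na(coordinate$k[1])) {
      sqrt(sum((m[coordinate$j[1], ] - m[coordinate$i[1], ])^2))
    } else {
      u <- m[coordinate$i[1], ] - m[coordinate$j[1], ]
      v <- m[coordinate$k[1], ] - m[coordinate$j[1], ]
      ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
      if (angle_unit == "degrees") ang * 180 / pi else ang
    }
  }
  out <- matrix(0, nrow(geom), 3)
  for (a in seq_len(nrow(geom))) {
    for (c in 1:3) {
      p <- xyz; p[a, c] <- p[a, c] + step
      m <- xyz; m[a, c] <- m[a, c] - step
      out[a, c] <- (value_of(p) - value_of(m)) / (2 * step)
    }
  }
  out
}

# Five-point central stencil: O(h^4) truncation keeps the oracle itself
# well below the 1e-8 relative agreement it is used to certify.
fd_penalty_gradient <- function(geom, targets, reference_angles, settings,
                                step = 1e-4) {
  base <- as_geometry(geom)
  s_at <- function(col, a, h) {
    g2 <- base
    g2[[col]][a] <- g2[[col]][a] + h
    penalty_value(g2, targets, reference_angles, settings)
  }
  out <- matrix(0, nrow(base), 3)
  for (a in seq_len(nrow(base))) {
    for (ci in 1:3) {
      col <- c("x", "y", "z")[ci]
      out[a, ci] <- (-s_at(col, a, 2 * step) + 8 * s_at(col, a, step) -
                       8 * s_at(col, a, -step) + s_at(col, a, -2 * step)) /
        (12 * step)
    }
  }
  out
}

# Canonical representation of a bond set for order-invariance comparisons.
bond_signature <- function(bonds) {
  sig <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
  sort(sig)
}
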