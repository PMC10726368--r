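test_that("Pauling bond order has its reference points and monotonicity", {
  # order 1 exactly at the covalent-radius sum, for every element pair
  els <- element_data()$symbol
  for (a in els) for (b in els) {
    rsum <- lookup_element(a)$covalent_radius + lookup_element(b)$covalent_radius
    expect_equal(pauling_bond_order(rsum, a, b), 1.0, tolerance = 1e-12)
    # bonding threshold ~0.3 about 0.35 A beyond the radius sum
    expect_lt(abs(pauling_bond_order(rsum + 0.35, a, b) - 0.3), 0.02)
  }
  # strictly decreasing over a distance grid
  grid <- seq(0.5, 4.0, by = 0.01)
  p <- pauling_bond_order(grid, "C", "N")
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0))
  expect_error(pauling_bond_order(0, "C", "C"), "positive")
  expect_error(pauling_bond_order(-1, "C", "C"), "positive")
})

test_that("bond perception applies the 0.3 threshold pairwise", {
  far <- geometry(c("H", "H"), c(0, 5), c(0, 0), c(0, 0))
  expect_equal(nrow(perceive_bonds(far)), 0)

  h2 <- geometry(c("H", "H"), c(0, 0.74), c(0, 0), c(0, 0))
  b <- perceive_bonds(h2)
  expect_equal(nrow(b), 1)
  expect_equal(b$length, 0.74)
  expect_equal(b$order, exp((0.62 - 0.74) / 0.3), tolerance = 1e-12)
  expect_true(all(b$order >= 0.3))

  bz <- perceive_bonds(benzene_geometry())
  expect_equal(nrow(bz), 12)
  expect_true(all(bz$i < bz$j))
})

test_that("perception is invariant under rigid motion and atom reordering", {
  g <- furonitrile_geometry()
  ref <- perceive_bonds(g)
  # rigid rotation + translation
  th <- 0.81
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- cbind(g$x, g$y, g$z) %*% R
  g_rot <- geometry(g$element, xyz[, 1] + 3, xyz[, 2] - 1, xyz[, 3] + 0.5)
  rot <- perceive_bonds(g_rot)
  expect_identical(bond_signature(rot), bond_signature(ref))
  expect_equal(sort(rot$length), sort(ref$length), tolerance = 1e-12)
  # reordering up to relabeling
  perm <- c(3, 1, 4, 2, 5, 10, 7, 6, 9, 8)
  g_perm <- geometry(g$element[perm], g$x[perm], g$y[perm], g$z[perm])
  inv <- order(perm)
  back <- perceive_bonds(g_perm)
  relabeled <- tibble::tibble(i = pmin(perm[back$i], perm[back$j]),
                              j = pmax(perm[back$i], perm[back$j]))
  expect_identical(bond_signature(relabeled), bond_signature(ref))
})

test_that("connectivity overrides force and forbid specific pairs", {
  far <- geometry(c("H", "H"), c(0, 5), c(0, 0), c(0, 0))
  forced <- perceive_bonds(far, force = rbind(c(1, 2)))
  expect_equal(nrow(forced), 1)
  expect_equal(forced$length, 5)
  h2 <- geometry(c("H", "H"), c(0, 0.74), c(0, 0), c(0, 0))
  expect_equal(nrow(perceive_bonds(h2, forbid = rbind(c(2, 1)))), 0)
})

test_that("redundant internals enumerate one angle per bond pair at a centre", {
  w <- build_internals(water_geom())
  expect_equal(nrow(w$bonds), 2)
  expect_equal(nrow(w$angles), 1)
  expect_equal(w$angles$j, 1)  # oxygen central
  expect_equal(w$angles$value, 104.52, tolerance = 1e-6)

  m <- build_internals(methane_geom())
  expect_equal(nrow(m$bonds), 4)
  expect_equal(nrow(m$angles), 6)

  bz <- build_internals(benzene_geometry())
  expect_equal(nrow(bz$bonds), 12)
  expect_equal(nrow(bz$angles), 18)

  # angle count equals sum over centres of choose(degree, 2)
  for (seed in 1:5) {
    g <- random_cluster(6, seed = 100 + seed)
    ic <- build_internals(g)
    deg <- table(factor(c(ic$bonds$i, ic$bonds$j), levels = seq_len(nrow(g))))
    expect_equal(nrow(ic$angles), sum(choose(deg, 2)))
  }
})

test_that("Wilson derivatives match central finite differences", {
  # diatomic closed form: unit vector at j, negated at i
  h2 <- geometry(c("H", "H"), c(0, 0.74), c(0, 0), c(0, 0))
  d <- internal_derivatives(h2, list(i = 1L, j = 2L))
  expect_equal(d[2, ], c(1, 0, 0))
  expect_equal(d[1, ], c(-1, 0, 0))

  worst <- 0
  for (seed in 1:100) {
    g <- random_cluster(5, seed = 7000 + seed)
    ic <- build_internals(g)
    coords <- list()
    if (nrow(ic$bonds) > 0) coords <- c(coords, list(ic$bonds[1, ]))
    if (nrow(ic$angles) > 0) coords <- c(coords, list(ic$angles[1, ]))
    for (coord in coords) {
      ana <- internal_derivatives(g, coord)
      num <- fd_internal_derivative(g, coord)
      worst <- max(worst, max(abs(ana - num)))
      # translation invariance: per-coordinate derivatives sum to zero
      expect_lt(max(abs(colSums(ana))), 1e-12)
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("degenerate internal coordinates are rejected", {
  lin <- geometry(c("C", "C", "C"), c(0, 1.3, 2.6), c(0, 0, 0), c(0, 0, 0))
  expect_error(internal_derivatives(lin, list(i = 1L, j = 2L, k = 3L)),
               "collinear")
})

test_that("radians option rescales angle derivatives exactly", {
  g <- water_geom()
  ic <- build_internals(g)
  ddeg <- internal_derivatives(g, ic$angles[1, ], angle_unit = "degrees")
  drad <- internal_derivatives(g, ic$angles[1, ], angle_unit = "radians")
  expect_equal(ddeg, drad * 180 / pi, tolerance = 1e-12)
})
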