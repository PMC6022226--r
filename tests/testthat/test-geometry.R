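# Inertial alignment, dipole arithmetic, Shrake-Rupley SASA and shadow
# projections, against analytic geometry oracles.

two_atom_mol <- function(xyz1, xyz2, elements = c("C", "C")) {
  a <- data.frame(element = elements, formal_charge = 0L, n_implicit_h = 0L,
                  x = c(xyz1[1], xyz2[1]), y = c(xyz1[2], xyz2[2]),
                  z = c(xyz1[3], xyz2[3]))
  new_molecule("two", a, data.frame(i = 1L, j = 2L, order = 1L))
}

test_that("alignment puts a diatomic on the x-axis and is idempotent", {
  d <- sqrt(sum((c(1, 2, 2))^2))
  m <- two_atom_mol(c(0, 0, 0), c(1, 2, 2))
  al <- inertial_align(m)
  X <- coumarinQSAR:::coords_matrix(al)
  expect_lt(max(abs(X[, 2:3])), 1e-9)
  expect_equal(abs(diff(X[, 1])), d, tolerance = 1e-9)

  # coordinates are a fixed point (the degenerate perpendicular moments
  # leave the y/z axis pair free, but every atom sits on the x-axis)
  al2 <- inertial_align(al)
  expect_lt(max(abs(coumarinQSAR:::coords_matrix(al2) - X)), 1e-9)

  # for a generic polyatomic the second transform is the identity
  big <- inertial_align(cached_embedded()[["4a"]])
  big2 <- inertial_align(big)
  expect_lt(max(abs(big2$align_rotation - diag(3))), 1e-9)
  expect_lt(max(abs(coumarinQSAR:::coords_matrix(big2) -
                    coumarinQSAR:::coords_matrix(big))), 1e-9)
})

test_that("single atom aligns with the identity frame", {
  a <- data.frame(element = "C", formal_charge = 0L, n_implicit_h = 4L,
                  x = 3, y = -1, z = 2)
  m <- new_molecule("one", a, data.frame(i = integer(), j = integer(),
                                         order = integer()))
  al <- inertial_align(m)
  expect_equal(unname(unlist(al$atoms[, c("x", "y", "z")])), c(0, 0, 0))
  expect_equal(al$align_rotation, diag(3))
})

test_that("alignment is invariant to rigid motion up to the sign convention", {
  m <- cached_embedded()[["4a"]]
  ref <- coumarinQSAR:::coords_matrix(inertial_align(m))
  set.seed(99)
  for (k in 1:20) {
    R <- random_rotation()
    t <- rnorm(3, sd = 5)
    m2 <- m
    X <- sweep(coumarinQSAR:::coords_matrix(m) %*% t(R), 2, t, `+`)
    m2$atoms$x <- X[, 1]; m2$atoms$y <- X[, 2]; m2$atoms$z <- X[, 3]
    out <- coumarinQSAR:::coords_matrix(inertial_align(m2))
    expect_lt(max(abs(out - ref)), 1e-6)
  }
})

test_that("dipole arithmetic and invariances", {
  # two point charges +/- 0.1 e at 1 A separation -> 0.4803 D
  m <- two_atom_mol(c(0, 0, 0), c(1, 0, 0))
  m$atoms$partial_charge <- c(0.1, -0.1)
  d <- dipole_descriptors(m)
  expect_equal(unname(d["Dipole_mag"]), 0.480320, tolerance = 1e-9)
  expect_equal(unname(d["Dipole_mag"]^2),
               unname(d["Dipole_X"]^2 + d["Dipole_Y"]^2 + d["Dipole_Z"]^2),
               tolerance = 1e-9)

  # neutral molecule: translation leaves the dipole unchanged
  mt <- m
  mt$atoms$x <- mt$atoms$x + 10
  expect_equal(dipole_descriptors(mt), d, tolerance = 1e-9)

  # methane is apolar
  met <- gasteiger_charges(embed_3d(parse_structure("C"), 1))
  expect_lt(dipole_descriptors(inertial_align(met))[["Dipole_mag"]], 0.05)

  expect_error(dipole_descriptors(two_atom_mol(c(0, 0, 0), c(1, 0, 0))),
               "charges")
})

test_that("SASA matches the analytic sphere and is additive at distance", {
  a <- data.frame(element = "C", formal_charge = 0L, n_implicit_h = 0L,
                  x = 0, y = 0, z = 0)
  m <- new_molecule("atom", a, data.frame(i = integer(), j = integer(),
                                          order = integer()))
  area <- sum(sasa(m, probe_radius = 1.4, n_points = 960))
  expect_equal(area, 4 * pi * (1.70 + 1.40)^2, tolerance = 0.01)

  far <- two_atom_mol(c(0, 0, 0), c(100, 0, 0))
  expect_equal(sum(sasa(far)), 2 * 4 * pi * 3.1^2, tolerance = 1e-6)

  expect_error(sasa(m, n_points = 16), "accuracy floor")
})

test_that("SASA converges to the two-sphere lens formula", {
  d <- 1.5
  m <- two_atom_mol(c(0, 0, 0), c(d, 0, 0), elements = c("C", "O"))
  R1 <- 1.70 + 1.4; R2 <- 1.52 + 1.4
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x1
  h2 <- R2 - (d - x1)
  exact <- (4 * pi * R1^2 - 2 * pi * R1 * h1) +
           (4 * pi * R2^2 - 2 * pi * R2 * h2)
  approx <- sum(sasa(m, n_points = 10000))
  expect_equal(approx, exact, tolerance = 2e-3)
})

test_that("SASA is stable under point-count refinement on a fixture", {
  m <- cached_embedded()[["4a"]]
  a960 <- sum(sasa(m, n_points = 960))
  a10k <- sum(sasa(m, n_points = 10000))
  expect_lt(abs(a960 - a10k) / a10k, 0.02)
})

test_that("shadow projections match analytic discs and extents", {
  a <- data.frame(element = "C", formal_charge = 0L, n_implicit_h = 0L,
                  x = 0, y = 0, z = 0)
  m <- new_molecule("atom", a, data.frame(i = integer(), j = integer(),
                                          order = integer()))
  s <- shadow_descriptors(m, grid_step = 0.05)
  expect_equal(unname(s["Shadow_XY"]), pi * 1.70^2, tolerance = 0.01)
  expect_equal(unname(s[c("Shadow_Xlength", "Shadow_Ylength",
                          "Shadow_Zlength")]),
               rep(3.40, 3), tolerance = 1e-9)
  expect_equal(unname(s["Shadow_XYfrac"]),
               pi * 1.70^2 / 3.4^2, tolerance = 0.01)

  dia <- two_atom_mol(c(0, 0, 0), c(1.5, 0, 0))
  sd <- shadow_descriptors(dia)
  expect_equal(unname(sd["Shadow_Xlength"]), 1.5 + 2 * 1.7)
  expect_error(shadow_descriptors(dia, grid_step = 0), "positive")
})

test_that("shadow areas converge under grid refinement", {
  m <- cached_embedded()[["13a"]]
  al <- inertial_align(m)
  s1 <- shadow_descriptors(al, grid_step = 0.1)
  s2 <- shadow_descriptors(al, grid_step = 0.05)
  for (k in c("Shadow_XY", "Shadow_YZ", "Shadow_XZ"))
    expect_lt(abs(s1[[k]] - s2[[k]]) / s2[[k]], 0.005)
})

test_that("orientation-dependent descriptors are invariant to input pose", {
  m <- cached_embedded()[["8a"]]
  m <- gasteiger_charges(m)
  base <- inertial_align(m)
  v0 <- c(dipole_descriptors(base)["Dipole_mag"],
          Total_SASA = sum(sasa(base)),
          shadow_descriptors(base)[c("Shadow_XY", "Shadow_YZ", "Shadow_XZ")])
  set.seed(3)
  R <- random_rotation()
  m2 <- m
  X <- sweep(coumarinQSAR:::coords_matrix(m) %*% t(R), 2, c(4, -2, 7), `+`)
  m2$atoms$x <- X[, 1]; m2$atoms$y <- X[, 2]; m2$atoms$z <- X[, 3]
  al2 <- inertial_align(m2)
  v1 <- c(dipole_descriptors(al2)["Dipole_mag"],
          Total_SASA = sum(sasa(al2)),
          shadow_descriptors(al2)[c("Shadow_XY", "Shadow_YZ", "Shadow_XZ")])
  expect_equal(v1, v0, tolerance = 1e-6)
})
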