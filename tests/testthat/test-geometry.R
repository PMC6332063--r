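test_that("ring centroid and normal are exact for a planar hexagon and equivariant under rotation", {
  st <- hexagon_structure()
  rcn <- ring_centroid_normal(st, paste0("R", 1:6))
  expect_equal(rcn$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(rcn$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(rcn$max_dev, 0, tolerance = 1e-12)
  m <- rigid_motion(3)
  rcn2 <- ring_centroid_normal(apply_motion(st, m), paste0("R", 1:6))
  expect_equal(rcn2$centroid, drop(m$R %*% rcn$centroid) + m$t,
               tolerance = 1e-9)
  expect_equal(abs(sum(rcn2$normal * (m$R %*% rcn$normal))), 1,
               tolerance = 1e-9)
})

test_that("plane fit of a puckered ring agrees with the SVD oracle", {
  set.seed(21)
  th <- 2 * pi * (0:5) / 6
  z <- rnorm(6, 0, 0.05)
  st <- structure_coordinates(paste0("R", 1:6), rep("C", 6),
                              1.39 * cos(th), 1.39 * sin(th), z)
  rcn <- ring_centroid_normal(st, paste0("R", 1:6))
  P <- as.matrix(st[, c("x", "y", "z")])
  Q <- sweep(P, 2, colMeans(P))
  n_svd <- svd(Q)$v[, 3]
  expect_equal(abs(sum(rcn$normal * n_svd)), 1, tolerance = 1e-9)
  ang_z <- acos(abs(rcn$normal[3])) * 180 / pi
  expect_lt(ang_z, 3)
  # collinear atoms have no plane
  line <- structure_coordinates(paste0("L", 1:4), rep("C", 4),
                                1:4, 2 * (1:4), 3 * (1:4))
  expect_error(ring_centroid_normal(line, paste0("L", 1:4)), "collinear")
})

test_that("CH-pi parameters reproduce axial and laterally displaced textbook geometries", {
  axial <- hexagon_structure(data.frame(atom_id = c("C7", "H7"),
                                        element = c("C", "H"),
                                        x = 0, y = 0, z = c(3.59, 2.5)))
  g <- chpi_parameters(axial, "C7", "H7", paste0("R", 1:6))
  expect_equal(g$d, 2.5)
  expect_equal(g$theta, 180)
  expect_equal(g$phi, 0)
  lateral <- hexagon_structure(data.frame(atom_id = c("C7", "H7"),
                                          element = c("C", "H"),
                                          x = c(1.0, 1.0), y = 0,
                                          z = c(3.59, 2.5)))
  gl <- chpi_parameters(lateral, "C7", "H7", paste0("R", 1:6))
  expect_equal(gl$phi, atan2(1.0, 2.5) * 180 / pi, tolerance = 1e-9)
  expect_equal(gl$d, sqrt(1 + 2.5^2), tolerance = 1e-12)
  heavy <- hexagon_structure(data.frame(atom_id = "C7", element = "C",
                                        x = 0, y = 0, z = 3.5))
  gh <- chpi_parameters(heavy, "C7", NULL, paste0("R", 1:6))
  expect_equal(gh$d, 3.5)
  expect_true(gh$heavy_atom_mode)
  expect_true(is.na(gh$theta))
  far <- hexagon_structure(data.frame(atom_id = c("C7", "H7"),
                                      element = c("C", "H"),
                                      x = 0, y = 0, z = c(6, 2.5)))
  expect_error(chpi_parameters(far, "C7", "H7", paste0("R", 1:6)),
               "not bonded")
})

test_that("all contact descriptors are invariant under rigid motion and phi complements the in-plane angle", {
  gc <- generate_complex_geometry(4, d_contact = 3.4, perturbation = 0.08,
                                  seed = 5)
  st <- gc$structure
  for (k in 1:4) {
    g0 <- chpi_parameters(st, sprintf("C%d", k), sprintf("H%d", k),
                          gc$rings[[k]])
    m <- rigid_motion(100 + k)
    g1 <- chpi_parameters(apply_motion(st, m), sprintf("C%d", k),
                          sprintf("H%d", k), gc$rings[[k]])
    expect_equal(g1$d, g0$d, tolerance = 1e-9)
    expect_equal(g1$theta, g0$theta, tolerance = 1e-7)
    expect_equal(g1$phi, g0$phi, tolerance = 1e-7)
    # phi + elevation of the H above the ring plane = 90 degrees
    rcn <- ring_centroid_normal(st, gc$rings[[k]],
                                toward = sprintf("C%d", k))
    u <- unlist(st[st$atom_id == sprintf("H%d", k), c("x", "y", "z")]) -
      rcn$centroid
    elev <- asin(abs(sum(u * rcn$normal)) / sqrt(sum(u^2))) * 180 / pi
    expect_equal(g0$phi + elev, 90, tolerance = 1e-7)
  }
})

test_that("contact counting matches brute-force pair enumeration on randomized fixtures", {
  for (seed in c(2, 9, 17)) {
    gc <- generate_complex_geometry(4, d_contact = 3.6, perturbation = 0.4,
                                    seed = seed)
    st <- gc$structure
    cutoff <- 4.0
    got <- count_contacts(st, gc$methyl_atoms, gc$rings, cutoff = cutoff)
    # oracle: exhaustive distances from raw coordinates
    pairs <- list()
    for (m in gc$methyl_atoms) {
      pm <- unlist(st[st$atom_id == m, c("x", "y", "z")])
      for (ri in seq_along(gc$rings)) {
        cen <- colMeans(st[match(gc$rings[[ri]], st$atom_id), c("x", "y", "z")])
        dd <- sqrt(sum((pm - cen)^2))
        if (dd <= cutoff) pairs[[paste(m, ri)]] <- dd
      }
    }
    expect_equal(got$n_contacts, length(pairs))
    expect_setequal(paste(got$contacts$methyl, got$contacts$ring),
                    names(pairs))
    expect_false(is.unsorted(got$contacts$d))
  }
  gc <- generate_complex_geometry(4, d_contact = 3.5)
  expect_equal(count_contacts(gc$structure, gc$methyl_atoms, gc$rings,
                              cutoff = 2.0)$n_contacts, 0L)
  expect_error(count_contacts(gc$structure, gc$methyl_atoms, list()), "ring")
})

test_that("hydrogen-bond distances are plain Euclidean lengths", {
  st <- structure_coordinates(c("H1", "O1", "H2", "O2"),
                              c("H", "O", "H", "O"),
                              x = c(0, 0, 1, 1), y = c(0, 0, 2, 2),
                              z = c(0, 2.095, 0, 0))
  d <- hydrogen_bond_distances(st, c("H1", "H2"), c("O1", "O2"))
  expect_equal(d, c(2.095, 0))
  set.seed(8)
  P <- matrix(rnorm(30), ncol = 3)
  st2 <- structure_coordinates(paste0("A", 1:10), rep("X", 10),
                               P[, 1], P[, 2], P[, 3])
  d2 <- hydrogen_bond_distances(st2, paste0("A", 1:5), paste0("A", 6:10))
  expect_equal(d2, sqrt(rowSums((P[1:5, ] - P[6:10, ])^2)))
  expect_error(hydrogen_bond_distances(st, "H1", c("O1", "O2")), "length")
  expect_error(hydrogen_bond_distances(st, "H9", "O1"), "H9")
})

test_that("XYZ files round-trip and PDB records are parsed into coordinates", {
  gc <- generate_complex_geometry(2, perturbation = 0.1, seed = 4)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(gc$structure, p, comment = "synthetic two-wall fixture")
  back <- read_xyz(p)
  expect_equal(back$element, gc$structure$element)
  expect_equal(back$x, gc$structure$x, tolerance = 1e-7)
  expect_equal(back$z, gc$structure$z, tolerance = 1e-7)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("HETATM    1  N1  LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           N", 0, 0, 0),
    sprintf("HETATM    2  O1  LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           O", 0, 0, 1.36),
    sprintf("HETATM    3  C1  LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00           C", 1.5, 0, 0),
    "END"), pdb)
  st <- read_pdb_coords(pdb)
  expect_equal(nrow(st), 3L)
  expect_equal(st$element, c("N", "O", "C"))
  expect_equal(st$z[2], 1.36)
})
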