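test_that("centre of mass matches direct weighted means", {
  g1 <- atom_group(matrix(c(1, 2, 3), 1, 3), 12)
  expect_equal(center_of_mass(g1), c(1, 2, 3))
  g2 <- atom_group(rbind(c(-1, 0, 0), c(1, 0, 0)), c(5, 5))
  expect_equal(center_of_mass(g2), c(0, 0, 0))
  set.seed(4)
  for (i in 1:20) {
    xyz <- matrix(rnorm(30), 10, 3)
    m <- runif(10, 0.1, 30)
    g <- atom_group(xyz, m)
    expect_equal(center_of_mass(g),
                 as.numeric(t(xyz) %*% m / sum(m)), tolerance = 1e-12)
  }
})

test_that("canonical dihedral and angle cases evaluate correctly", {
  pt <- function(...) atom_group(matrix(c(...), 1, 3), 1)
  cis <- collective_variable("dihedral", list(pt(0, 0, 0), pt(1, 0, 0),
                                              pt(1, 1, 0), pt(0, 1, 0)))
  expect_equal(eval_cv(cis), 0, tolerance = 1e-12)
  orth <- collective_variable("dihedral", list(pt(0, 0, 0), pt(1, 0, 0),
                                               pt(1, 1, 0), pt(1, 1, 1)))
  expect_equal(abs(eval_cv(orth)), 90, tolerance = 1e-12)
  right <- collective_variable("planar_angle", list(pt(1, 0, 0), pt(0, 0, 0),
                                                    pt(0, 1, 0)))
  expect_equal(eval_cv(right), 90, tolerance = 1e-12)
  d <- collective_variable("distance", list(pt(0, 0, 0), pt(3, 4, 0)))
  expect_equal(eval_cv(d), 5)
  colinear <- collective_variable("dihedral", list(pt(0, 0, 0), pt(1, 0, 0),
                                                   pt(2, 0, 0), pt(3, 1, 0)))
  expect_error(eval_cv(colinear), "colinear")
})

test_that("CVs agree with independent oracles on random configurations", {
  set.seed(12)
  max_dih <- 0
  max_ang <- 0
  for (i in 1:50) {
    gs <- replicate(4, rand_atom_group(), simplify = FALSE)
    coms <- lapply(gs, center_of_mass)
    dih <- eval_cv(collective_variable("dihedral", gs))
    oracle <- dihedral_frame_oracle(coms[[1]], coms[[2]], coms[[3]], coms[[4]])
    max_dih <- max(max_dih, abs(dih - oracle))
    ang <- eval_cv(collective_variable("planar_angle", gs[1:3]))
    max_ang <- max(max_ang,
                   abs(ang - planar_angle_oracle(coms[[1]], coms[[2]],
                                                 coms[[3]])))
  }
  expect_lt(max_dih, 1e-9)
  expect_lt(max_ang, 1e-9)
})

test_that("distance is symmetric and dihedrals flip sign under mirror inversion", {
  set.seed(13)
  gs <- replicate(4, rand_atom_group(), simplify = FALSE)
  d12 <- eval_cv(collective_variable("distance", gs[1:2]))
  d21 <- eval_cv(collective_variable("distance", gs[2:1]))
  expect_identical(d12, d21)
  dih <- eval_cv(collective_variable("dihedral", gs))
  mirrored <- lapply(gs, function(g) {
    xyz <- g$coords
    xyz[, 3] <- -xyz[, 3]
    atom_group(xyz, g$masses)
  })
  expect_equal(eval_cv(collective_variable("dihedral", mirrored)), -dih,
               tolerance = 1e-9)
})

test_that("dihedral matches bio3d's torsion for single-atom groups", {
  set.seed(14)
  for (i in 1:10) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    gs <- lapply(1:4, function(j) atom_group(p[j, , drop = FALSE], 1))
    mine <- eval_cv(collective_variable("dihedral", gs))
    ref <- bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4)
    expect_equal(mine, as.numeric(ref)[1], tolerance = 1e-6)
  }
})

test_that("RMSD honours rigid-body invariance and the translation closed form", {
  set.seed(15)
  A <- matrix(rnorm(60), 20, 3)
  expect_identical(backbone_rmsd(A, A, superpose = FALSE), 0)
  # arbitrary rotation + translation vanishes under superposition
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  B <- A %*% t(R) + matrix(c(1, -2, 3), 20, 3, byrow = TRUE)
  expect_lt(backbone_rmsd(B, A, superpose = TRUE), 1e-10)
  # uniform translation without superposition is exactly the shift
  C <- A
  C[, 1] <- C[, 1] + 0.37
  expect_equal(backbone_rmsd(C, A, superpose = FALSE), 0.37,
               tolerance = 1e-12)
  expect_error(backbone_rmsd(A[1:5, ], A), "equal size")
  # cross-check superposed RMSD against bio3d on a deformed copy
  D <- B + matrix(rnorm(60, sd = 0.1), 20, 3)
  ref <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(D)), fit = TRUE)
  # bio3d rounds its RMSD to three decimals
  expect_lt(abs(backbone_rmsd(D, A, superpose = TRUE) - ref), 1e-3)
})

test_that("PDB-derived atom groups and configured CVs evaluate on a structure", {
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(pdb_path)
  g <- atom_group_from_pdb(pdb_path, chain = "A", resno = c(1, 107),
                           elety = "CA")
  expect_equal(nrow(g$coords), 1L)
  expect_equal(g$coords[1, ], c(0, 0, 0), ignore_attr = TRUE)  # in nm
  cfg <- system.file("extdata", "hsa_cv_domains.yaml", package = "alloitc")
  tab <- eval_cv_set(pdb_path, cfg)
  expect_equal(nrow(tab), 4L)
  expect_true(all(is.finite(tab$value)))
  expect_equal(tab$unit, c("degrees", "degrees", "nm", "nm"))
  # R2 distance: CA at resno 50 (origin) to CA at resno 250 -> |(10,10,0)| A
  expect_equal(tab$value[tab$label == "R2"], sqrt(200) / 10,
               tolerance = 1e-6)
  expect_error(atom_group_from_pdb(pdb_path, chain = "B"), "no atoms")
})
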