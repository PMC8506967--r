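# Torsions, chi-1, Kabsch superposition, minimal distances.

test_that("dihedral matches symmetry-forced and independently derived values", {
  # coplanar cis and anti arrangements
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0)), 180)
  # sign fixed by the independent projection oracle
  p <- list(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))
  expect_equal(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
               torsion_by_projection(p[[1]], p[[2]], p[[3]], p[[4]]))
  expect_equal(abs(dihedral(p[[1]], p[[2]], p[[3]], p[[4]])), 90)
})

test_that("dihedral agrees with the projection oracle and is reversal-invariant", {
  withr::with_seed(42, {
    for (k in 1:50) {
      pts <- lapply(1:4, function(i) stats::rnorm(3, sd = 3))
      d <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
      expect_equal(d, torsion_by_projection(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
                   tolerance = 1e-8)
      # a torsion reads identically from either end of the chain
      rev <- dihedral(pts[[4]], pts[[3]], pts[[2]], pts[[1]])
      expect_equal(rev, d, tolerance = 1e-8)
    }
  })
})

test_that("collinear points make the dihedral undefined", {
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("chi-1 recovers a constructed rotamer and errors on missing atoms", {
  # gamma atom placed by rotating an ideal position about the CA-CB axis
  build_glu <- function(target_chi) {
    N <- c(0, 1.45, 0); CA <- c(0, 0, 0); CB <- c(1.2, -0.8, 0)
    axis <- (CB - CA) / sqrt(sum((CB - CA)^2))
    # start from a gamma position at chi = 0 (eclipsing N), rotate by chi
    perp <- N - sum(N * axis) * axis
    perp <- perp / sqrt(sum(perp^2))
    th <- target_chi * pi / 180
    crossp <- c(axis[2]*perp[3]-axis[3]*perp[2],
                axis[3]*perp[1]-axis[1]*perp[3],
                axis[1]*perp[2]-axis[2]*perp[1])
    cg_dir <- cos(th) * perp + sin(th) * crossp
    CG <- CB + 1.52 * cg_dir
    toy_residue("A", 1265, "GLU", c("N", "CA", "CB", "CG"),
                rbind(N, CA, CB, CG))
  }
  for (chi in c(-120, 60, 180)) {
    res <- build_glu(chi)
    got <- chi1(res)
    expect_equal(((got - chi + 180) %% 360) - 180, 0, tolerance = 1e-6)
  }
  no_cb <- build_glu(60)
  no_cb <- no_cb[no_cb$atom != "CB", ]
  expect_error(chi1(no_cb), "CB")
  gly <- toy_residue("A", 1, "GLY", c("N", "CA"), rbind(c(0, 1.4, 0), c(0, 0, 0)))
  expect_error(chi1(gly), "undefined")
})

test_that("chi-1 handles alternate conformers as a set", {
  N <- c(0, 1.45, 0); CA <- c(0, 0, 0); CB <- c(1.2, -0.8, 0)
  base <- toy_residue("A", 9, "GLU", c("N", "CA", "CB"), rbind(N, CA, CB))
  place_cg <- function(chi) {
    axis <- (CB - CA) / sqrt(sum((CB - CA)^2))
    perp <- N - sum(N * axis) * axis; perp <- perp / sqrt(sum(perp^2))
    th <- chi * pi / 180
    crossp <- c(axis[2]*perp[3]-axis[3]*perp[2],
                axis[3]*perp[1]-axis[1]*perp[3],
                axis[1]*perp[2]-axis[2]*perp[1])
    CB + 1.52 * (cos(th) * perp + sin(th) * crossp)
  }
  cgA <- toy_residue("A", 9, "GLU", "CG", rbind(place_cg(60)), alt = "A",
                     occ = 0.6)
  cgB <- toy_residue("A", 9, "GLU", "CG", rbind(place_cg(180)), alt = "B",
                     occ = 0.4)
  res <- rbind(base, cgA, cgB)
  chis <- chi1_altlocs(res)
  expect_setequal(names(chis), c("A", "B"))
  # circular match of {+60, 180} as a set
  for (target in c(60, 180))
    expect_true(any(abs(((chis - target + 180) %% 360) - 180) < 1e-6))
})

test_that("kabsch recovers exact transforms and excludes reflections", {
  withr::with_seed(7, P <- matrix(stats::rnorm(30, sd = 5), ncol = 3))
  id <- kabsch(P, P)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$rotation, diag(3), tolerance = 1e-8)
  R <- rot_about_z(90)
  Q <- P %*% t(R) + matrix(c(5, 0, 0), nrow(P), 3, byrow = TRUE)
  fit <- kabsch(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(fit$translation, c(5, 0, 0), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(3), tolerance = 1e-8)
})

test_that("kabsch rmsd matches the quaternion oracle on noisy instances", {
  withr::with_seed(99, {
    for (k in 1:25) {
      P <- matrix(stats::rnorm(30, sd = 4), ncol = 3)
      R <- bromospec:::random_rotation()
      Q <- P %*% t(R) + matrix(stats::rnorm(3, sd = 10), 10, 3, byrow = TRUE) +
        matrix(stats::rnorm(30, sd = 0.5), ncol = 3)
      expect_equal(kabsch(P, Q)$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-8)
    }
  })
})

test_that("kabsch rmsd is invariant under a common rigid transform", {
  withr::with_seed(5, {
    P <- matrix(stats::rnorm(24, sd = 3), ncol = 3)
    Q <- P + matrix(stats::rnorm(24, sd = 0.4), ncol = 3)
    base <- kabsch(P, Q)$rmsd
    R <- bromospec:::random_rotation()
    shift <- matrix(c(3, -7, 11), nrow(P), 3, byrow = TRUE)
    expect_equal(kabsch(P %*% t(R) + shift, Q %*% t(R) + shift)$rmsd,
                 base, tolerance = 1e-8)
  })
})

test_that("degenerate inputs raise superposition errors", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "degenerate|collinear")
})

test_that("minimal heavy-atom distance matches brute force and is symmetric", {
  a <- toy_residue("A", 1, "ALA", "CB", rbind(c(0, 0, 0)))
  b <- toy_residue("B", 2, "ALA", "CB", rbind(c(2.5, 0, 0)))
  expect_equal(min_heavy_atom_distance(a, b)$distance, 2.5)
  withr::with_seed(31, {
    for (k in 1:20) {
      ra <- toy_residue("A", 1, "LYS", c("N", "CA", "CB", "CG", "CD"),
                        matrix(stats::rnorm(15, sd = 3), ncol = 3))
      rb <- toy_residue("B", 2, "SER", c("N", "CA", "CB", "OG"),
                        matrix(stats::rnorm(12, mean = 4, sd = 3), ncol = 3))
      d <- min_heavy_atom_distance(ra, rb)
      expect_equal(d$distance, brute_min_distance(ra, rb), tolerance = 1e-10)
      expect_equal(min_heavy_atom_distance(rb, ra)$distance, d$distance)
    }
  })
})

test_that("altloc-only approaches are found by the minimal distance", {
  base <- toy_residue("A", 1, "GLU", c("N", "CA"),
                      rbind(c(0, 1.4, 0), c(0, 0, 0)))
  far <- toy_residue("A", 1, "GLU", "CG", rbind(c(0, -8, 0)), alt = "A",
                     occ = 0.6)
  near <- toy_residue("A", 1, "GLU", "CG", rbind(c(3.0, 0, 0)), alt = "B",
                      occ = 0.4)
  other <- toy_residue("B", 5, "ALA", "CB", rbind(c(5.8, 0, 0)))
  d <- min_heavy_atom_distance(rbind(base, far, near), other)
  expect_equal(d$distance, 2.8)
  expect_equal(d$alt_a, "B")
})
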