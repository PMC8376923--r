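test_that("torsion-distance equivalence is symmetric, monotone and invertible", {
  p <- test_params()
  for (kind in c("phi", "psi")) {
    expect_equal(torsion_to_distance(60, kind, p),
                 torsion_to_distance(-60, kind, p))
    expect_gt(torsion_to_distance(180, kind, p),
              torsion_to_distance(0, kind, p))
    d_seq <- vapply(seq(0, 180, by = 5), torsion_to_distance, numeric(1),
                    kind = kind, params = p)
    expect_true(all(diff(d_seq) > 0))
    for (ang in seq(-175, 175, by = 12.5)) {
      d <- torsion_to_distance(ang, kind, p)
      expect_equal(distance_to_torsion(d, kind, p), abs(ang),
                   tolerance = 1e-9)
    }
  }
  expect_error(torsion_to_distance(10, "chi1", p), "unsupported torsion")
})

test_that("phi distance matches an explicitly constructed four-atom chain", {
  p <- test_params()
  conf <- build_backbone("AA", phi = c(NA, -65), psi = c(140, 120), params = p)
  d_measured <- vnorm(confenum:::atom_xyz(conf, 2, "C") -
                        confenum:::atom_xyz(conf, 1, "C"))
  expect_equal(torsion_to_distance(-65, "phi", p), d_measured,
               tolerance = 1e-9)
  d_psi <- vnorm(confenum:::atom_xyz(conf, 2, "N") -
                   confenum:::atom_xyz(conf, 1, "N"))
  expect_equal(torsion_to_distance(140, "psi", p), d_psi, tolerance = 1e-9)
})

test_that("trilateration returns mirror pairs, tangent points and rejections", {
  refs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  two <- trilaterate(refs, c(1, 1, 1))
  expect_equal(nrow(two), 2)
  expect_equal(two[1, 1:2], two[2, 1:2])
  expect_equal(two[1, 3], -two[2, 3])
  for (i in 1:2) {
    expect_equal(sqrt(rowSums(sweep(refs, 2, two[i, ])^2)), c(1, 1, 1),
                 tolerance = 1e-6)
  }
  # tangency: target point lies in the reference plane
  pt <- c(0.3, 0.4, 0)
  d <- sqrt(rowSums(sweep(refs, 2, pt)^2))
  one <- trilaterate(refs, d)
  expect_equal(nrow(one), 1)
  expect_equal(as.vector(one), pt, tolerance = 1e-6)
  # infeasible
  expect_equal(nrow(trilaterate(refs, c(0.1, 0.1, 5))), 0)
  expect_error(trilaterate(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                           c(1, 1, 1)), "degenerate trilateration")
})

test_that("interval discretization widens, caps and midpoints correctly", {
  expect_equal(discretize_interval(3, 3), 3)
  expect_length(discretize_interval(2, 3), 4)
  # width 0.12 + 2 * 0.05 = 0.22 -> 2 samples at sub-interval midpoints
  s <- discretize_interval(3.00, 3.12)
  expect_length(s, 2)
  expect_equal(s, c(2.95 + 0.055, 2.95 + 0.165))
})

test_that("steric check scales van der Waals radii and skips bonded pairs", {
  p <- test_params()
  # two nonbonded CA carbons in non-adjacent residues (r = 1.7 each)
  mk <- function(d) {
    conformation(resid = c(1, 5), resname = "ALA", atom = "CA",
                 x = c(0, d), y = 0, z = 0, element = "C")
  }
  expect_false(steric_ok(mk(2.37), p))   # 2.37 < 0.7 * 3.4 = 2.38
  expect_true(steric_ok(mk(2.39), p))
  expect_true(steric_ok(mk(2.37)[1, ], p))  # single atom
  expect_error(steric_ok(conformation(1, "UNK", "XX", 0, 0, 0,
                                      element = "Zz"), p),
               "unparameterized atom")
  # bonded N-CA at bond length passes although far below radii sum
  bonded <- conformation(resid = 1, resname = "ALA", atom = c("N", "CA"),
                         x = c(0, 1.458), y = 0, z = 0)
  expect_true(steric_ok(bonded, p))
})

test_that("inflating all distances never makes a passing check fail", {
  p <- test_params()
  conf <- random_helixish(6, seed = 3)
  base <- steric_ok(conf, p)
  for (f in c(1.1, 1.5, 2)) {
    bigger <- conf
    bigger$x <- conf$x * f; bigger$y <- conf$y * f; bigger$z <- conf$z * f
    if (base) expect_true(steric_ok(bigger, p))
  }
})

test_that("improper targets accept ideal geometry and reject mirror images", {
  p <- test_params()
  conf <- build_backbone("AAA", phi = c(NA, -65, -120),
                         psi = c(140, -40, 180), params = p)
  expect_true(improper_ok(conf, p, tol_deg = 5))
  mirror <- conf
  mirror$z <- -conf$z
  expect_false(improper_ok(mirror, p, tol_deg = 50))
  # small perturbation stays within a 5-degree tolerance
  jig <- conf
  cb <- which(jig$resid == 2 & jig$atom == "CB")
  jig[cb, c("x", "y", "z")] <- jig[cb, c("x", "y", "z")] + 0.02
  expect_true(improper_ok(jig, p, tol_deg = 5))
})

test_that("Kabsch superposition recovers exact transforms and the grid optimum", {
  pts <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 1, 1, 1),
                ncol = 3, byrow = TRUE)
  fit <- kabsch_superpose(pts, pts)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rotated <- pts %*% t(Rz)
  fit2 <- kabsch_superpose(pts, rotated)
  expect_equal(fit2$rotation, Rz, tolerance = 1e-9)
  expect_lt(fit2$rmsd, 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)

  withr::with_seed(5, {
    for (rep in 1:3) {
      a <- matrix(stats::rnorm(15), ncol = 3)
      b <- matrix(stats::rnorm(15), ncol = 3)
      expect_equal(kabsch_superpose(a, b)$rmsd, oracle_min_rmsd(a, b),
                   tolerance = 1e-3)
    }
  })
  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]),
               "underdetermined superposition")
})

test_that("backbone builder reproduces requested torsions", {
  p <- test_params()
  phi <- c(NA, -72.5, 58, -130)
  psi <- c(150, -40.25, 40, 170)
  conf <- build_backbone("AGVA", phi, psi, params = p)
  tor <- backbone_torsions(conf)
  expect_equal(tor$phi[2:4], phi[2:4], tolerance = 1e-9)
  expect_equal(tor$psi[1:3], psi[1:3], tolerance = 1e-9)
  # built bonds match the parameter table
  for (r in 1:4) {
    expect_equal(vnorm(confenum:::atom_xyz(conf, r, "CA") -
                         confenum:::atom_xyz(conf, r, "N")),
                 bond_length(p, "N", "CA"), tolerance = 1e-9)
  }
  expect_false(any(conf$atom == "CB" & conf$resname == "GLY"))
})
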