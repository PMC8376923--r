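box_named <- function(...) {
  bs <- list(...)
  out <- list()
  for (b in bs) {
    rid <- as.character(b$residue_id)
    out[[rid]] <- c(out[[rid]], list(b))
  }
  out
}

test_that("box combinations form the full Cartesian product", {
  boxes <- box_named(
    torsion_box(1, -80, -60, -60, -40), torsion_box(1, -140, -120, 120, 140),
    torsion_box(2, -80, -60, -60, -40),
    torsion_box(3, -80, -60, -60, -40), torsion_box(3, -140, -120, 120, 140),
    torsion_box(3, 40, 60, 20, 40))
  spec <- fragment_spec("AAA", 1, boxes)
  combos <- box_combinations(spec)
  expect_length(combos, 6)
  expect_equal(length(unique(vapply(combos, paste, character(1),
                                    collapse = ","))), 6)

  single <- fragment_spec("AA", 1, box_named(
    torsion_box(1, -80, -60, -60, -40), torsion_box(2, -80, -60, -60, -40)))
  expect_length(box_combinations(single), 1)

  ten <- do.call(box_named, unlist(lapply(1:10, function(r) {
    list(torsion_box(r, -80, -60, -60, -40),
         torsion_box(r, -140, -120, 120, 140))
  }), recursive = FALSE))
  expect_length(box_combinations(fragment_spec(strrep("A", 10), 1, ten)), 1024)
})

test_that("a zero-width box yields exactly one clash-free conformation", {
  p <- test_params()
  spec <- fragment_spec("A", 10, box_named(
    torsion_box(10, -65, -64.999, -41, -40.999)))
  res <- enumerate_fragment(spec, 1L, enumeration_settings(), p)
  expect_length(res$conformations, 1)
  expect_true(res$complete)
  conf <- res$conformations[[1]]
  expect_setequal(conf$atom, c("N", "CA", "C", "O", "CB"))
  expect_equal(unique(conf$resid), 10L)
})

test_that("saved conformations biject with the torsion-grid oracle", {
  p <- test_params()
  st <- enumeration_settings(save_rmsd_gate = -Inf)
  cases <- list(
    list(seq = "AV", start = 10,
         boxes = list(torsion_box(10, -80, -40, -60, -20),
                      torsion_box(11, -150, -110, 110, 150))),
    list(seq = "AGA", start = 5,
         boxes = list(torsion_box(5, -75, -55, -50, -30),
                      torsion_box(6, 40, 80, 10, 50),
                      torsion_box(7, -140, -100, 120, 160))))
  for (case in cases) {
    named <- list()
    for (b in case$boxes) named[[as.character(b$residue_id)]] <- list(b)
    spec <- fragment_spec(case$seq, case$start, named)
    res <- enumerate_fragment(spec, rep(1L, nchar(case$seq)), st, p)
    oracle <- oracle_enumerate(case$seq, case$start, case$boxes, p, st)
    expect_equal(length(res$conformations), length(oracle))
    for (i in seq_along(oracle)) {
      expect_lt(max(abs(coords(res$conformations[[i]]) -
                          coords(oracle[[i]]))), 1e-6)
    }
    # no saved conformation violates the pruning rules
    for (conf in res$conformations) {
      expect_true(steric_ok(conf, p, st$vdw_scale))
      expect_true(improper_ok(conf, p, st$improper_tol))
    }
  }
})

test_that("a box forcing self-intersection saves nothing yet completes", {
  p <- test_params()
  # fully eclipsed backbone (phi = psi = 0) clashes at full radii
  spec <- fragment_spec("VVV", 1, box_named(
    torsion_box(1, -5, 5, -5, 5), torsion_box(2, -5, 5, -5, 5),
    torsion_box(3, -5, 5, -5, 5)))
  st <- enumeration_settings(vdw_scale = 1.0, save_rmsd_gate = -Inf)
  res <- enumerate_fragment(spec, rep(1L, 3), st, p)
  expect_length(res$conformations, 0)
  expect_true(res$complete)
  oracle <- oracle_enumerate("VVV", 1,
                             list(torsion_box(1, -5, 5, -5, 5),
                                  torsion_box(2, -5, 5, -5, 5),
                                  torsion_box(3, -5, 5, -5, 5)),
                             p, st)
  expect_length(oracle, 0)
})

test_that("run_fragment totals compose from per-assignment runs", {
  p <- test_params()
  boxes <- box_named(
    torsion_box(1, -80, -60, -50, -30),
    torsion_box(2, -80, -60, -50, -30), torsion_box(2, -140, -120, 120, 140),
    torsion_box(3, -140, -120, 120, 140),
    torsion_box(4, -80, -60, -50, -30))
  spec <- fragment_spec("AAAA", 1, boxes)
  st <- enumeration_settings(save_rmsd_gate = -Inf, max_branches = 2)
  merged <- run_fragment(spec, st, p)
  expect_equal(merged$N_iBPrun, 2)
  separate <- lapply(box_combinations(spec), function(a) {
    enumerate_fragment(spec, a, st, p)
  })
  expect_equal(merged$N_iBPconf,
               sum(vapply(separate, function(r) unname(r$counters["N_saved"]),
                          numeric(1))))
  expect_equal(length(merged$conformations),
               sum(lengths(lapply(separate, `[[`, "conformations"))))
})

test_that("traversal is deterministic and the save cap flags incompleteness", {
  p <- test_params()
  spec <- fragment_spec("AA", 1, box_named(
    torsion_box(1, -80, -40, -60, -20), torsion_box(2, -80, -40, -60, -20)))
  st <- enumeration_settings(save_rmsd_gate = -Inf)
  r1 <- enumerate_fragment(spec, c(1L, 1L), st, p)
  r2 <- enumerate_fragment(spec, c(1L, 1L), st, p)
  expect_identical(lapply(r1$conformations, coords),
                   lapply(r2$conformations, coords))

  capped <- enumerate_fragment(spec, c(1L, 1L),
                               enumeration_settings(save_rmsd_gate = -Inf,
                                                    max_saved = 3), p)
  expect_false(capped$complete)
  expect_length(capped$conformations, 3)
})

test_that("shrinking a box never increases the saved count (gate disabled)", {
  p <- test_params()
  st <- enumeration_settings(save_rmsd_gate = -Inf)
  count_for <- function(width) {
    spec <- fragment_spec("AA", 1, box_named(
      torsion_box(1, -60 - width, -60 + width, -40 - width, -40 + width),
      torsion_box(2, -120 - width, -120 + width, 130 - width, 130 + width)))
    length(enumerate_fragment(spec, c(1L, 1L), st, p)$conformations)
  }
  counts <- vapply(c(25, 15, 5, 0.01), count_for, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the RMSD save gate thins the saved set against the previous save", {
  p <- test_params()
  spec <- fragment_spec("AAA", 1, box_named(
    torsion_box(1, -170, 170, -60, -20), torsion_box(2, -80, -40, -60, -20),
    torsion_box(3, -80, -40, -60, -20)))
  all_saved <- enumerate_fragment(spec, rep(1L, 3),
                                  enumeration_settings(save_rmsd_gate = -Inf), p)
  gated <- enumerate_fragment(spec, rep(1L, 3),
                              enumeration_settings(save_rmsd_gate = 2), p)
  expect_lt(length(gated$conformations), length(all_saved$conformations))
  expect_gt(length(gated$conformations), 0)
  # successive saved conformations respect the gate
  cas <- lapply(gated$conformations, coords, atom = "CA")
  for (i in seq_len(length(cas) - 1)) {
    expect_gt(kabsch_superpose(cas[[i + 1]], cas[[i]])$rmsd, 2)
  }
})
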