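test_that("gyration radius matches closed-form values", {
  one <- conformation(1, "ALA", "CA", 0, 0, 0)
  expect_equal(gyration_radius(one), 0)
  two <- conformation(1, "ALA", c("CA", "CA"), x = c(0, 2), y = 0, z = 0)
  expect_equal(gyration_radius(two), 1)
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  eight <- conformation(1, "ALA", rep("CA", 8), cube[, 1], cube[, 2],
                        cube[, 3])
  expect_equal(gyration_radius(eight, mass_weighted = FALSE), sqrt(3))
  expect_equal(gyration_radius(eight), sqrt(3))  # equal masses
})

test_that("candidate grid honours both strict distance predicates", {
  linker <- ca_chain(c(1, 4), rbind(c(0, 0, 0), c(0.5, 0, 0)))
  spec <- attachment_spec(1, 4)
  grid <- candidate_grid(linker, spec, r_g = 5, spacing = 2.5)
  # oracle: explicit triple loop over the bounding lattice
  ax <- lapply(1:3, function(k) {
    seq(min(c(0, 0.5, 0, 0, 0, 0)[k * 2 - 1:0]) - 5,
        max(c(0, 0.5)[if (k == 1) 1:2 else 1], 0) + 5, by = 2.5)
  })
  # simpler: rebuild expected from the same definition
  ca <- coords(linker, "CA")
  lo <- apply(ca, 2, min) - 5; hi <- apply(ca, 2, max) + 5
  expected <- 0
  anchor <- c(0.5, 0, 0)
  for (x in seq(lo[1], hi[1], by = 2.5))
    for (y in seq(lo[2], hi[2], by = 2.5))
      for (z in seq(lo[3], hi[3], by = 2.5)) {
        pnt <- c(x, y, z)
        if (vnorm(pnt - anchor) < 5 &&
            min(sqrt(colSums((t(ca) - pnt)^2))) > 2) {
          expected <- expected + 1
        }
      }
  expect_equal(nrow(grid), expected)
  d_anchor <- sqrt(colSums((t(grid) - anchor)^2))
  expect_true(all(d_anchor < 5))
  for (k in seq_len(nrow(grid))) {
    expect_gt(min(sqrt(colSums((t(ca) - grid[k, ])^2))), 2)
  }

  # boundary: lattice points at exactly distance r_g are excluded (strict <)
  single <- ca_chain(c(1, 4), rbind(c(0, 0, 0), c(0, 0, 0)))
  g2 <- candidate_grid(single, attachment_spec(1, 4), r_g = 5, spacing = 2.5)
  d2 <- sqrt(rowSums(g2^2))
  expect_true(all(d2 < 5 & d2 > 2))
  expect_true(any(apply(g2, 1, function(p) all(p == c(2.5, 0, 0)))))
  expect_false(any(apply(g2, 1, function(p) all(p == c(5, 0, 0)))))

  # with spacing 5 every lattice point violates one of the two predicates
  expect_error(candidate_grid(single, attachment_spec(1, 4), r_g = 5,
                              spacing = 5), "no candidate placements")
})

test_that("anchor-aligned placement accepts and rejects by the stated rules", {
  # linker anchors 14 A apart along z; decoration atom keeps it 3D
  linker <- ca_chain(c(1, 2, 4), rbind(c(0, 0, 0), c(30, 30, 0), c(0, 0, 14)))
  # domain anchors 4 A apart, parallel: mean anchor offset = (14 - 4)/2 = 5
  dom <- ca_chain(c(1, 2, 4), rbind(c(5, 5, 0), c(-20, 8, 3), c(5, 5, 4)))
  spec <- attachment_spec(1, 4)
  ctr <- colMeans(coords(dom))
  res <- place_domain(dom, linker, ctr, spec)
  expect_equal(res$mean_anchor_dist, 5, tolerance = 1e-9)
  expect_true(res$accepted)
  # 17 A apart: mean offset 6.5 > 6 rejects
  linker2 <- ca_chain(c(1, 2, 4), rbind(c(0, 0, 0), c(30, 30, 0),
                                        c(0, 0, 17)))
  res2 <- place_domain(dom, linker2, ctr, spec)
  expect_equal(res2$mean_anchor_dist, 6.5, tolerance = 1e-9)
  expect_false(res2$accepted)

  # rigid motion only: intra-domain distances preserved
  expect_equal(as.vector(stats::dist(coords(res$domain))),
               as.vector(stats::dist(coords(dom))), tolerance = 1e-9)
})

test_that("placement aligns anchor vectors, including the anti-parallel case", {
  linker <- ca_chain(c(1, 2, 4), rbind(c(0, 0, 0), c(20, 20, 5), c(0, 0, 10)))
  dom_anti <- ca_chain(c(1, 2, 4), rbind(c(3, 3, 10), c(15, -9, 2),
                                         c(3, 3, 0)))
  spec <- attachment_spec(1, 4)
  res <- place_domain(dom_anti, linker, colMeans(coords(dom_anti)), spec)
  va <- atom_xyz(res$domain, 4, "CA") - atom_xyz(res$domain, 1, "CA")
  vl <- atom_xyz(linker, 4, "CA") - atom_xyz(linker, 1, "CA")
  cosang <- sum(va * vl) / (vnorm(va) * vnorm(vl))
  expect_equal(cosang, 1, tolerance = 1e-9)

  # identical-anchor case: rotation is the identity, translation zero
  dom_same <- ca_chain(c(1, 2, 4), rbind(c(0, 0, 0), c(25, 25, 0),
                                         c(0, 0, 10)))
  res_id <- place_domain(dom_same, linker, colMeans(coords(dom_same)), spec)
  expect_equal(res_id$mean_anchor_dist, 0, tolerance = 1e-9)
  expect_true(res_id$accepted)

  expect_error(place_domain(ca_chain(c(1, 4), rbind(c(0, 0, 0), c(0, 0, 0))),
                            linker, c(0, 0, 0), spec), "degenerate anchors")
})

test_that("acceptance is invariant under a global rigid motion", {
  linker <- ca_chain(c(1, 2, 4), rbind(c(0, 0, 0), c(30, 30, 0),
                                       c(0, 0, 14)))
  dom <- ca_chain(c(1, 2, 4), rbind(c(5, 5, 0), c(-20, 8, 3), c(5, 5, 4)))
  spec <- attachment_spec(1, 4)
  base <- place_domain(dom, linker, colMeans(coords(dom)), spec)
  R <- confenum:::axis_rotation(c(1, 1, 2), 63)
  tr <- c(7, -4, 12)
  res <- place_domain(transform_conformation(dom, R, tr),
                      transform_conformation(linker, R, tr),
                      as.vector(R %*% colMeans(coords(dom))) + tr, spec)
  expect_equal(res$accepted, base$accepted)
  expect_equal(res$mean_anchor_dist, base$mean_anchor_dist, tolerance = 1e-9)
  expect_equal(res$n_clashes, base$n_clashes)
})

test_that("domain-linker merge keeps continuous numbering", {
  dom <- ca_chain(136:238, cbind(3.8 * seq_len(103), 0, 0))
  lnk <- ca_chain(225:280, cbind(3.8 * seq_len(56), 5, 0))
  m <- merge_domain_linker(dom, lnk, 238)
  expect_length(unique(m$resid), 145)
  expect_equal(range(m$resid), c(136, 280))
  expect_error(merge_domain_linker(dom, ca_chain(241:280,
                                                 cbind(seq_len(40), 0, 0)),
                                   238), "not continuous")
})

test_that("second-domain attachment translates by the bridge vector and counts clashes", {
  # reference complex: residues 1-10 (first part incl. bridge 10) and a
  # second domain 20-24 placed far away
  part <- random_helixish(10, seed = 3)
  dom2 <- ca_chain(20:24, cbind(50 + 3.8 * (0:4), 0, 0))
  complex_ <- conformation(
    resid = c(part$resid, dom2$resid),
    resname = c(part$resname, dom2$resname),
    atom = c(part$atom, dom2$atom),
    x = c(part$x, dom2$x), y = c(part$y, dom2$y), z = c(part$z, dom2$z),
    element = c(part$element, dom2$element))
  spec <- second_domain_spec(1:9, bridge_residue = 10, domain_start = 20)
  res <- attach_second_domain(complex_, part, spec)
  expect_true(res$accepted)
  expect_equal(res$n_clashes, 0)
  expect_equal(range(res$conformation$resid), c(1, 24))
  # partial identical: second domain lands exactly at its reference place
  expect_equal(coords(res$conformation[res$conformation$resid >= 20, ]),
               coords(dom2), tolerance = 1e-6)

  # plant exactly 50 clashing atom pairs: strict < 50 rejects
  clash50 <- ca_chain(20:24, coords(part, "CA")[rep(1:10, 5), ] +
                        matrix(c(0.9, 0, 0), 50, 3, byrow = TRUE))
  cplx50 <- conformation(
    resid = c(part$resid, clash50$resid),
    resname = c(part$resname, clash50$resname),
    atom = c(part$atom, clash50$atom),
    x = c(part$x, clash50$x), y = c(part$y, clash50$y),
    z = c(part$z, clash50$z))
  res50 <- attach_second_domain(cplx50, part, spec)
  expect_gte(res50$n_clashes, 50)
  expect_false(res50$accepted)

  expect_error(attach_second_domain(complex_,
                                    part[part$resid <= 9, ], spec),
               "bridge residue absent")
})
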