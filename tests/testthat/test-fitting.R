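prof <- function(vals, absc = seq_along(vals), sig = NULL) {
  observable_profile("PRE", absc, vals, sig)
}

test_that("fit metrics follow their closed forms", {
  a <- prof(c(1, 2, 3)); b <- prof(c(3, 2, 1))
  m <- fit_metrics(a, a)
  expect_equal(c(m$RMS, m$R, m$Q), c(0, 1, 0))

  shifted <- prof(c(1, 2, 3) + 0.7)
  m2 <- fit_metrics(shifted, a)
  expect_equal(m2$RMS, 0.7)
  expect_equal(m2$R, 1)

  m3 <- fit_metrics(a, b)
  expect_equal(m3$R, -1)
  expect_equal(m3$RMS, sqrt(8 / 3))
  expect_equal(m3$Q, sqrt(8 / 3) / sqrt(mean(c(9, 4, 1))))

  expect_error(fit_metrics(a, prof(c(2, 2, 2))), "zero variance")
  expect_error(fit_metrics(a, prof(c(1, 2, 3), absc = 4:6)),
               "different abscissae")
})

test_that("ensemble profiles are pointwise weighted means", {
  p0 <- prof(rep(0, 4)); p4 <- prof(rep(4, 4))
  expect_equal(ensemble_profile(list(p0, p4), c(1, 0))$values, rep(0, 4))
  expect_equal(ensemble_profile(list(p4, p4), c(0.5, 0.5))$values, rep(4, 4))
  expect_equal(ensemble_profile(list(p0, p4), c(0.25, 0.75))$values,
               rep(3, 4))
  expect_error(ensemble_profile(list(p0, p4), 1), "lengths")
})

test_that("greedy selection grows the best-correlating set", {
  obs <- prof(c(1, 5, 2, 8, 3))
  exact <- prof(c(1, 5, 2, 8, 3))
  noise <- prof(c(5, 1, 8, 2, 3))
  sel <- greedy_select(list(noise, exact), obs)
  expect_equal(sel$order[1], 2)
  expect_equal(sel$metrics$R[1], 1)
  expect_equal(sel$metrics$RMS[1], 0)
  expect_lte(sel$metrics$R[2], sel$metrics$R[1])

  # complementary pair: their mean matches, neither alone does
  c1 <- prof(c(2, 0, 2, 0, 2) + c(1, 5, 2, 8, 3))
  c2 <- prof(c(-2, 0, -2, 0, -2) + c(1, 5, 2, 8, 3))
  sel2 <- greedy_select(list(c1, c2), obs)
  expect_gt(sel2$metrics$R[2], sel2$metrics$R[1] - 1e-12)
  expect_equal(sel2$metrics$RMS[2], 0, tolerance = 1e-9)
})

test_that("greedy selection recovers a planted subset on noiseless data", {
  withr::with_seed(21, {
    curves <- lapply(1:10, function(i) prof(stats::rnorm(30)))
    truth <- c(2, 5, 9)
    obs <- ensemble_profile(curves[truth], rep(1, 3))
  })
  sel <- greedy_select(curves, obs, max_size = 5)
  expect_setequal(sel$order[1:3], truth)
  expect_equal(sel$metrics$R[3], 1, tolerance = 1e-9)
  # exhaustive subset oracle confirms no triple beats the planted one
  best <- -Inf; best_set <- NULL
  for (s in utils::combn(10, 3, simplify = FALSE)) {
    r <- stats::cor(ensemble_profile(curves[s], rep(1, 3))$values, obs$values)
    if (r > best) { best <- r; best_set <- s }
  }
  expect_setequal(best_set, truth)
  # R trajectory is non-decreasing up to the optimum
  expect_true(all(diff(sel$metrics$R[1:3]) >= -1e-12))
})

test_that("maximum-entropy reweighting hits its limiting cases", {
  y <- matrix(c(1, 2, 3, 4), 1, 4)
  obs <- prof(c(1.1, 2, 3, 4), sig = rep(0.1, 4))
  single <- maxent_reweight(y, obs)
  expect_equal(single$weights, 1)
  expect_equal(single$S, 0)
  expect_equal(single$chi2, 1)

  withr::with_seed(3, {
    Y <- matrix(stats::rnorm(5 * 20), 5, 20)
  })
  obs2 <- prof(colSums(Y * c(0.5, 0.2, 0.1, 0.1, 0.1)), sig = rep(0.01, 20))
  w0 <- rep(0.2, 5)
  huge_theta <- maxent_reweight(Y, obs2, w0 = w0, theta = 1e8)
  expect_equal(huge_theta$weights, w0, tolerance = 1e-3)

  fit <- maxent_reweight(Y, obs2, theta = 1e-3)
  expect_lte(fit$objective,
             maxent_reweight(Y, obs2, theta = 1e-3, w_init = w0)$objective +
               1e-6)
  expect_lte(fit$S, 1e-12)
  expect_gte(fit$chi2, 0)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_error(maxent_reweight(matrix(c(1, NA), 1, 2), prof(c(1, 2))),
               "non-finite")
})

test_that("an exact three-component mixture is recovered within 0.02", {
  sc <- synthetic_scenario(strrep("A", 15), weights = c(0.6, 0.3, 0.1),
                           noise = 0.01, seed = 3)
  ens <- make_synthetic_ensemble(sc)
  fit <- maxent_reweight(ens$predicted, ens$observed, theta = 0.01)
  expect_equal(fit$weights, c(0.6, 0.3, 0.1), tolerance = 0.02)
  # matches the simplex least-squares oracle as theta -> 0
  Y <- do.call(rbind, lapply(ens$predicted, function(p) p$values))
  w_ls <- oracle_simplex_ls(Y, ens$observed$values, ens$observed$uncertainties)
  expect_equal(fit$weights, w_ls, tolerance = 0.01)
  expect_lte(fit$chi2,
             sum(((colSums(Y * w_ls) - ens$observed$values) /
                    ens$observed$uncertainties)^2) + 1e-3)
})

test_that("two-round fitting finds a dominant conformer and flags degeneracy", {
  sc <- synthetic_scenario(strrep("A", 15), weights = c(1, 0, 0),
                           noise = 0, seed = 5)
  ens <- make_synthetic_ensemble(sc)
  obs <- observable_profile("SAXS", ens$observed$abscissa,
                            ens$observed$values,
                            pmax(0.01 * abs(ens$observed$values), 1e-9))
  tr <- two_round_populations(ens$predicted, obs, theta = 0.01, seed = 2)
  expect_gt(tr$populations$mean[1], 0.99)
  expect_lt(tr$populations$sd[1], 1e-3)
  expect_equal(sum(tr$populations$mean), 1, tolerance = 1e-6)

  # duplicated predicted profile: only the sum is identifiable; run-to-run
  # scatter of the individual populations reveals it (no entropy tie-break)
  dup <- list(ens$predicted[[1]], ens$predicted[[1]], ens$predicted[[2]])
  trd <- two_round_populations(dup, obs, theta = 0, seed = 3)
  expect_equal(trd$populations$mean[1] + trd$populations$mean[2], 1,
               tolerance = 0.01)
  expect_gt(max(trd$populations$sd[1:2]), 1e-3)
})

test_that("coarse Debye curves behave like scattering intensities", {
  pair <- ca_chain(1:2, rbind(c(0, 0, 0), c(8, 0, 0)))
  expect_equal(debye_curve(pair, 0)$values, 4)
  expect_equal(debye_curve(pair, 1e-6)$values, 4, tolerance = 1e-6)

  conf <- random_helixish(10, seed = 4)
  q <- seq(0.1, 4, by = 0.5)
  rot <- transform_conformation(conf,
                                confenum:::axis_rotation(c(0, 1, 1), 35),
                                c(3, 3, 3))
  expect_equal(debye_curve(rot, q)$values, debye_curve(conf, q)$values,
               tolerance = 1e-9)

  # three collinear points, q = 1 nm^-1: direct double sum
  three <- ca_chain(1:3, rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  r_nm <- c(1, 1, 2)
  expected <- 3 + 2 * sum(sin(r_nm) / r_nm)
  expect_equal(debye_curve(three, 1)$values, expected, tolerance = 1e-12)
})

test_that("synthetic PRE ratios saturate, vanish at the probe and increase with distance", {
  ca <- cbind(c(0, 60, 5, 10), 0, 0)
  conf <- ca_chain(1:4, ca)
  conf$atom <- "CA"
  # add N atoms at the CA positions so the profile has amide sites
  withN <- conformation(resid = rep(1:4, each = 2), resname = "ALA",
                        atom = rep(c("N", "CA"), 4),
                        x = rep(ca[, 1], each = 2), y = 0, z = 0)
  pr <- pre_profile(withN, probe_residue = 1)
  expect_lt(pr$values[1], 0.01)
  expect_gt(pr$values[2], 0.99)
  expect_true(all(pr$values >= 0 & pr$values <= 1))
  expect_lte(pr$values[3], pr$values[4])
})

test_that("weighted scalar averages are plain dot products", {
  expect_equal(weighted_scalar(c(24, 26, 28), c(1, 0, 0)), 24)
  expect_equal(weighted_scalar(c(24, 26, 28), rep(1 / 3, 3)), 26)
  vals <- c(24.3, 26.1, 28.9, 31.0, 22.5)
  w <- c(0.6, 0.1, 0.15, 0.03, 0.12)
  expect_equal(weighted_scalar(vals, w), sum(vals * w))
  expect_error(weighted_scalar(1:3, 1:2), "length mismatch")
})
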