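#' Synthetic study scenario
#'
#' Describes a fully synthetic test system: a peptide sequence, per-residue
#' backbone-torsion distributions (mixtures of 2D Gaussians on the torus),
#' planted ensemble weights and an observable noise level. The generator
#' emulates the shape of chemical-shift-derived torsion likelihood maps
#' (localized alpha and/or beta basins) and known-composition conformer
#' ensembles; it does not emulate residue-specific likelihoods of real
#' predictions.
#'
#' @param sequence one-letter peptide sequence.
#' @param start_resid first residue id (default 1).
#' @param modes either one data.frame applied to all residues or a list (one
#'   per residue) of data.frames with columns `phi`, `psi` (mode centres,
#'   degrees), `sd` (isotropic width, degrees) and `weight` (mixture weight,
#'   summing to 1). Default: an alpha mode at (-65, -45) and a beta mode at
#'   (-120, 130), equal weights, sd 10.
#' @param weights planted ensemble populations (default `c(0.6, 0.3, 0.1)`).
#' @param noise relative observable noise level (default 0.01).
#' @param q_grid scattering vectors for synthetic curves (nm^-1).
#' @param pre_probes residue ids carrying synthetic spin labels; their PRE
#'   profiles are stacked with the scattering curve into the fitted
#'   observable (`NULL` = scattering only). Distance-steep PRE blocks make
#'   the synthetic observable discriminate conformers that global
#'   shape curves alone cannot.
#' @param seed integer seed.
#' @return a `SyntheticScenario` list.
#' @export
synthetic_scenario <- function(sequence, start_resid = 1L, modes = NULL,
                               weights = c(0.6, 0.3, 0.1), noise = 0.01,
                               q_grid = seq(0.1, 5, by = 0.1),
                               pre_probes = NULL, seed = 1L) {
  if (is.null(modes)) {
    modes <- data.frame(phi = c(-65, -120), psi = c(-45, 130),
                        sd = 10, weight = 0.5)
  }
  n <- nchar(sequence)
  if (is.data.frame(modes)) modes <- rep(list(modes), n)
  stopifnot(length(modes) == n, all(weights >= 0), noise >= 0)
  for (m in modes) stopifnot(abs(sum(m$weight) - 1) < 1e-9)
  structure(list(sequence = sequence, start_resid = as.integer(start_resid),
                 modes = modes, weights = weights / sum(weights),
                 noise = noise, q_grid = q_grid, pre_probes = pre_probes,
                 seed = as.integer(seed)),
            class = "SyntheticScenario")
}

# wrapped (toroidal) isotropic Gaussian density at offsets dphi, dpsi (deg)
wrapped_gauss <- function(dphi, dpsi, sd) {
  acc <- 0
  for (kx in -1:1) for (ky in -1:1) {
    acc <- acc + exp(-((dphi + 360 * kx)^2 + (dpsi + 360 * ky)^2) / (2 * sd^2))
  }
  acc
}

#' Synthetic torsion likelihood maps
#'
#' Integrates each residue's planted torus-Gaussian mixture over the 324
#' Ramachandran voxels (by mid-point sub-sampling) and normalizes, giving
#' maps in the same form as chemical-shift-based likelihood predictions.
#'
#' @param scenario a `SyntheticScenario`.
#' @param subdiv sub-samples per voxel axis used for the integration
#'   (default 5).
#' @return list of `TorsionLikelihoodMap`, one per residue.
#' @export
make_synthetic_maps <- function(scenario, subdiv = 5L) {
  centers <- voxel_centers()
  sub_off <- (seq_len(subdiv) - (subdiv + 1) / 2) * (20 / subdiv)
  out <- list()
  for (i in seq_len(nchar(scenario$sequence))) {
    rid <- scenario$start_resid + i - 1L
    m <- scenario$modes[[i]]
    grid <- matrix(0, 18, 18)
    for (a in 1:18) for (b in 1:18) {
      pts_phi <- centers[a] + sub_off
      pts_psi <- centers[b] + sub_off
      acc <- 0
      for (k in seq_len(nrow(m))) {
        dphi <- outer(pts_phi - m$phi[k], rep(1, subdiv))
        dpsi <- outer(rep(1, subdiv), pts_psi - m$psi[k])
        acc <- acc + m$weight[k] * sum(wrapped_gauss(dphi, dpsi, m$sd[k]))
      }
      grid[a, b] <- acc / subdiv^2
    }
    out[[as.character(rid)]] <- normalize_map(torsion_likelihood_map(rid, grid))
  }
  out
}

#' Synthetic conformer ensemble with observables
#'
#' Builds one conformer per planted weight by sampling each residue's
#' torsions from its mixture, computes per-conformer scattering curves with
#' the coarse Debye predictor, and mixes them under the planted weights with
#' multiplicative Gaussian noise at the stated level. Deterministic given
#' the scenario seed.
#'
#' @param scenario a `SyntheticScenario`.
#' @return list with `conformations`, `weights` (planted), `predicted`
#'   (per-conformer `ObservableProfile`s), and `observed` (noisy mixture
#'   profile with uncertainties `noise * value`).
#' @export
make_synthetic_ensemble <- function(scenario) {
  withr::with_seed(scenario$seed, {
    n_conf <- length(scenario$weights)
    n_res <- nchar(scenario$sequence)
    confs <- lapply(seq_len(n_conf), function(k) {
      phi <- numeric(n_res); psi <- numeric(n_res)
      for (i in seq_len(n_res)) {
        m <- scenario$modes[[i]]
        j <- sample.int(nrow(m), 1, prob = m$weight)
        phi[i] <- wrap180(stats::rnorm(1, m$phi[j], m$sd[j]))
        psi[i] <- wrap180(stats::rnorm(1, m$psi[j], m$sd[j]))
      }
      phi[1] <- NA
      build_backbone(scenario$sequence, phi, psi,
                     start_resid = scenario$start_resid)
    })
    saxs <- lapply(confs, debye_curve, q_grid = scenario$q_grid)
    predicted <- saxs
    if (!is.null(scenario$pre_probes)) {
      # stack PRE blocks after the scattering block; the fitting machinery
      # only needs matched abscissae, so the stacked profile is indexed 1..K
      stacked <- lapply(seq_along(confs), function(k) {
        vals <- saxs[[k]]$values
        for (pr in scenario$pre_probes) {
          vals <- c(vals, pre_profile(confs[[k]], pr)$values)
        }
        observable_profile("SAXS", seq_along(vals), vals)
      })
      predicted <- stacked
    }
    mix <- ensemble_profile(predicted, scenario$weights)
    noise_sd <- scenario$noise * abs(mix$values)
    noisy <- mix$values + stats::rnorm(length(mix$values), 0, noise_sd)
    observed <- observable_profile(mix$kind, mix$abscissa, noisy,
                                   pmax(noise_sd, 1e-12))
    list(conformations = confs, weights = scenario$weights,
         predicted = predicted, saxs = saxs, observed = observed)
  })
}
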