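#' Agreement metrics between calculated and observed profiles
#'
#' RMS is the root-mean-square deviation (profile units), R the Pearson
#' correlation, and Q the normalized deviation
#' `rms(calc - obs) / rms(obs)` (standard NMR convention; switch
#' `q_norm = "rms_diff"` for plain rms(calc - obs) normalization by 1).
#'
#' @param calc,obs `ObservableProfile`s on matching abscissae.
#' @param q_norm `"rms_obs"` (default) or `"rms_diff"`.
#' @return list of class `FitMetrics` with `RMS`, `R`, `Q`.
#' @export
#' @examples
#' a <- observable_profile("PRE", 1:3, c(1, 2, 3))
#' b <- observable_profile("PRE", 1:3, c(3, 2, 1))
#' fit_metrics(a, b)$R  # -1
fit_metrics <- function(calc, obs, q_norm = c("rms_obs", "rms_diff")) {
  q_norm <- match.arg(q_norm)
  if (!isTRUE(all.equal(calc$abscissa, obs$abscissa))) {
    stop("profiles have different abscissae")
  }
  d <- calc$values - obs$values
  rms <- sqrt(mean(d^2))
  if (stats::sd(obs$values) == 0) {
    stop("observed profile has zero variance; R undefined")
  }
  r <- stats::cor(calc$values, obs$values)
  q <- if (q_norm == "rms_obs") rms / sqrt(mean(obs$values^2)) else rms
  structure(list(RMS = rms, R = r, Q = q), class = "FitMetrics")
}

#' Population-weighted ensemble profile
#'
#' @param members list of `ObservableProfile`s sharing an abscissa.
#' @param weights numeric weights, one per member (need not be normalized;
#'   they are renormalized to sum 1).
#' @return the pointwise weighted-mean `ObservableProfile`.
#' @export
ensemble_profile <- function(members, weights) {
  if (length(members) != length(weights)) {
    stop("lengths of members and weights differ")
  }
  w <- weights / sum(weights)
  vals <- Reduce(`+`, Map(function(m, wi) wi * m$values, members, as.list(w)))
  observable_profile(members[[1]]$kind, members[[1]]$abscissa, vals,
                     members[[1]]$uncertainties)
}

#' Greedy forward selection of conformers against an observed profile
#'
#' Starting from the single conformer whose profile correlates best with the
#' observation, each step adds the candidate maximizing the Pearson R of the
#' equal-weight ensemble profile of the enlarged set. The full metrics
#' trajectory is returned so the caller can pick the set size where RMS and
#' Q are minimal and R maximal.
#'
#' @param candidates list of per-conformer `ObservableProfile`s.
#' @param obs observed `ObservableProfile`.
#' @param max_size largest set size to grow to (default all candidates).
#' @return list with `order` (candidate indices in selection order) and
#'   `metrics` (data.frame with `size`, `RMS`, `R`, `Q`).
#' @export
greedy_select <- function(candidates, obs, max_size = length(candidates)) {
  stopifnot(length(candidates) >= 1)
  chosen <- integer(0)
  metrics <- data.frame(size = integer(0), RMS = numeric(0), R = numeric(0),
                        Q = numeric(0))
  while (length(chosen) < min(max_size, length(candidates))) {
    remaining <- setdiff(seq_along(candidates), chosen)
    best_r <- -Inf; best_i <- remaining[1]
    for (i in remaining) {
      prof <- ensemble_profile(candidates[c(chosen, i)],
                               rep(1, length(chosen) + 1))
      r <- stats::cor(prof$values, obs$values)
      if (r > best_r) { best_r <- r; best_i <- i }
    }
    chosen <- c(chosen, best_i)
    m <- fit_metrics(ensemble_profile(candidates[chosen],
                                      rep(1, length(chosen))), obs)
    metrics <- rbind(metrics, data.frame(size = length(chosen), RMS = m$RMS,
                                         R = m$R, Q = m$Q))
  }
  list(order = chosen, metrics = metrics)
}

#' Maximum-entropy ensemble reweighting
#'
#' Determines conformer populations `w` on the simplex minimizing
#' `chi^2 / 2 - theta * S`, where
#' `chi^2 = sum_j ((sum_i w_i y_ij - obs_j) / sigma_j)^2` and
#' `S = -sum_i w_i log(w_i / w0_i)` is the relative entropy to the reference
#' populations `w0` (S <= 0, zero only at `w = w0`). The optimization runs
#' in softmax-reparameterized coordinates with an analytic gradient
#' (BFGS), which enforces the simplex constraint exactly; if the start
#' point leads somewhere worse than `w0`, the fit is restarted from `w0`.
#'
#' @param predicted list of per-conformer `ObservableProfile`s, or a matrix
#'   (rows = conformers, columns = points).
#' @param obs observed `ObservableProfile`; its `uncertainties` are used as
#'   `sigma` when present, else `sigma = 1`.
#' @param w0 reference populations (default uniform).
#' @param theta entropy-regularization strength (default 10).
#' @param w_init optional starting populations (default `w0`).
#' @param max_iter mirror-descent iteration cap (default 2000).
#' @return a `MaxEntResult`: list with `weights`, `w0`, `chi2`, `S`,
#'   `objective`.
#' @export
maxent_reweight <- function(predicted, obs, w0 = NULL, theta = 10,
                            w_init = NULL, max_iter = 2000L) {
  Y <- profiles_to_matrix(predicted)
  if (any(!is.finite(Y))) stop("non-finite predicted profiles")
  y_obs <- obs$values
  sig <- if (!is.null(obs$uncertainties)) obs$uncertainties else
    rep(1, length(y_obs))
  n <- nrow(Y)
  if (is.null(w0)) w0 <- rep(1 / n, n)
  stopifnot(theta >= 0, all(w0 > 0), abs(sum(w0) - 1) < 1e-6)
  if (is.null(w_init)) w_init <- w0
  if (n == 1) {
    chi2 <- sum(((Y[1, ] - y_obs) / sig)^2)
    return(structure(list(weights = 1, w0 = w0, chi2 = chi2, S = 0,
                          objective = chi2 / 2), class = "MaxEntResult"))
  }
  objective_w <- function(w) {
    yhat <- as.vector(t(Y) %*% w)
    chi2 <- sum(((yhat - y_obs) / sig)^2)
    S <- -sum(w * log(w / w0))
    list(chi2 = chi2, S = S, obj = chi2 / 2 - theta * S)
  }
  grad_w <- function(w) {
    yhat <- as.vector(t(Y) %*% w)
    as.vector(Y %*% ((yhat - y_obs) / sig^2)) + theta * (log(w / w0) + 1)
  }
  # mirror descent (exponentiated gradient) with backtracking: the
  # multiplicative update respects the simplex and keeps iterates interior
  mirror_descent <- function(w) {
    w <- pmax(w, 1e-12); w <- w / sum(w)
    obj <- objective_w(w)$obj
    eta <- 1 / (1 + max(abs(grad_w(w))))
    for (it in seq_len(max_iter)) {
      g <- grad_w(w)
      g <- g - sum(w * g)
      improved <- FALSE
      for (bt in 1:40) {
        step <- eta * g
        step <- step - max(step)      # overflow guard
        w_new <- w * exp(-step)
        w_new <- pmax(w_new, 1e-300)
        w_new <- w_new / sum(w_new)
        obj_new <- objective_w(w_new)$obj
        if (is.finite(obj_new) && obj_new < obj) { improved <- TRUE; break }
        eta <- eta / 2
      }
      if (!improved) break
      if (obj - obj_new < 1e-12 * (1 + abs(obj))) { w <- w_new; break }
      w <- w_new; obj <- obj_new
      eta <- eta * 1.5
    }
    w
  }
  # damped Newton polish in softmax coordinates (analytic Hessian); the
  # chi-squared part is quadratic in w, so Newton handles the strong
  # ill-conditioning that first-order steps cannot
  A_ <- sweep(Y, 2, sig, "/")
  b_ <- y_obs / sig
  polish <- function(w_start) {
    a <- log(pmax(w_start, 1e-12))
    w <- softmax(a)
    obj <- objective_w(w)$obj
    lambda <- 1e-8
    for (it in 1:200) {
      g <- grad_w(w)
      u <- w * g
      g_a <- u - w * sum(u)
      if (sqrt(sum(g_a^2)) < 1e-12 * (1 + abs(obj))) break
      Hw <- A_ %*% t(A_) + diag(theta / w, n)
      J <- diag(w, n) - tcrossprod(w)
      s <- sum(u)
      Ha <- J %*% Hw %*% J + diag(u, n) - tcrossprod(u, w) -
        tcrossprod(w, u) + 2 * s * tcrossprod(w) - s * diag(w, n)
      step <- NULL
      for (bt in 1:60) {
        step <- tryCatch(solve(Ha + diag(lambda, n), -g_a),
                         error = function(e) NULL)
        if (!is.null(step)) {
          a_new <- a + step
          a_new <- a_new - max(a_new)
          w_new <- softmax(a_new)
          obj_new <- objective_w(w_new)$obj
          if (is.finite(obj_new) && obj_new <= obj) break
        }
        lambda <- lambda * 10
      }
      if (is.null(step) || !is.finite(obj_new) || obj_new > obj) break
      improved <- obj - obj_new
      a <- a_new; w <- w_new; obj <- obj_new
      lambda <- max(lambda / 10, 1e-10)
      if (improved < 1e-14 * (1 + abs(obj))) break
    }
    w
  }
  w <- mirror_descent(pmax(w_init, 1e-12) / sum(pmax(w_init, 1e-12)))
  w_p <- polish(w)
  if (objective_w(w_p)$obj < objective_w(w)$obj) w <- w_p
  if (objective_w(w)$obj > objective_w(w0)$obj + 1e-9) {
    w_alt <- polish(mirror_descent(w0))
    if (objective_w(w_alt)$obj < objective_w(w)$obj) w <- w_alt
  }
  parts <- objective_w(w)
  structure(list(weights = w, w0 = w0, chi2 = parts$chi2, S = parts$S,
                 objective = parts$obj), class = "MaxEntResult")
}

softmax <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

profiles_to_matrix <- function(predicted) {
  if (is.matrix(predicted)) return(predicted)
  do.call(rbind, lapply(predicted, function(p) p$values))
}

#' Two-round population determination
#'
#' Round one runs `n_runs` maximum-entropy fits from random points on the
#' simplex; conformers whose populations summed over the runs exceed
#' `keep_threshold` are gathered, and round two repeats `n_runs` fits on the
#' reduced set. Reported populations are the per-conformer mean and standard
#' deviation over the second-round runs (means renormalized to sum 1);
#' `chi2` and `S` are second-round means.
#'
#' @inheritParams maxent_reweight
#' @param n_runs fits per round (default 10).
#' @param keep_threshold keep conformers with summed round-one population
#'   strictly above this (default 0.01).
#' @param seed integer seed for the random starts.
#' @return list with `populations` (data.frame: `conformer`, `mean`, `sd`;
#'   dropped conformers have zero mean and sd), `kept` (indices),
#'   `chi2`, `chi2_sd`, `S`, `S_sd`.
#' @export
two_round_populations <- function(predicted, obs, n_runs = 10L,
                                  keep_threshold = 0.01, theta = 10,
                                  seed = 1L, w0 = NULL) {
  Y <- profiles_to_matrix(predicted)
  n <- nrow(Y)
  if (is.null(w0)) w0 <- rep(1 / n, n)
  withr::with_seed(seed, {
    random_simplex <- function(k) {
      g <- -log(stats::runif(k))
      g / sum(g)
    }
    run_round <- function(Ysub, w0sub) {
      vapply(seq_len(n_runs), function(r) {
        maxent_reweight(Ysub, obs, w0 = w0sub, theta = theta,
                        w_init = random_simplex(nrow(Ysub)))$weights
      }, numeric(nrow(Ysub)))
    }
    W1 <- run_round(Y, w0)                       # n x n_runs
    keep <- which(rowSums(W1) > keep_threshold)
    if (length(keep) == 0) stop("all conformers filtered in round one")
    w0k <- rep(1 / length(keep), length(keep))
    W2 <- run_round(Y[keep, , drop = FALSE], w0k)
    if (is.null(dim(W2))) W2 <- matrix(W2, nrow = 1)
    fits <- lapply(seq_len(n_runs), function(r) {
      maxent_reweight(Y[keep, , drop = FALSE], obs, w0 = w0k, theta = theta,
                      w_init = W2[, r])
    })
    mu <- rowMeans(W2)
    mu <- mu / sum(mu)
    sds <- apply(W2, 1, stats::sd)
    pops <- data.frame(conformer = seq_len(n), mean = 0, sd = 0)
    pops$mean[keep] <- mu
    pops$sd[keep] <- sds
    list(populations = pops, kept = keep,
         chi2 = mean(vapply(fits, `[[`, numeric(1), "chi2")),
         chi2_sd = stats::sd(vapply(fits, `[[`, numeric(1), "chi2")),
         S = mean(vapply(fits, `[[`, numeric(1), "S")),
         S_sd = stats::sd(vapply(fits, `[[`, numeric(1), "S")))
  })
}

#' Coarse Debye scattering curve
#'
#' Small-angle scattering intensity from the CA trace with unit form
#' factors: `I(q) = sum_ij sin(q r_ij) / (q r_ij)` over all CA pairs
#' (diagonal included), with the sinc limit at q = 0 so `I(0) = n^2`.
#' A deliberately coarse predictor for synthetic tests and qualitative
#' shapes; it models no solvation layer.
#'
#' @param conf a `Conformation` with at least 2 CA atoms.
#' @param q_grid scattering vectors in inverse nanometres.
#' @return an `ObservableProfile` of kind `"SAXS"`.
#' @export
debye_curve <- function(conf, q_grid) {
  ca <- coords(conf, "CA")
  n <- nrow(ca)
  if (n < 2) stop("need >= 2 CA atoms")
  r_nm <- as.vector(stats::dist(ca)) / 10
  vals <- vapply(q_grid, function(q) {
    if (q == 0) return(n^2)
    qr <- q * r_nm
    n + 2 * sum(sin(qr) / qr)
  }, numeric(1))
  observable_profile("SAXS", q_grid, vals)
}

#' Synthetic paramagnetic relaxation enhancement profile
#'
#' Back-calculates a per-residue intensity-ratio profile from a single spin
#' label placed at the probe residue's CB (CA when CB is absent):
#' `ratio_i = exp(-k / r_i^6)` with `r_i` the distance from the probe site
#' to residue i's amide nitrogen. The calibration constant `k` sets the
#' half-attenuation distance (default 15 Angstrom). This is a declared
#' approximation for synthetic tests and qualitative profiles, not a
#' spin-dynamics calculation.
#'
#' @param conf a `Conformation`.
#' @param probe_residue residue carrying the label.
#' @param r_half distance at which the ratio is 0.5 (Angstrom, default 15).
#' @return an `ObservableProfile` of kind `"PRE"` with values in \[0, 1\].
#' @export
pre_profile <- function(conf, probe_residue, r_half = 15) {
  probe <- atom_xyz(conf, probe_residue, "CB")
  if (is.null(probe)) probe <- atom_xyz(conf, probe_residue, "CA")
  if (is.null(probe)) stop("probe residue absent")
  k <- log(2) * r_half^6
  rids <- sort(unique(conf$resid))
  vals <- vapply(rids, function(r) {
    nn <- atom_xyz(conf, r, "N")
    if (is.null(nn)) nn <- atom_xyz(conf, r, "CA")
    d <- max(vnorm(nn - probe), 1e-3)
    exp(-k / d^6)
  }, numeric(1))
  observable_profile("PRE", rids, vals)
}

#' Population-weighted scalar average
#'
#' @param values per-conformer scalar values (e.g. radii of gyration).
#' @param weights populations, same length.
#' @return `sum(weights * values)`.
#' @export
weighted_scalar <- function(values, weights) {
  if (length(values) != length(weights)) stop("length mismatch")
  sum(weights * values)
}
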