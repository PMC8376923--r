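# Independent oracles and small fixture builders used across the suite.

# internal helpers used in assertions
vnorm <- confenum:::vnorm
atom_xyz <- confenum:::atom_xyz
wrap180 <- confenum:::wrap180

test_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_params()
    cache
  }
})

# --- flood-fill component oracle (iterative label propagation, toroidal) ----
# Different algorithm from the package's BFS: repeated minimum-label passes.
oracle_components <- function(voxels, n = 18L) {
  m <- nrow(voxels)
  labels <- seq_len(m)
  key <- paste(voxels[, 1], voxels[, 2])
  lookup <- stats::setNames(seq_len(m), key)
  repeat {
    changed <- FALSE
    for (v in seq_len(m)) {
      for (da in -1:1) for (db in -1:1) {
        if (da == 0 && db == 0) next
        na <- ((voxels[v, 1] - 1 + da) %% n) + 1
        nb <- ((voxels[v, 2] - 1 + db) %% n) + 1
        u <- lookup[paste(na, nb)]
        if (!is.na(u) && labels[u] < labels[v]) {
          labels[v] <- labels[u]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# --- brute-force torsion-grid enumeration oracle ----------------------------
# Builds every sampled torsion combination by sequential Cartesian
# construction (build_backbone), applies the same steric filter, and returns
# conformations in the enumerator's traversal order.
oracle_slot_values <- function(lo, hi, kind, params,
                               settings = enumeration_settings()) {
  ar <- confenum:::interval_abs_range(lo, hi)
  dd <- sort(c(torsion_to_distance(ar[2], kind, params),
               torsion_to_distance(ar[1], kind, params)))
  samples <- discretize_interval(dd[1], dd[2], settings$max_branches,
                                 settings$min_step, settings$tolerance)
  unlist(lapply(samples, function(d) {
    t <- distance_to_torsion(d, kind, params)
    cand <- unique(confenum:::wrap180(c(t, -t)))
    keep <- vapply(cand, confenum:::angle_in_interval, logical(1),
                   lo = lo, hi = hi, slack = settings$angle_slack)
    sort(cand[keep], decreasing = TRUE)
  }))
}

oracle_enumerate <- function(sequence, start_resid, box_list, params,
                             settings = enumeration_settings(),
                             dummy_phi = -139, dummy_psi = 135) {
  n <- nchar(sequence)
  resids <- start_resid + seq_len(n) - 1L
  slots <- list()
  for (i in seq_len(n)) {
    b <- box_list[[i]]
    slots[[length(slots) + 1L]] <-
      oracle_slot_values(b$phi_lo, b$phi_hi, "phi", params, settings)
    slots[[length(slots) + 1L]] <-
      oracle_slot_values(b$psi_lo, b$psi_hi, "psi", params, settings)
  }
  combos <- expand.grid(rev(slots), KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, rev(seq_along(slots)), drop = FALSE]
  full_seq <- paste0("A", sequence, "A")
  out <- list()
  for (row in seq_len(nrow(combos))) {
    tor <- as.numeric(combos[row, ])
    phi <- c(NA, tor[seq(1, 2 * n, by = 2)], dummy_phi)
    psi <- c(dummy_psi, tor[seq(2, 2 * n, by = 2)], 180)
    conf <- build_backbone(full_seq, phi, psi, params = params,
                           start_resid = start_resid - 1L)
    conf <- conf[!(conf$resid == start_resid + n & conf$atom == "O"), ,
                 drop = FALSE]
    if (!steric_ok(conf, params, settings$vdw_scale)) next
    keep <- conf[conf$resid %in% resids, , drop = FALSE]
    ord <- order(keep$resid, match(keep$atom, c("N", "CA", "C", "O", "CB")))
    keep <- keep[ord, , drop = FALSE]
    rownames(keep) <- NULL
    out[[length(out) + 1L]] <- keep
  }
  out
}

# --- rotation-grid superposition oracle -------------------------------------
rot_matrix_euler <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

oracle_min_rmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  rmsd_of <- function(R) sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  best <- Inf; best_abc <- c(0, 0, 0)
  coarse <- seq(0, 2 * pi, length.out = 13)[-13]
  beta <- seq(0, pi, length.out = 7)
  for (a in coarse) for (b in beta) for (c in coarse) {
    r <- rmsd_of(rot_matrix_euler(a, b, c))
    if (r < best) { best <- r; best_abc <- c(a, b, c) }
  }
  step <- pi / 6
  for (refine in 1:5) {
    step <- step / 4
    grid <- seq(-2, 2) * step
    for (da in grid) for (db in grid) for (dc in grid) {
      abc <- best_abc + c(da, db, dc)
      r <- rmsd_of(rot_matrix_euler(abc[1], abc[2], abc[3]))
      if (r < best) { best <- r; best_abc <- abc }
    }
  }
  best
}

# --- simplex-constrained least squares oracle (active set) ------------------
oracle_simplex_ls <- function(Y, y_obs, sig = NULL) {
  n <- nrow(Y)
  if (is.null(sig)) sig <- rep(1, length(y_obs))
  A <- sweep(Y, 2, sig, "/")
  b <- y_obs / sig
  active <- rep(TRUE, n)
  for (iter in seq_len(2 * n)) {
    idx <- which(active)
    k <- length(idx)
    # minimize |A[idx,]^T w - b|^2 s.t. sum w = 1 (Lagrange KKT system)
    M <- A[idx, , drop = FALSE] %*% t(A[idx, , drop = FALSE])
    KKT <- rbind(cbind(2 * M, 1), c(rep(1, k), 0))
    rhs <- c(2 * as.vector(A[idx, , drop = FALSE] %*% b), 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) {
      solve(KKT + diag(1e-10, k + 1), rhs)
    })
    w <- sol[seq_len(k)]
    if (all(w >= -1e-12)) {
      out <- rep(0, n)
      out[idx] <- pmax(w, 0)
      return(out / sum(out))
    }
    active[idx[which.min(w)]] <- FALSE
  }
  stop("active-set oracle failed to converge")
}

# --- small conformer builders -----------------------------------------------
random_helixish <- function(n_res, seed, phi0 = -65, psi0 = -45, sd = 8,
                            start_resid = 1L) {
  withr::with_seed(seed, {
    build_backbone(strrep("A", n_res),
                   phi = c(NA, stats::rnorm(n_res - 1, phi0, sd)),
                   psi = c(stats::rnorm(n_res - 1, psi0, sd), 180),
                   start_resid = start_resid)
  })
}

# bare coordinate-table conformation (not necessarily physical)
ca_chain <- function(resids, ca_xyz, resname = "ALA") {
  conformation(resid = resids, resname = resname, atom = "CA",
               x = ca_xyz[, 1], y = ca_xyz[, 2], z = ca_xyz[, 3],
               element = "C")
}
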