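#' Backbone torsion to interatomic distance and back
#'
#' The backbone dihedrals phi and psi are equivalent to 1-4 interatomic
#' distances: phi(i) to the C(i-1)...C(i) distance and psi(i) to the
#' N(i)...N(i+1) distance, through the standard relation between a torsion
#' angle and the distance across the four atoms defining it. Because the
#' relation depends only on cos(torsion), d(x) = d(-x) and d is strictly
#' monotone in |x|; `distance_to_torsion` therefore returns the magnitude.
#'
#' @param angle torsion angle in degrees, in \[-180, 180\].
#' @param kind one of `"phi"`, `"psi"`, `"omega"`.
#' @param params a `ForceFieldParams` object (see [load_params()]).
#' @return `torsion_to_distance`: the 1-4 distance in Angstrom;
#'   `distance_to_torsion`: the torsion magnitude in degrees in \[0, 180\].
#' @export
#' @examples
#' p <- load_params()
#' torsion_to_distance(-65, "phi", p)
#' distance_to_torsion(torsion_to_distance(-65, "phi", p), "phi", p)  # 65
torsion_to_distance <- function(angle, kind, params) {
  g <- torsion_chain_geometry(kind, params)
  d14(g$r1, g$r2, g$r3, g$th1, g$th2, angle)
}

#' @rdname torsion_to_distance
#' @param distance 1-4 distance in Angstrom.
#' @export
distance_to_torsion <- function(distance, kind, params) {
  g <- torsion_chain_geometry(kind, params)
  c1 <- cos(g$th1 * pi / 180); s1 <- sin(g$th1 * pi / 180)
  c2 <- cos(g$th2 * pi / 180); s2 <- sin(g$th2 * pi / 180)
  num <- g$r1^2 + g$r2^2 + g$r3^2 -
    2 * g$r1 * g$r2 * c1 - 2 * g$r2 * g$r3 * c2 +
    2 * g$r1 * g$r3 * c1 * c2 - distance^2
  cosom <- num / (2 * g$r1 * g$r3 * s1 * s2)
  acos(max(-1, min(1, cosom))) * 180 / pi
}

# the four-atom chain behind each backbone torsion
torsion_chain_geometry <- function(kind, params) {
  if (kind == "phi") {
    # C(i-1) - N(i) - CA(i) - C(i)
    list(r1 = bond_length(params, "C", "N"),
         r2 = bond_length(params, "N", "CA"),
         r3 = bond_length(params, "CA", "C"),
         th1 = bond_angle(params, "C", "N", "CA"),
         th2 = bond_angle(params, "N", "CA", "C"))
  } else if (kind == "psi") {
    # N(i) - CA(i) - C(i) - N(i+1)
    list(r1 = bond_length(params, "N", "CA"),
         r2 = bond_length(params, "CA", "C"),
         r3 = bond_length(params, "C", "N"),
         th1 = bond_angle(params, "N", "CA", "C"),
         th2 = bond_angle(params, "CA", "C", "N"))
  } else if (kind == "omega") {
    # CA(i) - C(i) - N(i+1) - CA(i+1)
    list(r1 = bond_length(params, "CA", "C"),
         r2 = bond_length(params, "C", "N"),
         r3 = bond_length(params, "N", "CA"),
         th1 = bond_angle(params, "CA", "C", "N"),
         th2 = bond_angle(params, "C", "N", "CA"))
  } else {
    stop("unsupported torsion: ", kind)
  }
}

# 1-4 distance across a chain with bonds r1,r2,r3, angles th1,th2 (deg),
# torsion om (deg)
d14 <- function(r1, r2, r3, th1, th2, om) {
  c1 <- cos(th1 * pi / 180); s1 <- sin(th1 * pi / 180)
  c2 <- cos(th2 * pi / 180); s2 <- sin(th2 * pi / 180)
  d2 <- r1^2 + r2^2 + r3^2 - 2 * r1 * r2 * c1 - 2 * r2 * r3 * c2 +
    2 * r1 * r3 * (c1 * c2 - s1 * s2 * cos(om * pi / 180))
  sqrt(d2)
}

# 1-3 distance across bonds r1, r2 with angle th (deg)
d13 <- function(r1, r2, th) {
  sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(th * pi / 180))
}

#' Trilaterate a point from three reference points
#'
#' Solves for the positions at given distances from three non-collinear
#' reference points (sphere intersection). There are zero, one (tangency) or
#' two solutions; when two exist they are mirror images through the plane of
#' the references.
#'
#' @param refs 3x3 matrix, one reference point per row.
#' @param d numeric length-3: target distances to the three references.
#' @param tol absolute tolerance on the squared out-of-plane coordinate used
#'   to decide tangency versus infeasibility.
#' @return a matrix with 0, 1 or 2 rows (candidate points).
#' @export
#' @examples
#' refs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' trilaterate(refs, c(1, 1, 1))
trilaterate <- function(refs, d, tol = 1e-9) {
  stopifnot(is.matrix(refs), nrow(refs) == 3, length(d) == 3)
  A <- refs[1, ]; B <- refs[2, ]; C <- refs[3, ]
  ex <- B - A
  nex <- vnorm(ex)
  cr <- pracma_cross(ex, C - A)
  if (nex < 1e-12 || vnorm(cr) / max(nex, 1) < 1e-10) {
    stop("degenerate trilateration: collinear reference points")
  }
  ex <- ex / nex
  i <- sum(ex * (C - A))
  ey <- C - A - i * ex
  ey <- ey / vnorm(ey)
  ez <- pracma_cross(ex, ey)
  j <- sum(ey * (C - A))
  x <- (d[1]^2 - d[2]^2 + nex^2) / (2 * nex)
  y <- (d[1]^2 - d[3]^2 + i^2 + j^2 - 2 * i * x) / (2 * j)
  z2 <- d[1]^2 - x^2 - y^2
  scale <- 1 + d[1]^2
  if (z2 < -tol * scale) return(matrix(numeric(0), ncol = 3))
  if (z2 <= tol * scale) {
    return(matrix(A + x * ex + y * ey, nrow = 1))
  }
  z <- sqrt(z2)
  rbind(A + x * ex + y * ey + z * ez,
        A + x * ex + y * ey - z * ez)
}

#' Discretize an interval distance into branch samples
#'
#' The interval is first widened by `tolerance` on both sides (guarding
#' against pruning by slight numerical discrepancies), then split into equal
#' sub-intervals whose midpoints are the sampled distances. The number of
#' samples is `min(max_branches, max(1, floor(width / min_step)))`, so small
#' intervals are not over-sampled and wide ones are capped.
#'
#' @param lo,hi interval bounds (Angstrom), `lo <= hi`.
#' @param max_branches maximum number of branches per interval (default 4).
#' @param min_step minimum discretization step in Angstrom (default 0.1).
#' @param tolerance widening added to each bound (default 0.05 Angstrom).
#' @return numeric vector of sampled distances, ascending.
#' @export
#' @examples
#' discretize_interval(3, 3)           # one sample at 3.0
#' discretize_interval(2, 3)           # four samples (cap)
discretize_interval <- function(lo, hi, max_branches = 4L,
                                min_step = 0.1, tolerance = 0.05) {
  stopifnot(lo <= hi)
  wlo <- lo - tolerance
  whi <- hi + tolerance
  width <- whi - wlo
  n <- min(max_branches, max(1L, floor(width / min_step)))
  edges <- seq(wlo, whi, length.out = n + 1L)
  (edges[-1L] + edges[-(n + 1L)]) / 2
}

#' Steric acceptability of a conformation
#'
#' Checks every non-bonded atom pair (pairs separated by more than two bonds
#' in the backbone bond graph) against scaled van der Waals contact:
#' the conformation passes iff every checked pair is at distance
#' `>= scale * (r_i + r_j)`.
#'
#' @param conf a `Conformation` (backbone + CB/O atoms).
#' @param params `ForceFieldParams` with radii for every element present.
#' @param scale van der Waals scaling factor (default 0.7).
#' @return logical.
#' @export
steric_ok <- function(conf, params, scale = 0.7) {
  n <- nrow(conf)
  rad <- vdw_radius(params, conf$element)
  if (n < 2) return(TRUE)
  excl <- bonded_exclusions(conf)
  xyz <- coords(conf)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    js <- js[!paste(i, js) %in% excl]
    if (length(js) == 0L) next
    dd <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2))
    if (any(dd < scale * (rad[i] + rad[js]))) return(FALSE)
  }
  TRUE
}

# adjacency of the standard backbone topology: N-CA, CA-C, C-O, CA-CB within
# a residue, C(i)-N(i+1) between consecutive residues
backbone_adjacency <- function(conf) {
  idx <- function(resid, atom) {
    which(conf$resid == resid & conf$atom == atom)[1]
  }
  edges <- list()
  for (r in unique(conf$resid)) {
    for (pair in list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"))) {
      i <- idx(r, pair[1]); j <- idx(r, pair[2])
      if (!is.na(i) && !is.na(j)) edges[[length(edges) + 1L]] <- c(i, j)
    }
    i <- idx(r, "C"); j <- idx(r + 1L, "N")
    if (!is.na(i) && !is.na(j)) edges[[length(edges) + 1L]] <- c(i, j)
  }
  adj <- vector("list", nrow(conf))
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  adj
}

# character keys "i j" (i < j) of pairs within 2 bonds, given backbone topology
bonded_exclusions <- function(conf) {
  adj <- backbone_adjacency(conf)
  keys <- character(0)
  for (i in seq_along(adj)) {
    near <- unique(c(adj[[i]], unlist(adj[adj[[i]]])))
    near <- setdiff(near, i)
    for (j in near) {
      keys <- c(keys, paste(min(i, j), max(i, j)))
    }
  }
  unique(keys)
}

#' Improper-angle acceptability
#'
#' Measures every improper torsion defined in the parameter table whose four
#' atoms are present (a `+` prefix in the definition refers to the next
#' residue) and compares it to its target. Improper targets encode the
#' planarity of the peptide group and the L-chirality of the CA centre;
#' a mirror-image build flips the sign of the chirality improper and fails.
#'
#' @inheritParams steric_ok
#' @param tol_deg allowed absolute deviation from the target, degrees
#'   (default 5).
#' @return logical.
#' @export
improper_ok <- function(conf, params, tol_deg = 5) {
  devs <- improper_deviations(conf, params)
  all(abs(devs) <= tol_deg)
}

# signed deviations (deg, wrapped to (-180,180]) of all measurable impropers
improper_deviations <- function(conf, params) {
  defs <- params$impropers
  if (is.null(defs)) return(numeric(0))
  devs <- numeric(0)
  for (r in unique(conf$resid)) {
    for (k in seq_len(nrow(defs))) {
      pts <- lapply(c(defs$a[k], defs$b[k], defs$c[k], defs$d[k]), function(nm) {
        rr <- r + (substr(nm, 1, 1) == "+")
        atom_xyz(conf, rr, sub("^\\+", "", nm))
      })
      if (any(vapply(pts, is.null, logical(1)))) next
      val <- measure_torsion(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
      devs <- c(devs, wrap180(val - defs$target[k]))
    }
  }
  devs
}

wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `target` via singular value
#' decomposition of the cross-covariance, constrained to a proper rotation
#' (determinant +1).
#'
#' @param mobile,target numeric n x 3 matrices, n >= 3, matched row-wise.
#' @return list with `rotation` (3x3), `translation` (length 3) and `rmsd`
#'   (Angstrom); the fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
#' @examples
#' pts <- matrix(rnorm(15), ncol = 3)
#' kabsch_superpose(pts, pts)$rmsd  # 0
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("point counts differ")
  if (nrow(mobile) < 3) stop("underdetermined superposition: need >= 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = ct - as.vector(R %*% cm), rmsd = rmsd)
}

# aligned CA rmsd between two conformations with matching CA counts
ca_rmsd <- function(confA, confB) {
  a <- coords(confA, "CA"); b <- coords(confB, "CA")
  if (nrow(a) != nrow(b)) stop("CA counts differ")
  kabsch_superpose(b, a)$rmsd
}
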