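#' Build a peptide backbone from torsion angles
#'
#' Constructs backbone coordinates (N, CA, C plus carbonyl O and CB where
#' requested) for a peptide sequence at given phi/psi torsions, using ideal
#' bond lengths and angles from the parameter table and a fixed trans peptide
#' bond (omega = 180 degrees by default). The first residue's phi is
#' undefined (no preceding carbonyl) and is ignored.
#'
#' This sequential internal-to-Cartesian construction is independent of the
#' trilateration-based tree enumerator and serves as its reference
#' construction in tests.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi numeric vectors of torsions in degrees, one per residue.
#' @param params `ForceFieldParams` (defaults loaded when `NULL`).
#' @param start_resid residue index of the first residue.
#' @param include_o,include_cb place carbonyl oxygens / beta carbons.
#' @return a `Conformation`.
#' @export
#' @examples
#' conf <- build_backbone("AAA", phi = c(NA, -60, -60), psi = c(-45, -45, -45))
build_backbone <- function(sequence, phi, psi, params = NULL,
                           start_resid = 1L, include_o = TRUE,
                           include_cb = TRUE) {
  if (is.null(params)) params <- load_params()
  res3 <- one_to_three(sequence)
  n <- length(res3)
  stopifnot(length(phi) == n, length(psi) == n)
  if (n > 1 && anyNA(phi[-1])) stop("phi undefined for a non-terminal residue")
  if (n > 1 && anyNA(psi[-n])) stop("psi undefined for a non-terminal residue")
  # psi of the final residue only orients its carbonyl O; default trans-like
  if (is.na(psi[n])) psi[n] <- 180
  rNCA <- bond_length(params, "N", "CA")
  rCAC <- bond_length(params, "CA", "C")
  rCN <- bond_length(params, "C", "N")
  aNCAC <- bond_angle(params, "N", "CA", "C")
  aCACN <- bond_angle(params, "CA", "C", "N")
  aCNCA <- bond_angle(params, "C", "N", "CA")

  N <- matrix(NA_real_, n, 3); CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(rNCA, 0, 0)
  th <- aNCAC * pi / 180
  C[1, ] <- CA[1, ] + rCAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], rCAC, aNCAC, phi[i])
    }
    if (i < n) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], rCN, aCACN, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                                rNCA, aCNCA, params$omega)
    }
  }

  rows <- list()
  for (i in seq_len(n)) {
    rid <- start_resid + i - 1L
    add <- function(atom, xyz, element) {
      rows[[length(rows) + 1L]] <<- data.frame(
        resid = rid, resname = res3[i], atom = atom, element = element,
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
    add("N", N[i, ], "N")
    add("CA", CA[i, ], "C")
    add("C", C[i, ], "C")
    if (include_o) {
      o <- place_atom(N[i, ], CA[i, ], C[i, ],
                      bond_length(params, "C", "O"),
                      bond_angle(params, "CA", "C", "O"),
                      wrap180(psi[i] + 180))
      add("O", o, "O")
    }
    if (include_cb && res3[i] != "GLY") {
      cb <- place_cb(N[i, ], CA[i, ], C[i, ], params)
      add("CB", cb, "C")
    }
  }
  as_conformation(structure(do.call(rbind, rows),
                            class = c("Conformation", "data.frame")))
}

# place atom D from references A-B-C at bond |CD|, angle BCD (deg) and
# torsion ABCD (deg); standard internal-to-Cartesian (NeRF) step
place_atom <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- C - B; bc <- bc / vnorm(bc)
  ab <- B - A
  nv <- pracma_cross(ab, bc); nv <- nv / vnorm(nv)
  mv <- pracma_cross(nv, bc)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  C + d_local[1] * bc + d_local[2] * mv + d_local[3] * nv
}

# place CB from exact distances to N, CA, C, resolving the mirror ambiguity
# with the CA chirality improper target
place_cb <- function(N, CA, C, params) {
  dCB_N <- d13(bond_length(params, "CA", "CB"), bond_length(params, "N", "CA"),
               bond_angle(params, "N", "CA", "CB"))
  dCB_C <- d13(bond_length(params, "CA", "CB"), bond_length(params, "CA", "C"),
               bond_angle(params, "C", "CA", "CB"))
  cand <- trilaterate(rbind(CA, N, C),
                      c(bond_length(params, "CA", "CB"), dCB_N, dCB_C))
  if (nrow(cand) == 0) stop("infeasible CB geometry")
  target <- chirality_improper_target(params)
  devs <- apply(cand, 1, function(p) {
    abs(wrap180(measure_torsion(CA, N, C, p) - target))
  })
  cand[which.min(devs), ]
}

chirality_improper_target <- function(params) {
  defs <- params$impropers
  k <- which(defs$a == "CA" & defs$d == "CB")
  if (length(k) == 0) stop("no CA chirality improper in parameter table")
  defs$target[k[1]]
}

#' Measure backbone torsions of a conformation
#'
#' @param conf a `Conformation` with backbone N, CA, C atoms.
#' @return data.frame with columns `resid`, `phi`, `psi` (degrees; NA where
#'   the flanking residue is absent).
#' @export
backbone_torsions <- function(conf) {
  rids <- sort(unique(conf$resid))
  out <- data.frame(resid = rids, phi = NA_real_, psi = NA_real_)
  for (k in seq_along(rids)) {
    r <- rids[k]
    N <- atom_xyz(conf, r, "N"); CA <- atom_xyz(conf, r, "CA")
    C <- atom_xyz(conf, r, "C")
    Cm <- atom_xyz(conf, r - 1L, "C")
    Np <- atom_xyz(conf, r + 1L, "N")
    if (!is.null(Cm) && !is.null(N) && !is.null(CA) && !is.null(C)) {
      out$phi[k] <- measure_torsion(Cm, N, CA, C)
    }
    if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Np)) {
      out$psi[k] <- measure_torsion(N, CA, C, Np)
    }
  }
  out
}
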