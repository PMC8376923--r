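#' Fragment specification for enumeration
#'
#' A `FragmentSpec` names a peptide fragment (one-letter sequence plus its
#' residue index range) together with the per-residue torsion boxes that
#' bound the enumeration. One dummy alanine residue is appended at each
#' terminus at build time; the dummies participate in construction and
#' pruning (their backbone torsions are fixed, not sampled) and are stripped
#' from saved conformations.
#'
#' @param sequence one-letter string covering `start_resid` onwards.
#' @param start_resid residue index of the first (real) residue.
#' @param boxes named list: for each residue id (as character) a list of
#'   `TorsionBox` objects with components `phi` and `psi`, i.e.
#'   `boxes[["221"]]` is a list of boxes for residue 221. Each box bounds phi
#'   and psi jointly.
#' @param dummy_phi,dummy_psi fixed backbone torsions (degrees) given to the
#'   dummy terminal residues; extended-region values by default.
#' @return a `FragmentSpec`.
#' @export
fragment_spec <- function(sequence, start_resid, boxes,
                          dummy_phi = -139, dummy_psi = 135) {
  seq_letters <- strsplit(sequence, "")[[1]]
  resids <- start_resid + seq_along(seq_letters) - 1L
  for (r in resids) {
    bl <- boxes[[as.character(r)]]
    if (is.null(bl) || length(bl) == 0) {
      stop("residue ", r, " has no torsion box")
    }
  }
  structure(list(sequence = sequence, start_resid = as.integer(start_resid),
                 resids = resids, boxes = boxes,
                 dummy_phi = dummy_phi, dummy_psi = dummy_psi),
            class = "FragmentSpec")
}

#' Enumeration settings
#'
#' Bundles every tunable of the branch-and-prune traversal: interval
#' branching limits, the van der Waals pruning scale, the save gate on the
#' CA coordinate RMSD between successively saved conformations, and the cap
#' on saved conformations.
#'
#' @param max_branches maximum branches per interval distance (default 4).
#' @param min_step minimum interval discretization step, Angstrom (0.1).
#' @param tolerance widening of interval bounds, Angstrom (0.05).
#' @param vdw_scale van der Waals radius scaling for clash pruning (0.7).
#' @param save_rmsd_gate a leaf is saved only when its CA RMSD to the
#'   previously saved conformation exceeds this value, Angstrom (2.0); set
#'   to `-Inf` to save every leaf.
#' @param max_saved cap on saved conformations per run (1e9).
#' @param improper_tol improper-angle pruning tolerance, degrees (5).
#' @param angle_slack angular slack (degrees) admitted around a torsion box
#'   when validating branch candidates, matching the distance-bound widening.
#' @param compare_all_saved gate against all previously saved conformations
#'   instead of only the most recent one.
#' @param seed integer seed recorded with results (tie-breaking only; the
#'   traversal itself is deterministic).
#' @return an `EnumerationSettings` list.
#' @export
enumeration_settings <- function(max_branches = 4L, min_step = 0.1,
                                 tolerance = 0.05, vdw_scale = 0.7,
                                 save_rmsd_gate = 2.0, max_saved = 1e9,
                                 improper_tol = 5, angle_slack = 2,
                                 compare_all_saved = FALSE, seed = 1L) {
  stopifnot(max_branches >= 1, min_step > 0, tolerance >= 0, vdw_scale > 0,
            max_saved >= 1)
  structure(list(max_branches = as.integer(max_branches), min_step = min_step,
                 tolerance = tolerance, vdw_scale = vdw_scale,
                 save_rmsd_gate = save_rmsd_gate, max_saved = max_saved,
                 improper_tol = improper_tol, angle_slack = angle_slack,
                 compare_all_saved = compare_all_saved, seed = as.integer(seed)),
            class = "EnumerationSettings")
}

#' All per-residue box assignments of a fragment
#'
#' The boxes of different residues are combined by Cartesian product; each
#' combination defines one independent enumeration run.
#'
#' @param spec a `FragmentSpec`.
#' @return list of integer vectors, each one box index per residue (in
#'   residue order); length = product of per-residue box counts.
#' @export
box_combinations <- function(spec) {
  counts <- vapply(spec$resids, function(r) {
    length(spec$boxes[[as.character(r)]])
  }, integer(1))
  grid <- do.call(expand.grid, lapply(rev(counts), seq_len))
  grid <- grid[, rev(seq_along(counts)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# --- build-order machinery ---------------------------------------------------

# atom key helper
akey <- function(resid, atom) paste0(resid, ":", atom)

#' Build order of the enumerator
#'
#' Returns the explicit placement schedule used by [enumerate_fragment()]:
#' after the three seed atoms, every atom is trilaterated from three placed
#' references, two distances exact and at most one an interval (the
#' torsion-equivalent distance). The default order is backbone-plus-CB/O:
#' N, CA, C, CB per residue, with each carbonyl O placed once the next
#' residue's N exists.
#'
#' @param spec a `FragmentSpec`.
#' @param params `ForceFieldParams`.
#' @return list of placement steps (internal structure; exposed for
#'   inspection and testing).
#' @export
backbone_build_order <- function(spec, params) {
  s <- spec$start_resid
  e <- s + length(spec$resids) - 1L
  res3 <- one_to_three(spec$sequence)
  resname_of <- function(r) {
    if (r < s || r > e) "ALA" else res3[r - s + 1L]
  }
  rNCA <- bond_length(params, "N", "CA")
  rCAC <- bond_length(params, "CA", "C")
  rCN <- bond_length(params, "C", "N")
  rCO <- bond_length(params, "C", "O")
  rCACB <- bond_length(params, "CA", "CB")
  steps <- list()
  add <- function(resid, atom, element, refs, d1, d2, d3_spec, improper = NULL) {
    steps[[length(steps) + 1L]] <<- list(
      resid = resid, atom = atom, element = element,
      resname = resname_of(resid), refs = refs, d1 = d1, d2 = d2,
      d3 = d3_spec, improper = improper)
  }
  # CB of residue r: three exact distances, chirality improper check
  add_cb <- function(r) {
    if (resname_of(r) == "GLY") return()
    add(r, "CB", "C",
        c(akey(r, "CA"), akey(r, "N"), akey(r, "C")),
        rCACB,
        d13(rCACB, rNCA, bond_angle(params, "N", "CA", "CB")),
        list(type = "exact",
             value = d13(rCACB, rCAC, bond_angle(params, "C", "CA", "CB"))),
        improper = "chirality")
  }
  # O of residue r (requires N of r+1): exact, planarity improper check
  add_o <- function(r) {
    add(r, "O", "O",
        c(akey(r, "C"), akey(r, "CA"), akey(r + 1L, "N")),
        rCO,
        d13(rCO, rCAC, bond_angle(params, "CA", "C", "O")),
        list(type = "exact",
             value = d13(rCO, rCN, bond_angle(params, "O", "C", "N"))),
        improper = "planarity")
  }
  # dummy N-terminal residue s-1: seeded N, CA, C; CB right after
  add_cb(s - 1L)
  for (r in s:(e + 1L)) {
    is_dummy <- r == e + 1L
    # N(r): psi(r-1) torsion distance N(r-1)..N(r)
    psi_spec <- if (r == s) {
      list(type = "fixed", kind = "psi", value = spec$dummy_psi,
           tor_resid = r - 1L)
    } else {
      bx <- NULL  # boxes resolved per assignment at run time
      list(type = "interval", kind = "psi", tor_resid = r - 1L)
    }
    add(r, "N", "N",
        c(akey(r - 1L, "C"), akey(r - 1L, "CA"), akey(r - 1L, "N")),
        rCN, d13(rCN, rCAC, bond_angle(params, "CA", "C", "N")), psi_spec)
    # O(r-1) now placeable
    add_o(r - 1L)
    # CA(r): omega torsion distance CA(r-1)..CA(r), fixed
    add(r, "CA", "C",
        c(akey(r, "N"), akey(r - 1L, "C"), akey(r - 1L, "CA")),
        rNCA, d13(rNCA, rCN, bond_angle(params, "C", "N", "CA")),
        list(type = "fixed", kind = "omega", value = params$omega,
             tor_resid = r - 1L))
    # C(r): phi torsion distance C(r-1)..C(r)
    phi_spec <- if (is_dummy) {
      list(type = "fixed", kind = "phi", value = spec$dummy_phi, tor_resid = r)
    } else {
      list(type = "interval", kind = "phi", tor_resid = r)
    }
    add(r, "C", "C",
        c(akey(r, "CA"), akey(r, "N"), akey(r - 1L, "C")),
        rCAC, d13(rCAC, rNCA, bond_angle(params, "N", "CA", "C")), phi_spec)
    add_cb(r)
  }
  steps
}

# torsion path (4 atom keys) whose dihedral equals the sampled torsion
torsion_path_keys <- function(kind, tor_resid) {
  r <- tor_resid
  switch(kind,
         phi = c(akey(r - 1L, "C"), akey(r, "N"), akey(r, "CA"), akey(r, "C")),
         psi = c(akey(r, "N"), akey(r, "CA"), akey(r, "C"), akey(r + 1L, "N")),
         omega = c(akey(r, "CA"), akey(r, "C"), akey(r + 1L, "N"),
                   akey(r + 1L, "CA")),
         stop("unsupported torsion: ", kind))
}

# signed torsion values admitted for a sampled distance under a box;
# the box may extend past 180 (periodic seam crossing)
allowed_torsions <- function(d_sample, kind, lo, hi, params, slack) {
  t <- distance_to_torsion(d_sample, kind, params)
  # +180 and -180 alias the same geometry: deduplicate on the wrapped circle
  cand <- unique(wrap180(c(t, -t)))
  cand[vapply(cand, angle_in_interval, logical(1), lo = lo, hi = hi,
              slack = slack)]
}

angle_in_interval <- function(t, lo, hi, slack = 0) {
  any(t + c(-360, 0, 360) >= lo - slack & t + c(-360, 0, 360) <= hi + slack)
}

# range of |t| over the (possibly seam-crossing) angular interval [lo, hi]
interval_abs_range <- function(lo, hi) {
  subs <- if (hi <= 180) list(c(lo, hi)) else
    list(c(lo, 180), c(-180, hi - 360))
  lo_abs <- Inf; hi_abs <- 0
  for (sub in subs) {
    mn <- if (sub[1] <= 0 && sub[2] >= 0) 0 else min(abs(sub))
    lo_abs <- min(lo_abs, mn)
    hi_abs <- max(hi_abs, max(abs(sub)))
  }
  c(lo_abs, hi_abs)
}

# --- enumeration -------------------------------------------------------------

#' Enumerate fragment conformations for one box assignment
#'
#' Depth-first traversal of the branch-and-prune tree: atoms are placed in
#' build order by trilateration; interval (torsion) distances are sampled by
#' [discretize_interval()]; every branch whose new atom clashes sterically
#' (scaled van der Waals), breaks an improper-angle target, or falls outside
#' the torsion box is pruned with its whole subtree. A completed leaf is
#' saved when its CA RMSD to the previously saved conformation exceeds the
#' save gate. Traversal stops once `max_saved` conformations are kept.
#'
#' @param spec a `FragmentSpec`.
#' @param assignment integer vector: one box index per (real) residue.
#' @param settings an `EnumerationSettings`.
#' @param params `ForceFieldParams` (defaults when `NULL`).
#' @return an `EnumerationResult`: list with `conformations` (list of
#'   `Conformation`, dummies stripped), `counters` (named integer vector
#'   with `N_explored`, `N_pruned_steric`, `N_pruned_improper`,
#'   `N_pruned_box`, `N_leaves`, `N_saved`) and `complete` (TRUE iff the
#'   cap was never hit).
#' @export
enumerate_fragment <- function(spec, assignment, settings = enumeration_settings(),
                               params = NULL) {
  if (is.null(params)) params <- load_params()
  stopifnot(length(assignment) == length(spec$resids))
  steps <- backbone_build_order(spec, params)
  nsteps <- length(steps)
  natoms <- nsteps + 3L

  # atom bookkeeping: seed atoms first
  s <- spec$start_resid
  atom_tab <- data.frame(
    resid = c(rep(s - 1L, 3L), vapply(steps, `[[`, integer(1), "resid")),
    resname = c(rep("ALA", 3L), vapply(steps, `[[`, character(1), "resname")),
    atom = c("N", "CA", "C", vapply(steps, `[[`, character(1), "atom")),
    element = c("N", "C", "C", vapply(steps, `[[`, character(1), "element")),
    stringsAsFactors = FALSE)
  keys <- akey(atom_tab$resid, atom_tab$atom)
  key_index <- stats::setNames(seq_len(natoms), keys)

  # steric exclusions (<= 2 bonds) on the full topology
  topo <- as_conformation(cbind(atom_tab, x = 0, y = 0, z = 0))
  excl <- bonded_exclusions(topo)
  radii <- vdw_radius(params, atom_tab$element)

  # per-box resolution for interval torsions
  box_for <- function(r) {
    spec$boxes[[as.character(r)]][[assignment[match(r, spec$resids)]]]
  }

  xyz <- matrix(NA_real_, natoms, 3)
  rNCA <- bond_length(params, "N", "CA")
  rCAC <- bond_length(params, "CA", "C")
  th <- bond_angle(params, "N", "CA", "C") * pi / 180
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(rNCA, 0, 0)
  xyz[3, ] <- xyz[2, ] + rCAC * c(-cos(th), sin(th), 0)

  chir_target <- chirality_improper_target(params)
  plan_target <- {
    defs <- params$impropers
    k <- which(defs$a == "O")
    if (length(k)) defs$target[k[1]] else 180
  }

  counters <- c(N_explored = 0, N_pruned_steric = 0, N_pruned_improper = 0,
                N_pruned_box = 0, N_leaves = 0, N_saved = 0)
  saved <- list()
  saved_ca <- list()
  complete <- TRUE

  strip_and_order <- function() {
    conf <- as_conformation(cbind(atom_tab,
                                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
    keep <- conf$resid %in% spec$resids
    conf <- conf[keep, , drop = FALSE]
    ord <- order(conf$resid, match(conf$atom, c("N", "CA", "C", "O", "CB")))
    as_conformation(conf[ord, , drop = FALSE])
  }

  check_improper <- function(kind, step) {
    r <- step$resid
    pts <- if (kind == "chirality") {
      list(xyz[key_index[akey(r, "CA")], ], xyz[key_index[akey(r, "N")], ],
           xyz[key_index[akey(r, "C")], ], xyz[key_index[akey(r, "CB")], ])
    } else {
      list(xyz[key_index[akey(r, "O")], ], xyz[key_index[akey(r, "CA")], ],
           xyz[key_index[akey(r, "C")], ], xyz[key_index[akey(r + 1L, "N")], ])
    }
    target <- if (kind == "chirality") chir_target else plan_target
    val <- measure_torsion(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    abs(wrap180(val - target)) <= settings$improper_tol
  }

  # candidate positions at one step: list of xyz rows, already box-filtered
  step_candidates <- function(step) {
    refs <- xyz[key_index[step$refs], , drop = FALSE]
    spec3 <- step$d3
    if (spec3$type == "exact") {
      d3s <- spec3$value
      lo <- NULL
    } else {
      kind <- spec3$kind
      if (spec3$type == "fixed") {
        lo <- spec3$value; hi <- spec3$value
      } else {
        bx <- box_for(spec3$tor_resid)
        if (kind == "phi") { lo <- bx$phi_lo; hi <- bx$phi_hi }
        else { lo <- bx$psi_lo; hi <- bx$psi_hi }
      }
      ar <- interval_abs_range(lo, hi)
      dd <- sort(c(torsion_to_distance(ar[2], kind, params),
                   torsion_to_distance(ar[1], kind, params)))
      d3s <- discretize_interval(dd[1], dd[2], settings$max_branches,
                                 settings$min_step, settings$tolerance)
    }
    out <- list()
    for (d3 in d3s) {
      cand <- trilaterate(refs, c(step$d1, step$d2, d3))
      if (nrow(cand) == 0) next
      if (spec3$type == "exact") {
        for (i in seq_len(nrow(cand))) out[[length(out) + 1L]] <- cand[i, ]
      } else {
        allowed <- allowed_torsions(d3, spec3$kind, lo, hi, params,
                                    settings$angle_slack)
        if (length(allowed) == 0) next
        path <- torsion_path_keys(spec3$kind, spec3$tor_resid)
        p123 <- lapply(path[1:3], function(k) xyz[key_index[k], ])
        tors <- apply(cand, 1, function(p) {
          measure_torsion(p123[[1]], p123[[2]], p123[[3]], p)
        })
        # positive torsion branch first, then negative
        for (tv in sort(allowed, decreasing = TRUE)) {
          i <- which.min(abs(wrap180(tors - tv)))
          if (abs(wrap180(tors[i] - tv)) < 0.01) {
            out[[length(out) + 1L]] <- cand[i, ]
          }
        }
      }
    }
    out
  }

  descend <- function(k) {
    if (!complete) return()
    if (k > nsteps) {
      counters["N_leaves"] <<- counters["N_leaves"] + 1
      conf <- strip_and_order()
      ca <- coords(conf, "CA")
      gate <- settings$save_rmsd_gate
      keep <- if (length(saved) == 0 || gate == -Inf) TRUE else {
        ref <- if (settings$compare_all_saved) saved_ca else
          saved_ca[length(saved_ca)]
        all(vapply(ref, function(m) kabsch_superpose(ca, m)$rmsd,
                   numeric(1)) > gate)
      }
      if (keep) {
        saved[[length(saved) + 1L]] <<- conf
        saved_ca[[length(saved_ca) + 1L]] <<- ca
        counters["N_saved"] <<- counters["N_saved"] + 1
        if (counters["N_saved"] >= settings$max_saved) {
          # cap reached: stop the traversal, flag incompleteness
          complete <<- FALSE
        }
      }
      return()
    }
    step <- steps[[k]]
    row <- k + 3L
    for (pos in step_candidates(step)) {
      if (!complete) return()
      counters["N_explored"] <<- counters["N_explored"] + 1
      xyz[row, ] <<- pos
      # incremental steric check against placed, non-excluded atoms
      placed <- seq_len(row - 1L)
      js <- placed[!paste(pmin(placed, row), pmax(placed, row)) %in% excl]
      ok <- TRUE
      if (length(js)) {
        dd <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - pos)^2))
        if (any(dd < settings$vdw_scale * (radii[js] + radii[row]))) {
          counters["N_pruned_steric"] <<- counters["N_pruned_steric"] + 1
          ok <- FALSE
        }
      }
      if (ok && !is.null(step$improper) &&
          !check_improper(step$improper, step)) {
        counters["N_pruned_improper"] <<- counters["N_pruned_improper"] + 1
        ok <- FALSE
      }
      if (ok) descend(k + 1L)
      xyz[row, ] <<- NA_real_
    }
  }
  descend(1L)

  structure(list(conformations = saved, counters = counters,
                 complete = complete),
            class = "EnumerationResult")
}

#' Run all box assignments of a fragment
#'
#' Executes [enumerate_fragment()] for every assignment produced by
#' [box_combinations()] and merges the results.
#'
#' @inheritParams enumerate_fragment
#' @return list with `conformations` (concatenated), `counters` (summed),
#'   `per_run` (list of per-assignment counters), `N_iBPrun` (number of
#'   assignments executed), `N_iBPconf` (cumulative saved conformations) and
#'   `complete`.
#' @export
run_fragment <- function(spec, settings = enumeration_settings(), params = NULL) {
  if (is.null(params)) params <- load_params()
  combos <- box_combinations(spec)
  confs <- list()
  per_run <- list()
  total <- NULL
  complete <- TRUE
  for (as_ in combos) {
    res <- enumerate_fragment(spec, as_, settings, params)
    confs <- c(confs, res$conformations)
    per_run[[length(per_run) + 1L]] <- res$counters
    total <- if (is.null(total)) res$counters else total + res$counters
    complete <- complete && res$complete
  }
  list(conformations = confs, counters = total, per_run = per_run,
       N_iBPrun = length(combos),
       N_iBPconf = unname(total["N_saved"]), complete = complete)
}
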