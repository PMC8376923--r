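#' Assemble two overlapping fragment conformations
#'
#' Superposes the first `overlap_residues` residues of `confB` onto the last
#' `overlap_residues` residues of `confA` over their shared backbone atoms,
#' then splices the chains at the "switch atom": the overlap backbone atom
#' whose two copies end up closest after superposition. The merged chain
#' takes A's atoms up to and including the switch atom and B's atoms after
#' it. The merge is rejected when any non-neighbouring CA pair of the merged
#' chain lies closer than `clash_dist`.
#'
#' Fragments must carry consistent global residue numbering: the last
#' `overlap_residues` residue ids (and names) of A must equal the first ones
#' of B.
#'
#' @param confA,confB `Conformation`s.
#' @param overlap_residues residues in the overlap (default 3).
#' @param clash_dist CA clash distance, Angstrom (default 1).
#' @return the merged `Conformation`, or `NULL` when rejected for clashes
#'   (attribute `"rmsd"` carries the overlap superposition RMSD on success).
#' @export
assemble_pair <- function(confA, confB, overlap_residues = 3L, clash_dist = 1) {
  ra <- sort(unique(confA$resid)); rb <- sort(unique(confB$resid))
  ov_a <- utils::tail(ra, overlap_residues)
  ov_b <- utils::head(rb, overlap_residues)
  if (!identical(ov_a, ov_b)) {
    stop("incompatible fragments: overlap residue ids differ (",
         paste(ov_a, collapse = ","), " vs ", paste(ov_b, collapse = ","), ")")
  }
  name_a <- confA$resname[match(ov_a, confA$resid)]
  name_b <- confB$resname[match(ov_b, confB$resid)]
  if (!identical(name_a, name_b)) {
    stop("incompatible fragments: overlap sequences differ")
  }
  bb <- c("N", "CA", "C", "O")
  selA <- confA[confA$resid %in% ov_a & confA$atom %in% bb, , drop = FALSE]
  selB <- confB[confB$resid %in% ov_a & confB$atom %in% bb, , drop = FALSE]
  keyA <- paste(selA$resid, selA$atom); keyB <- paste(selB$resid, selB$atom)
  common <- intersect(keyA, keyB)
  tA <- coords(as_conformation(selA[match(common, keyA), , drop = FALSE]))
  mB <- coords(as_conformation(selB[match(common, keyB), , drop = FALSE]))
  fit <- kabsch_superpose(mB, tA)
  confB <- transform_conformation(confB, fit$rotation, fit$translation)

  # switch atom: overlap backbone atom with smallest post-fit displacement
  selB2 <- confB[confB$resid %in% ov_a & confB$atom %in% bb, , drop = FALSE]
  keyB2 <- paste(selB2$resid, selB2$atom)
  d_pair <- sqrt(rowSums((coords(as_conformation(
    selA[match(common, keyA), , drop = FALSE])) -
      coords(as_conformation(selB2[match(common, keyB2), , drop = FALSE])))^2))
  # order atom keys in build order (residue-major, N CA C O)
  ord <- order(selA$resid[match(common, keyA)],
               match(selA$atom[match(common, keyA)], bb))
  common_o <- common[ord]; d_o <- d_pair[ord]
  switch_key <- common_o[which.min(d_o)]  # ties: earliest in build order

  atom_rank <- function(conf) {
    order_key <- match(conf$atom, c("N", "CA", "C", "O", "CB"))
    conf$resid * 10 + order_key
  }
  # split: A up to and including the switch atom, B after it
  sw <- as.integer(strsplit(switch_key, " ")[[1]][1]) * 10 +
    match(strsplit(switch_key, " ")[[1]][2], c("N", "CA", "C", "O", "CB"))
  partA <- confA[atom_rank(confA) <= sw, , drop = FALSE]
  partB <- confB[atom_rank(confB) > sw, , drop = FALSE]
  merged <- as_conformation(rbind(partA, partB))
  ord2 <- order(merged$resid, match(merged$atom, c("N", "CA", "C", "O", "CB")))
  merged <- as_conformation(merged[ord2, , drop = FALSE])

  ca <- coords(merged, "CA")
  n <- nrow(ca)
  if (n >= 3) {
    dm <- as.matrix(stats::dist(ca))
    off <- abs(outer(seq_len(n), seq_len(n), "-")) >= 2
    if (any(dm[off] < clash_dist)) return(NULL)
  }
  attr(merged, "rmsd") <- fit$rmsd
  merged
}

#' Assemble two conformer sets all-against-all
#'
#' Every pair (a in `setA`, b in `setB`) is tried with [assemble_pair()];
#' clashing merges are discarded. Counters follow the bookkeeping identity
#' `N_saved = N_trials - N_clashes`. The merged set is then passed through
#' [maybe_cluster()] to give `N_clust`.
#'
#' @param setA,setB lists of `Conformation`s.
#' @param overlap_residues overlap length (default 3).
#' @param cluster logical: run the SOM reduction on the merged set.
#' @param cluster_args list of arguments forwarded to [maybe_cluster()].
#' @return list with `conformations` (after optional clustering) and
#'   `counters` (an `AssemblyCounters` named vector: `N_trials`,
#'   `N_clashes`, `N_saved`, `N_clust`).
#' @export
assemble_sets <- function(setA, setB, overlap_residues = 3L, cluster = TRUE,
                          cluster_args = list()) {
  stopifnot(length(setA) > 0, length(setB) > 0)
  merged <- list()
  n_clash <- 0L
  for (a in setA) for (b in setB) {
    m <- assemble_pair(a, b, overlap_residues)
    if (is.null(m)) n_clash <- n_clash + 1L else {
      merged[[length(merged) + 1L]] <- m
    }
  }
  out <- if (cluster) {
    do.call(maybe_cluster, c(list(merged), cluster_args))
  } else merged
  counters <- assembly_counters(length(setA), length(setB), n_clash,
                                n_clust = length(out))
  list(conformations = out, counters = counters)
}

#' Assembly bookkeeping counters
#'
#' The arithmetic of one assembly step: all-against-all trials
#' `N_trials = n_a * n_b`, clash-rejected merges `N_clashes`, kept solutions
#' `N_saved = N_trials - N_clashes`, and the post-clustering count `N_clust`.
#'
#' @param n_a,n_b sizes of the two conformer sets.
#' @param n_clashes number of clash-rejected merges.
#' @param n_clust number of representatives after clustering (defaults to
#'   `N_saved` when no clustering is applied).
#' @return named numeric vector of class `AssemblyCounters`.
#' @export
#' @examples
#' assembly_counters(477, 331, 15103)  # N_trials 157887, N_saved 142784
assembly_counters <- function(n_a, n_b, n_clashes, n_clust = NULL) {
  n_trials <- n_a * n_b
  n_saved <- n_trials - n_clashes
  if (is.null(n_clust)) n_clust <- n_saved
  stopifnot(n_clashes >= 0, n_saved >= 0, n_clust <= max(n_saved, 0))
  structure(c(N_trials = n_trials, N_clashes = n_clashes,
              N_saved = n_saved, N_clust = n_clust),
            class = c("AssemblyCounters", "numeric"))
}

#' Assemble an ordered chain of fragment sets
#'
#' Left fold over the fragment sets: the running set (clustered at each
#' step) is assembled with the next fragment's set, emitting one
#' `AssemblyCounters` per step.
#'
#' @param fragment_sets list of conformer sets, ordered N- to C-terminal.
#' @inheritParams assemble_sets
#' @return list with `conformations` (final set) and `steps` (list of
#'   per-step counters).
#' @export
assemble_chain <- function(fragment_sets, overlap_residues = 3L,
                           cluster = TRUE, cluster_args = list()) {
  stopifnot(length(fragment_sets) >= 2)
  current <- fragment_sets[[1]]
  steps <- list()
  for (k in 2:length(fragment_sets)) {
    res <- assemble_sets(current, fragment_sets[[k]], overlap_residues,
                         cluster = cluster, cluster_args = cluster_args)
    current <- res$conformations
    steps[[length(steps) + 1L]] <- res$counters
    if (length(current) == 0) break
  }
  list(conformations = current, steps = steps)
}
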