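#' Torsion likelihood maps
#'
#' A `TorsionLikelihoodMap` is a per-residue 18 x 18 grid of non-negative
#' likelihood values over the Ramachandran plane, one voxel covering
#' 20 x 20 degrees. Voxel `(a, b)` (1-based in R) covers
#' phi in \[-180 + 20(a-1), -160 + 20(a-1)) and likewise for psi, so voxel
#' centres sit at -170 + 20k degrees and the map holds exactly 324 voxels.
#'
#' @param residue_id integer residue index.
#' @param grid 18 x 18 numeric matrix, non-negative; rows index phi voxels,
#'   columns psi voxels.
#' @return an object of class `TorsionLikelihoodMap`.
#' @export
torsion_likelihood_map <- function(residue_id, grid) {
  grid <- as.matrix(grid)
  if (!all(dim(grid) == c(18L, 18L))) {
    stop("likelihood grid must be 18 x 18 (324 voxels)")
  }
  if (any(grid < 0) || any(!is.finite(grid))) {
    stop("likelihood values must be finite and non-negative")
  }
  structure(list(residue_id = as.integer(residue_id), grid = grid),
            class = "TorsionLikelihoodMap")
}

#' @rdname torsion_likelihood_map
#' @export
voxel_centers <- function() seq(-170, 170, by = 20)

#' Rectangular phi/psi torsion box
#'
#' @param residue_id integer residue index.
#' @param phi_lo,phi_hi,psi_lo,psi_hi box limits in degrees, lower strictly
#'   below upper and lower in \[-180, 180\]. A box crossing the +/-180 seam
#'   of the periodic Ramachandran plane is written with its upper limit
#'   beyond 180 (e.g. phi in \[160, 200\] covers \[160, 180\] and
#'   \[-180, -160\]); widths never exceed 360.
#' @return an object of class `TorsionBox`.
#' @export
torsion_box <- function(residue_id, phi_lo, phi_hi, psi_lo, psi_hi) {
  stopifnot(phi_lo < phi_hi, psi_lo < psi_hi,
            phi_lo >= -180, phi_lo <= 180, phi_hi <= phi_lo + 360,
            psi_lo >= -180, psi_lo <= 180, psi_hi <= psi_lo + 360)
  structure(list(residue_id = as.integer(residue_id),
                 phi_lo = phi_lo, phi_hi = phi_hi,
                 psi_lo = psi_lo, psi_hi = psi_hi),
            class = "TorsionBox")
}

#' @export
print.TorsionBox <- function(x, ...) {
  cat(sprintf("TorsionBox res %d: phi [%g, %g], psi [%g, %g]\n",
              x$residue_id, x$phi_lo, x$phi_hi, x$psi_lo, x$psi_hi))
  invisible(x)
}

#' Normalize a likelihood map to a probability map
#'
#' Rescales the grid so that the 324 voxel values sum to one, preserving
#' proportions.
#'
#' @param map a `TorsionLikelihoodMap`.
#' @return the normalized `TorsionLikelihoodMap`.
#' @export
normalize_map <- function(map) {
  s <- sum(map$grid)
  if (s <= 0) stop("empty likelihood map: all voxels are zero")
  map$grid <- map$grid / s
  map
}

#' Select voxels above a probability threshold
#'
#' @param map a normalized `TorsionLikelihoodMap`.
#' @param threshold strict lower bound on the normalized voxel value
#'   (default 0.01).
#' @return integer matrix with columns `phi_idx`, `psi_idx` (1-based voxel
#'   indices); zero rows when nothing exceeds the threshold.
#' @export
select_voxels <- function(map, threshold = 0.01) {
  idx <- which(map$grid > threshold, arr.ind = TRUE)
  colnames(idx) <- c("phi_idx", "psi_idx")
  idx
}

#' Extract torsion boxes from selected voxels
#'
#' Groups the selected voxels into 8-connected components (treating both the
#' phi and psi axes as periodic across +/-180 degrees) and returns the
#' axis-aligned bounding rectangle of each component as a `TorsionBox`.
#' A component that wraps around the periodic boundary is bounded in the
#' unwrapped frame and then shifted back into \[-180, 180\].
#'
#' @param voxels index matrix as returned by [select_voxels()].
#' @param residue_id residue the boxes belong to.
#' @return list of `TorsionBox` objects.
#' @export
boxes_from_voxels <- function(voxels, residue_id) {
  if (is.null(voxels) || nrow(voxels) == 0) {
    stop("no box for residue ", residue_id,
         ": empty voxel selection (consider copying a neighbour's boxes)")
  }
  comp <- connected_components_toroidal(voxels, 18L)
  lapply(unique(comp$component), function(k) {
    sub <- comp[comp$component == k, , drop = FALSE]
    # unwrapped integer indices; convert to degree bounds then wrap
    phi_b <- index_range_to_degrees(sub$phi_unwrapped)
    psi_b <- index_range_to_degrees(sub$psi_unwrapped)
    torsion_box(residue_id, phi_b[1], phi_b[2], psi_b[1], psi_b[2])
  })
}

# label 8-connected components of voxel indices on an n x n torus; returns a
# data.frame with unwrapped coordinates chosen per component so that the
# component is contiguous in Z^2
connected_components_toroidal <- function(voxels, n) {
  m <- nrow(voxels)
  key <- paste(voxels[, 1], voxels[, 2])
  lookup <- stats::setNames(seq_len(m), key)
  comp <- integer(m)
  phi_un <- integer(m); psi_un <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    comp[s] <- cur
    phi_un[s] <- voxels[s, 1]; psi_un[s] <- voxels[s, 2]
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (da in -1:1) for (db in -1:1) {
        if (da == 0 && db == 0) next
        na_w <- ((voxels[v, 1] - 1 + da) %% n) + 1
        nb_w <- ((voxels[v, 2] - 1 + db) %% n) + 1
        u <- lookup[paste(na_w, nb_w)]
        if (!is.na(u) && comp[u] == 0L) {
          comp[u] <- cur
          phi_un[u] <- phi_un[v] + da
          psi_un[u] <- psi_un[v] + db
          queue <- c(queue, u)
        }
      }
    }
  }
  data.frame(phi_idx = voxels[, 1], psi_idx = voxels[, 2],
             phi_unwrapped = phi_un, psi_unwrapped = psi_un,
             component = comp)
}

# bounding interval in degrees of a set of unwrapped voxel indices; shifted
# back so the lower bound lies in [-180, 180)
index_range_to_degrees <- function(idx_unwrapped) {
  lo <- -180 + 20 * (min(idx_unwrapped) - 1)
  hi <- -160 + 20 * (max(idx_unwrapped) - 1)
  shift <- 0
  while (lo + shift < -180) shift <- shift + 360
  while (lo + shift >= 180) shift <- shift - 360
  c(lo, hi) + shift
}

#' Extract all torsion boxes for a set of likelihood maps
#'
#' Convenience driver: normalizes each map, selects voxels above the
#' threshold and extracts component bounding boxes. Residues whose selection
#' is empty, or that have no map at all, can copy the boxes of another
#' residue through `copy_from`, an explicit escape hatch for residues with
#' no usable prediction; they are never skipped silently.
#'
#' @param maps list of `TorsionLikelihoodMap`s.
#' @param threshold voxel selection threshold (default 0.01).
#' @param copy_from optional named integer vector: `copy_from["254"] = 255`
#'   copies residue 255's boxes to residue 254.
#' @return named list (by residue id) of lists of `TorsionBox`.
#' @export
extract_boxes <- function(maps, threshold = 0.01, copy_from = NULL) {
  out <- list()
  for (map in maps) {
    rid <- as.character(map$residue_id)
    boxes <- tryCatch({
      nm <- normalize_map(map)
      boxes_from_voxels(select_voxels(nm, threshold), map$residue_id)
    }, error = function(e) e)
    out[[rid]] <- boxes
  }
  for (rid in names(copy_from)) {
    if (is.null(out[[rid]])) out[[rid]] <- simpleError(
      paste0("no box for residue ", rid, ": no likelihood map"))
  }
  for (rid in names(out)) {
    if (inherits(out[[rid]], "error")) {
      src <- copy_from[[rid]]
      if (is.null(src) || is.na(src)) stop(conditionMessage(out[[rid]]))
      src_boxes <- out[[as.character(src)]]
      if (is.null(src_boxes) || inherits(src_boxes, "error")) {
        stop("cannot copy boxes for residue ", rid, " from residue ", src)
      }
      out[[rid]] <- lapply(src_boxes, function(b) {
        b$residue_id <- as.integer(rid); b
      })
    }
  }
  out
}
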