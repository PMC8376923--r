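#' Radius of gyration
#'
#' Mass-weighted (or unweighted) root-mean-square distance of atoms from
#' their centroid.
#'
#' @param conf a `Conformation`.
#' @param mass_weighted use atomic masses from the element symbol
#'   (default TRUE).
#' @return radius of gyration in Angstrom.
#' @export
#' @examples
#' two <- conformation(1, "ALA", c("CA", "CA"), x = c(0, 2), y = 0, z = 0)
#' gyration_radius(two)  # 1
gyration_radius <- function(conf, mass_weighted = TRUE) {
  xyz <- coords(conf)
  m <- if (mass_weighted) atomic_mass(conf$element) else rep(1, nrow(xyz))
  ctr <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, ctr)^2)) / sum(m))
}

atomic_mass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974)
  m <- tab[element]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Attachment specification for the first domain
#'
#' @param anchor_a,anchor_b residue ids of the two anchor residues shared by
#'   the domain's terminal segment and the linker (`anchor_a < anchor_b`).
#' @param grid_exclusion grid points closer than this to any linker CA are
#'   dropped (Angstrom, default 2).
#' @param clash_dist CA-CA clash distance (default 1).
#' @param max_clashes acceptance requires strictly fewer CA clash pairs than
#'   this (default 3).
#' @param max_anchor_dist acceptance requires the mean of the two anchor
#'   CA-CA distances strictly below this (Angstrom, default 6).
#' @return an `AttachmentSpec`.
#' @export
attachment_spec <- function(anchor_a, anchor_b, grid_exclusion = 2,
                            clash_dist = 1, max_clashes = 3,
                            max_anchor_dist = 6) {
  stopifnot(anchor_a < anchor_b, grid_exclusion > 0, clash_dist > 0,
            max_clashes > 0, max_anchor_dist > 0)
  structure(list(anchor_a = as.integer(anchor_a),
                 anchor_b = as.integer(anchor_b),
                 grid_exclusion = grid_exclusion, clash_dist = clash_dist,
                 max_clashes = max_clashes,
                 max_anchor_dist = max_anchor_dist),
            class = "AttachmentSpec")
}

#' Candidate grid for domain placement
#'
#' Builds a regular lattice spanning the linker's CA bounding box widened by
#' the domain's radius of gyration `r_g` on every axis, then keeps the
#' points strictly closer than `r_g` to the CA of the second anchor residue
#' and strictly farther than the exclusion distance from every linker CA.
#'
#' @param linker a linker `Conformation`.
#' @param spec an `AttachmentSpec`.
#' @param r_g the domain's radius of gyration (Angstrom).
#' @param spacing lattice spacing (Angstrom, default 2).
#' @return matrix of candidate points (n x 3).
#' @export
candidate_grid <- function(linker, spec, r_g, spacing = 2) {
  stopifnot(spacing > 0)
  ca <- coords(linker, "CA")
  anchor <- atom_xyz(linker, spec$anchor_b, "CA")
  if (is.null(anchor)) stop("anchor residue CA absent from linker")
  lo <- apply(ca, 2, min) - r_g
  hi <- apply(ca, 2, max) + r_g
  axes <- lapply(1:3, function(k) seq(lo[k], hi[k], by = spacing))
  pts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  colnames(pts) <- NULL
  d_anchor <- sqrt(colSums((t(pts) - anchor)^2))
  keep <- d_anchor < r_g
  if (any(keep)) {
    sub <- pts[keep, , drop = FALSE]
    dmin <- apply(sub, 1, function(pnt) {
      min(sqrt(colSums((t(ca) - pnt)^2)))
    })
    keep2 <- dmin > spec$grid_exclusion
    sub <- sub[keep2, , drop = FALSE]
  } else sub <- pts[0, , drop = FALSE]
  if (nrow(sub) == 0) stop("no candidate placements: grid filtered empty")
  sub
}

#' Place a rigid domain at a grid point and test acceptance
#'
#' Moves the domain's geometric centre to `grid_point`, rotates it by the
#' minimal rotation mapping its internal anchor vector (CA of `anchor_a` to
#' CA of `anchor_b`) onto the linker's, optionally spins it about the
#' aligned axis, then translates it by `T = (V_a + V_b)/2` where `V_r` is
#' the vector from the domain's to the linker's anchor-residue CA. The pose
#' is accepted when fewer than `max_clashes` domain-linker CA pairs are
#' closer than `clash_dist`, and the mean of the two anchor CA-CA distances
#' stays below `max_anchor_dist`.
#'
#' @param domain,linker `Conformation`s sharing the anchor residue ids.
#' @param grid_point length-3 numeric.
#' @param spec an `AttachmentSpec`.
#' @param spin additional rotation about the aligned anchor vector, degrees.
#' @return list with `domain` (placed), `accepted` (logical), `n_clashes`
#'   and `mean_anchor_dist`.
#' @export
place_domain <- function(domain, linker, grid_point, spec, spin = 0) {
  va <- atom_xyz(linker, spec$anchor_a, "CA")
  vb <- atom_xyz(linker, spec$anchor_b, "CA")
  if (is.null(va) || is.null(vb)) stop("anchor residues absent from linker")
  v_lnk <- vb - va
  if (vnorm(v_lnk) < 1e-9) stop("degenerate anchors: zero-length linker vector")

  ctr <- colMeans(coords(domain))
  placed <- transform_conformation(domain, translation = grid_point - ctr)
  da <- atom_xyz(placed, spec$anchor_a, "CA")
  db <- atom_xyz(placed, spec$anchor_b, "CA")
  if (is.null(da) || is.null(db)) stop("anchor residues absent from domain")
  v_dom <- db - da
  if (vnorm(v_dom) < 1e-9) stop("degenerate anchors: zero-length domain vector")
  R <- rotation_between(v_dom, v_lnk)
  if (spin != 0) R <- axis_rotation(v_lnk, spin) %*% R
  placed <- transform_conformation(placed, rotation = R, center = grid_point)
  da <- atom_xyz(placed, spec$anchor_a, "CA")
  db <- atom_xyz(placed, spec$anchor_b, "CA")
  Tv <- ((va - da) + (vb - db)) / 2
  placed <- transform_conformation(placed, translation = Tv)

  da <- atom_xyz(placed, spec$anchor_a, "CA")
  db <- atom_xyz(placed, spec$anchor_b, "CA")
  mean_anchor <- (vnorm(va - da) + vnorm(vb - db)) / 2
  ca_d <- coords(placed, "CA"); ca_l <- coords(linker, "CA")
  n_clashes <- 0L
  for (i in seq_len(nrow(ca_d))) {
    n_clashes <- n_clashes +
      sum(sqrt(colSums((t(ca_l) - ca_d[i, ])^2)) < spec$clash_dist)
  }
  list(domain = placed,
       accepted = n_clashes < spec$max_clashes &&
         mean_anchor < spec$max_anchor_dist,
       n_clashes = n_clashes, mean_anchor_dist = mean_anchor)
}

# minimal rotation taking unit(a) to unit(b)
rotation_between <- function(a, b) {
  a <- a / vnorm(a); b <- b / vnorm(b)
  v <- pracma_cross(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # anti-parallel: rotate 180 degrees about any perpendicular axis
    perp <- pracma_cross(a, c(1, 0, 0))
    if (vnorm(perp) < 1e-6) perp <- pracma_cross(a, c(0, 1, 0))
    return(axis_rotation(perp, 180))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}

# rotation by angle (deg) about axis
axis_rotation <- function(axis, angle) {
  u <- axis / vnorm(axis)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Merge a placed domain and a linker into one chain
#'
#' @param domain,linker `Conformation`s with consistent residue numbering.
#' @param split_residue residues up to and including this id come from the
#'   domain, later ones from the linker.
#' @return the merged `Conformation` with continuous numbering.
#' @export
merge_domain_linker <- function(domain, linker, split_residue) {
  dpart <- domain[domain$resid <= split_residue, , drop = FALSE]
  lpart <- linker[linker$resid > split_residue, , drop = FALSE]
  rids <- sort(unique(c(dpart$resid, lpart$resid)))
  if (length(rids) == 0) stop("empty merge")
  if (!identical(rids, seq(min(rids), max(rids)))) {
    stop("overlapping residue ranges: merged numbering is not continuous")
  }
  if (max(dpart$resid) != split_residue ||
      (nrow(lpart) > 0 && min(lpart$resid) != split_residue + 1L)) {
    stop("overlapping residue ranges: split residue not shared cleanly")
  }
  as_conformation(rbind(dpart, lpart))
}

#' Second-domain specification
#'
#' @param superpose_range integer range of residues used for the backbone
#'   superposition of the reference complex onto the partial model.
#' @param bridge_residue residue whose CA displacement (complex to partial)
#'   defines the translation applied to the second domain.
#' @param domain_start first residue id of the second domain within the
#'   reference complex.
#' @param clash_dist atom clash distance (default 1 Angstrom).
#' @param max_clashes acceptance requires strictly fewer atom clashes
#'   (default 50).
#' @return a `SecondDomainSpec`.
#' @export
second_domain_spec <- function(superpose_range, bridge_residue, domain_start,
                               clash_dist = 1, max_clashes = 50) {
  stopifnot(clash_dist > 0, max_clashes > 0)
  structure(list(superpose_range = superpose_range,
                 bridge_residue = as.integer(bridge_residue),
                 domain_start = as.integer(domain_start),
                 clash_dist = clash_dist, max_clashes = max_clashes),
            class = "SecondDomainSpec")
}

#' Attach the second domain via a reference complex
#'
#' Superposes the reference complex onto the partial model over the backbone
#' atoms of `superpose_range`, translates the complex's second domain
#' (residues from `domain_start`) by the bridge-residue CA displacement from
#' the superposed complex to the partial model, counts atom pairs between
#' partial model and translated domain closer than the clash distance, and
#' concatenates when strictly fewer than `max_clashes`.
#'
#' @param reference_complex `Conformation` holding both domains in their
#'   reference relative orientation.
#' @param partial `Conformation` of the already-built part (first domain +
#'   linker), containing the bridge residue.
#' @param spec a `SecondDomainSpec`.
#' @return list with `conformation` (merged, or `NULL` when rejected),
#'   `accepted` and `n_clashes`.
#' @export
attach_second_domain <- function(reference_complex, partial, spec) {
  bb <- c("N", "CA", "C", "O")
  selC <- reference_complex[reference_complex$resid %in% spec$superpose_range &
                              reference_complex$atom %in% bb, , drop = FALSE]
  selP <- partial[partial$resid %in% spec$superpose_range &
                    partial$atom %in% bb, , drop = FALSE]
  keyC <- paste(selC$resid, selC$atom); keyP <- paste(selP$resid, selP$atom)
  common <- intersect(keyC, keyP)
  if (length(common) < 3) stop("superposition range absent or too sparse")
  fit <- kabsch_superpose(
    coords(as_conformation(selC[match(common, keyC), , drop = FALSE])),
    coords(as_conformation(selP[match(common, keyP), , drop = FALSE])))
  complex_fit <- transform_conformation(reference_complex, fit$rotation,
                                        fit$translation)
  b_complex <- atom_xyz(complex_fit, spec$bridge_residue, "CA")
  b_partial <- atom_xyz(partial, spec$bridge_residue, "CA")
  if (is.null(b_complex) || is.null(b_partial)) {
    stop("bridge residue absent")
  }
  v_bridge <- b_partial - b_complex
  dom2 <- complex_fit[complex_fit$resid >= spec$domain_start, , drop = FALSE]
  if (nrow(dom2) == 0) stop("second domain empty in reference complex")
  dom2 <- transform_conformation(as_conformation(dom2),
                                 translation = v_bridge)
  p_keep <- partial[partial$resid < spec$domain_start, , drop = FALSE]
  xp <- coords(as_conformation(p_keep)); xd <- coords(dom2)
  n_clashes <- 0L
  for (i in seq_len(nrow(xd))) {
    n_clashes <- n_clashes +
      sum(sqrt(colSums((t(xp) - xd[i, ])^2)) < spec$clash_dist)
  }
  accepted <- n_clashes < spec$max_clashes
  merged <- if (accepted) {
    as_conformation(rbind(p_keep, dom2))
  } else NULL
  list(conformation = merged, accepted = accepted, n_clashes = n_clashes)
}
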