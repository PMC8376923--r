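#' Read and write likelihood maps, boxes and observable profiles
#'
#' Likelihood-map files are plain text with one line per voxel:
#' `residue_id phi_center psi_center likelihood` (whitespace separated, `#`
#' comments). Voxels omitted from the file are zero. Box files carry one box
#' per line: `residue_id phi_lo phi_hi psi_lo psi_hi`. Profile files carry
#' 2 or 3 whitespace-separated columns: abscissa, value and optionally an
#' uncertainty.
#'
#' @param path file path.
#' @return `read_likelihood_maps`: list of `TorsionLikelihoodMap`;
#'   `read_boxes`: list of `TorsionBox`; `read_profile`: an
#'   `ObservableProfile`.
#' @name map_box_io
NULL

read_table_lines <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(NULL)
  parsed <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
    if (anyNA(f)) stop("malformed record at ", path, " line ", i)
    f
  })
  parsed
}

#' @rdname map_box_io
#' @export
read_likelihood_maps <- function(path) {
  rows <- read_table_lines(path)
  if (is.null(rows)) stop("empty likelihood map file: ", path)
  df <- do.call(rbind, rows)
  if (ncol(df) != 4) stop("likelihood map lines need 4 fields")
  centers <- voxel_centers()
  out <- list()
  for (rid in sort(unique(df[, 1]))) {
    sub <- df[df[, 1] == rid, , drop = FALSE]
    grid <- matrix(0, 18, 18)
    ai <- match(sub[, 2], centers)
    bi <- match(sub[, 3], centers)
    if (anyNA(ai) || anyNA(bi)) {
      stop("voxel centers must lie on the -170 + 20k grid (residue ", rid, ")")
    }
    grid[cbind(ai, bi)] <- sub[, 4]
    out[[as.character(rid)]] <- torsion_likelihood_map(rid, grid)
  }
  out
}

#' @rdname map_box_io
#' @param maps list of `TorsionLikelihoodMap`.
#' @export
write_likelihood_maps <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# residue_id phi_center psi_center likelihood", con)
  centers <- voxel_centers()
  for (map in maps) {
    nz <- which(map$grid != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(nz))) {
      writeLines(sprintf("%d %g %g %.10g", map$residue_id,
                         centers[nz[k, 1]], centers[nz[k, 2]],
                         map$grid[nz[k, 1], nz[k, 2]]), con)
    }
  }
  invisible(path)
}

#' @rdname map_box_io
#' @export
read_boxes <- function(path) {
  rows <- read_table_lines(path)
  if (is.null(rows)) stop("empty box file: ", path)
  lapply(rows, function(f) {
    if (length(f) != 5) stop("box lines need 5 fields")
    torsion_box(f[1], f[2], f[3], f[4], f[5])
  })
}

#' @rdname map_box_io
#' @param boxes list of `TorsionBox` (possibly nested per residue).
#' @export
write_boxes <- function(boxes, path) {
  if (length(boxes) && is.list(boxes[[1]]) && !inherits(boxes[[1]], "TorsionBox")) {
    boxes <- unlist(boxes, recursive = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# residue_id phi_lo phi_hi psi_lo psi_hi", con)
  for (b in boxes) {
    writeLines(sprintf("%d %g %g %g %g", b$residue_id,
                       b$phi_lo, b$phi_hi, b$psi_lo, b$psi_hi), con)
  }
  invisible(path)
}

#' Observable profiles
#'
#' An `ObservableProfile` couples an abscissa (residue index for PRE/RDC
#' data, scattering vector q in inverse nanometres for SAXS-like data) with
#' measured or predicted values and optional positive uncertainties.
#'
#' @param kind one of `"PRE"`, `"RDC"`, `"SAXS"`.
#' @param abscissa,values numeric vectors of equal length.
#' @param uncertainties optional positive numeric vector.
#' @return an `ObservableProfile`.
#' @export
observable_profile <- function(kind, abscissa, values, uncertainties = NULL) {
  kind <- match.arg(kind, c("PRE", "RDC", "SAXS"))
  stopifnot(length(abscissa) == length(values))
  if (!is.null(uncertainties)) {
    stopifnot(length(uncertainties) == length(values), all(uncertainties > 0))
  }
  structure(list(kind = kind, abscissa = as.numeric(abscissa),
                 values = as.numeric(values),
                 uncertainties = uncertainties),
            class = "ObservableProfile")
}

#' @rdname map_box_io
#' @param kind profile kind passed to [observable_profile()].
#' @param q_unit for SAXS-like curves, `"nm"` (q in nm^-1, default) or
#'   `"angstrom"` (q converted to nm^-1 on read).
#' @export
read_profile <- function(path, kind = "SAXS", q_unit = c("nm", "angstrom")) {
  q_unit <- match.arg(q_unit)
  rows <- read_table_lines(path)
  if (is.null(rows)) stop("empty profile file: ", path)
  df <- do.call(rbind, rows)
  if (!ncol(df) %in% c(2, 3)) stop("profile lines need 2 or 3 fields")
  absc <- df[, 1]
  if (kind == "SAXS" && q_unit == "angstrom") absc <- absc * 10
  observable_profile(kind, absc, df[, 2],
                     if (ncol(df) == 3) df[, 3] else NULL)
}

#' @rdname map_box_io
#' @param profile an `ObservableProfile`.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(profile$abscissa)) {
    if (is.null(profile$uncertainties)) {
      writeLines(sprintf("%.10g %.10g", profile$abscissa[i],
                         profile$values[i]), con)
    } else {
      writeLines(sprintf("%.10g %.10g %.10g", profile$abscissa[i],
                         profile$values[i], profile$uncertainties[i]), con)
    }
  }
  invisible(path)
}

#' Read and write conformations as PDB
#'
#' Thin wrappers over bio3d's PDB reader/writer converting to and from
#' `Conformation` objects.
#'
#' @param path PDB file path.
#' @return `read_pdb_conformation`: a `Conformation`.
#' @export
read_pdb_conformation <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), ]
  conformation(resid = a$resno, resname = a$resid, atom = a$elety,
               x = a$x, y = a$y, z = a$z,
               element = ifelse(is.na(a$elesy) | a$elesy == "",
                                substr(a$elety, 1, 1), a$elesy))
}

#' @rdname read_pdb_conformation
#' @param conf a `Conformation`.
#' @export
write_pdb_conformation <- function(conf, path) {
  xyz <- as.vector(t(coords(conf)))
  bio3d::write.pdb(file = path, xyz = xyz, resno = conf$resid,
                   resid = conf$resname, elety = conf$atom,
                   elesy = conf$element)
  invisible(path)
}

#' Write conformations as a multiframe DCD trajectory
#'
#' Writes a CHARMM-style binary DCD file (one frame per conformation) plus,
#' optionally, a template PDB of the first conformation carrying the atom
#' identities. All conformations must share the same atom list.
#'
#' @param confs list of `Conformation` objects with identical atom records.
#' @param path output DCD path.
#' @param template optional path for a template PDB.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(confs, path, template = NULL) {
  natoms <- if (length(confs)) nrow(confs[[1]]) else 0L
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L)
  icntrl <- integer(20)
  icntrl[1] <- length(confs)   # frames
  icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- length(confs)
  icntrl[20] <- 24L            # format version
  wint(84L); writeChar("CORD", con, nchars = 4, eos = NULL); wint(icntrl)
  wint(84L)
  title <- formatC("generated by confenum", width = 80, flag = "-")
  wint(84L + 0L * 4L); wint(1L); writeChar(title, con, nchars = 80, eos = NULL)
  wint(84L)
  wint(4L); wint(natoms); wint(4L)
  for (cf in confs) {
    if (nrow(cf) != natoms) stop("conformations differ in atom count")
    xyz <- coords(cf)
    for (k in 1:3) {
      wint(4L * natoms)
      writeBin(as.numeric(xyz[, k]), con, size = 4L)
      wint(4L * natoms)
    }
  }
  if (!is.null(template) && length(confs)) {
    write_pdb_conformation(confs[[1]], template)
  }
  invisible(path)
}

#' Read a multiframe DCD back into conformations
#'
#' Uses bio3d's DCD reader; atom identities come from the template PDB.
#'
#' @param path DCD path.
#' @param template template PDB path.
#' @return list of `Conformation` objects.
#' @export
read_dcd_conformations <- function(path, template) {
  tmpl <- read_pdb_conformation(template)
  traj <- bio3d::read.dcd(path, verbose = FALSE)
  if (is.null(dim(traj))) traj <- matrix(traj, nrow = 1)
  lapply(seq_len(nrow(traj)), function(i) {
    m <- matrix(traj[i, ], ncol = 3, byrow = TRUE)
    tmpl$x <- m[, 1]; tmpl$y <- m[, 2]; tmpl$z <- m[, 3]
    tmpl
  })
}

# title block length fix helper (DCD title block is 4 + 80*ntitle bytes)
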