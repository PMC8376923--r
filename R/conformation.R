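#' Conformation objects
#'
#' A `Conformation` holds one molecular conformation as an ordered table of
#' atom records (residue index, residue name, atom name, element and Cartesian
#' coordinates in Angstrom). Atom order is meaningful: atoms appear in build
#' order, residue-major.
#'
#' @param resid integer vector of residue indices.
#' @param resname character vector of three-letter residue names.
#' @param atom character vector of atom names (e.g. "N", "CA", "C", "O", "CB").
#' @param x,y,z numeric coordinate vectors (Angstrom).
#' @param element optional character vector of element symbols; derived from
#'   the first letter of the atom name when missing.
#'
#' @return An object of class `Conformation`: a data.frame with columns
#'   `resid`, `resname`, `atom`, `element`, `x`, `y`, `z`.
#' @export
#' @examples
#' conformation(resid = c(1, 1), resname = "ALA",
#'              atom = c("N", "CA"), x = c(0, 1.458), y = 0, z = 0)
conformation <- function(resid, resname, atom, x, y, z, element = NULL) {
  n <- max(length(resid), length(atom), length(x))
  if (is.null(element)) element <- substr(atom, 1L, 1L)
  df <- data.frame(resid = as.integer(rep_len(resid, n)),
                   resname = rep_len(as.character(resname), n),
                   atom = rep_len(as.character(atom), n),
                   element = rep_len(as.character(element), n),
                   x = rep_len(as.numeric(x), n),
                   y = rep_len(as.numeric(y), n),
                   z = rep_len(as.numeric(z), n),
                   stringsAsFactors = FALSE)
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  class(df) <- c("Conformation", "data.frame")
  df
}

#' @export
print.Conformation <- function(x, ...) {
  cat(sprintf("Conformation: %d atoms, residues %d-%d (%s)\n",
              nrow(x), min(x$resid), max(x$resid),
              paste0(conf_sequence(x), collapse = "")))
  invisible(x)
}

as_conformation <- function(df) {
  class(df) <- c("Conformation", "data.frame")
  rownames(df) <- NULL
  df
}

#' Coordinate matrix of a conformation
#'
#' @param conf a `Conformation`.
#' @param atom optional atom-name filter (e.g. `"CA"`).
#' @return numeric matrix with one row per (selected) atom and columns x,y,z.
#' @export
coords <- function(conf, atom = NULL) {
  if (!is.null(atom)) conf <- conf[conf$atom %in% atom, , drop = FALSE]
  m <- as.matrix(conf[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Apply a rigid-body transform to a conformation
#'
#' @param conf a `Conformation`.
#' @param rotation 3x3 rotation matrix (applied first).
#' @param translation length-3 numeric vector (applied second).
#' @param center optional length-3 centre about which to rotate.
#' @return the transformed `Conformation`.
#' @export
transform_conformation <- function(conf, rotation = diag(3),
                                   translation = c(0, 0, 0), center = NULL) {
  xyz <- coords(conf)
  if (is.null(center)) center <- c(0, 0, 0)
  xyz <- sweep(xyz, 2, center)
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, center + translation, FUN = "+")
  conf$x <- xyz[, 1]; conf$y <- xyz[, 2]; conf$z <- xyz[, 3]
  conf
}

# one-letter sequence over residues, in residue order
conf_sequence <- function(conf) {
  rid <- unique(conf$resid)
  rn <- conf$resname[match(rid, conf$resid)]
  aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  out <- aa3[rn]
  out[is.na(out)] <- "X"
  unname(out)
}

# xyz of one named atom of one residue (length-3 vector); NULL when absent
atom_xyz <- function(conf, resid, atom) {
  i <- which(conf$resid == resid & conf$atom == atom)
  if (length(i) == 0L) return(NULL)
  c(conf$x[i[1]], conf$y[i[1]], conf$z[i[1]])
}

vnorm <- function(v) sqrt(sum(v * v))

#' Measure a torsion (dihedral) angle
#'
#' Dihedral angle over the path p1-p2-p3-p4, in degrees in (-180, 180],
#' using the standard atan2 formulation (IUPAC sign convention).
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
measure_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle a-b-c in degrees
measure_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
}

one_to_three <- function(seq1) {
  aa1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  letters1 <- strsplit(toupper(seq1), "")[[1]]
  out <- aa1[letters1]
  if (anyNA(out)) stop("unknown one-letter residue code in sequence: ",
                       paste(letters1[is.na(out)], collapse = ","))
  unname(out)
}
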