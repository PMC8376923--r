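#' Load geometric force-field parameters
#'
#' Reads the plain-text parameter table used by the enumerator: bond lengths,
#' bond angles, improper-angle targets and van der Waals radii. The file
#' format is line based, `#` starts a comment, records are
#' whitespace-separated:
#'
#' ```
#' bond     A1 A2 length_A
#' angle    A1 A2 A3 degrees
#' improper A1 A2 A3 A4 degrees     # atom names; prefix "+" = next residue
#' radius   ELEMENT r_A
#' omega    degrees
#' ```
#'
#' The default file shipped with the package carries standard protein
#' heavy-atom geometry (Engh & Huber-style backbone bond lengths and angles,
#' Bondi van der Waals radii); every value can be overridden by supplying a
#' different file.
#'
#' @param path path to a parameter file; the packaged defaults when `NULL`.
#' @return an object of class `ForceFieldParams`: a list with elements
#'   `bonds` (named numeric, names like `"CA-C"`), `angles` (named numeric,
#'   `"N-CA-C"`), `impropers` (data.frame a, b, c, d, target), `radii`
#'   (named numeric by element) and `omega` (trans peptide torsion, degrees).
#' @export
#' @examples
#' p <- load_params()
#' bond_length(p, "N", "CA")
load_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "backbone_params.txt", package = "confenum")
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bonds <- numeric(0); angles <- numeric(0); radii <- numeric(0)
  impropers <- list()
  omega <- 180
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    kind <- f[1]
    if (kind == "bond") {
      bonds[paste(f[2], f[3], sep = "-")] <- as.numeric(f[4])
    } else if (kind == "angle") {
      angles[paste(f[2], f[3], f[4], sep = "-")] <- as.numeric(f[5])
    } else if (kind == "improper") {
      impropers[[length(impropers) + 1L]] <-
        data.frame(a = f[2], b = f[3], c = f[4], d = f[5],
                   target = as.numeric(f[6]), stringsAsFactors = FALSE)
    } else if (kind == "radius") {
      radii[f[2]] <- as.numeric(f[3])
    } else if (kind == "omega") {
      omega <- as.numeric(f[2])
    } else {
      stop("unknown parameter record: ", ln)
    }
  }
  stopifnot(all(bonds > 0), all(radii > 0))
  structure(list(bonds = bonds, angles = angles,
                 impropers = do.call(rbind, impropers),
                 radii = radii, omega = omega),
            class = "ForceFieldParams")
}

#' @rdname load_params
#' @param params a `ForceFieldParams` object.
#' @param a1,a2,a3 atom names.
#' @export
bond_length <- function(params, a1, a2) {
  v <- params$bonds[paste(a1, a2, sep = "-")]
  if (is.na(v)) v <- params$bonds[paste(a2, a1, sep = "-")]
  if (is.na(v)) stop("no bond length for ", a1, "-", a2)
  unname(v)
}

#' @rdname load_params
#' @export
bond_angle <- function(params, a1, a2, a3) {
  v <- params$angles[paste(a1, a2, a3, sep = "-")]
  if (is.na(v)) v <- params$angles[paste(a3, a2, a1, sep = "-")]
  if (is.na(v)) stop("no bond angle for ", a1, "-", a2, "-", a3)
  unname(v)
}

vdw_radius <- function(params, element) {
  v <- params$radii[element]
  if (any(is.na(v))) {
    stop("unparameterized atom: no van der Waals radius for element ",
         paste(unique(element[is.na(v)]), collapse = ","))
  }
  unname(v)
}
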