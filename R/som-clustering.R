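#' Encode a conformation for clustering
#'
#' Computes the covariance of the CA-CA distance matrix rows,
#' `C_ij = (1/n) sum_k (d_ik - dbar_i)(d_jk - dbar_j)`, and returns its four
#' largest eigenvalues followed by the four corresponding eigenvectors
#' (length n each), an input vector of length 4(n+1). Because only
#' interatomic distances enter, the encoding is invariant under rigid-body
#' motion (and blind to chirality). Eigenvector signs are fixed by forcing
#' each vector's largest-magnitude component positive so the encoding is
#' deterministic.
#'
#' @param conf a `Conformation` with at least 5 CA atoms.
#' @return numeric vector of length 4(n+1), eigenvalues first (descending).
#' @export
encode_conformation <- function(conf) {
  ca <- coords(conf, "CA")
  n <- nrow(ca)
  if (n < 5) stop("fragment too small to encode: need >= 5 CA atoms")
  D <- as.matrix(stats::dist(ca))
  Dc <- D - rowMeans(D)
  C <- (Dc %*% t(Dc)) / n
  eig <- eigen(C, symmetric = TRUE)
  vals <- eig$values[1:4]
  vecs <- eig$vectors[, 1:4, drop = FALSE]
  for (k in 1:4) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  c(vals, as.vector(vecs))
}

#' Train a periodic 2D self-organizing map
#'
#' Classic Kohonen training on a toroidal (periodic in both axes) rectangular
#' neuron lattice. Neurons are initialized uniformly at random within the
#' per-coordinate range of the inputs; at each step one input is presented,
#' its best-matching unit found, and all neurons are pulled toward the input
#' with a Gaussian neighbourhood kernel around the best-matching unit
#' (toroidal lattice distance). The learning rate decays linearly and the
#' neighbourhood radius exponentially over the schedule.
#'
#' @param vectors numeric matrix, one input vector per row (or list of
#'   vectors of equal length).
#' @param rows,cols lattice dimensions (production default 100 x 100 is set
#'   by [maybe_cluster()]; pick smaller maps for small problems).
#' @param epochs passes over the shuffled inputs (default 2).
#' @param lr learning rate range, linearly interpolated (default 0.5 to 0.05).
#' @param radius neighbourhood radius range, exponentially interpolated
#'   (default max(rows, cols)/2 to 1).
#' @param seed integer seed controlling initialization and shuffling.
#' @return a `SOMGrid`: list with `rows`, `cols`, `codes` (neurons x dim
#'   matrix, row-major over the lattice: neuron (i, j) at row (i-1)*cols+j)
#'   and the training schedule.
#' @export
train_som <- function(vectors, rows = 20L, cols = 20L, epochs = 2L,
                      lr = c(0.5, 0.05), radius = NULL, seed = 1L) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 1) stop("need at least one input vector")
  if (any(!is.finite(vectors))) stop("encoding mismatch: non-finite inputs")
  dim_v <- ncol(vectors)
  if (is.null(radius)) radius <- c(max(rows, cols) / 2, 1)
  nn <- rows * cols
  grid_i <- rep(seq_len(rows), each = cols)
  grid_j <- rep(seq_len(cols), times = rows)
  withr::with_seed(seed, {
    lo <- apply(vectors, 2, min); hi <- apply(vectors, 2, max)
    codes <- matrix(stats::runif(nn * dim_v), nn, dim_v)
    codes <- sweep(sweep(codes, 2, hi - lo, "*"), 2, lo, "+")
    order_all <- unlist(lapply(seq_len(epochs), function(e) {
      sample.int(nrow(vectors))
    }))
    total <- length(order_all)
    for (step in seq_len(total)) {
      v <- vectors[order_all[step], ]
      frac <- (step - 1) / max(1, total - 1)
      alpha <- lr[1] + (lr[2] - lr[1]) * frac
      sigma <- radius[1] * (radius[2] / radius[1])^frac
      bmu <- which.min(colSums((t(codes) - v)^2))
      di <- abs(grid_i - grid_i[bmu]); di <- pmin(di, rows - di)
      dj <- abs(grid_j - grid_j[bmu]); dj <- pmin(dj, cols - dj)
      h <- alpha * exp(-(di^2 + dj^2) / (2 * sigma^2))
      active <- which(h > 1e-6)
      codes[active, ] <- codes[active, ] +
        h[active] * (matrix(v, length(active), dim_v, byrow = TRUE) -
                       codes[active, , drop = FALSE])
    }
    structure(list(rows = as.integer(rows), cols = as.integer(cols),
                   codes = codes, epochs = epochs, lr = lr, radius = radius,
                   seed = as.integer(seed)),
              class = "SOMGrid")
  })
}

#' Best-matching unit of each input vector
#'
#' @param som a trained `SOMGrid`.
#' @param vectors input matrix (or list) as given to [train_som()].
#' @return integer vector of neuron indices (row-major).
#' @export
assign_bmu <- function(som, vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != ncol(som$codes)) {
    stop("encoding mismatch: vector length differs from neuron length")
  }
  apply(vectors, 1, function(v) which.min(colSums((t(som$codes) - v)^2)))
}

#' U-matrix of a trained map
#'
#' For each neuron, the mean Euclidean distance between its code vector and
#' those of its eight immediate neighbours on the toroidal lattice. Local
#' minima of the U-matrix mark cluster cores (regions of high conformational
#' homogeneity).
#'
#' @param som a `SOMGrid`.
#' @return a `rows x cols` numeric matrix of class `UMatrix`.
#' @export
umatrix <- function(som) {
  rows <- som$rows; cols <- som$cols
  um <- matrix(0, rows, cols)
  idx <- function(i, j) ((i - 1) %% rows) * cols + ((j - 1) %% cols) + 1
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      acc <- acc + sqrt(sum((som$codes[idx(i, j), ] -
                               som$codes[idx(i + di, j + dj), ])^2))
    }
    um[i, j] <- acc / 8
  }
  structure(um, class = c("UMatrix", "matrix"))
}

#' Representative conformations from U-matrix minima
#'
#' Finds the local minima of the U-matrix under the toroidal 8-neighbourhood
#' (entry less than or equal to all neighbours, strictly below at least
#' one), keeps the occupied ones, and returns for each the first
#' conformation assigned to that neuron (lowest input index). When no local
#' minimum is occupied, the globally lowest occupied neuron is used instead
#' (with a message).
#'
#' @param som a `SOMGrid`.
#' @param um its `UMatrix`.
#' @param assignments integer vector of best-matching neuron per input
#'   (see [assign_bmu()]).
#' @param confs list of conformations, parallel to `assignments`.
#' @return list of representative conformations (subset of `confs`).
#' @export
extract_representatives <- function(som, um, assignments, confs) {
  stopifnot(length(assignments) == length(confs))
  rows <- som$rows; cols <- som$cols
  is_min <- matrix(FALSE, rows, cols)
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    neigh <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      neigh <- c(neigh, um[((i - 1 + di) %% rows) + 1, ((j - 1 + dj) %% cols) + 1])
    }
    is_min[i, j] <- all(um[i, j] <= neigh) && any(um[i, j] < neigh)
  }
  min_neurons <- which(t(is_min))  # row-major indices
  occupied <- unique(assignments)
  chosen <- intersect(min_neurons, occupied)
  if (length(chosen) == 0) {
    umt <- as.vector(t(unclass(um)))
    chosen <- occupied[which.min(umt[occupied])]
    message("no occupied U-matrix minimum; falling back to the global ",
            "minimum among occupied neurons")
  }
  reps <- lapply(chosen, function(mu) confs[[min(which(assignments == mu))]])
  reps
}

#' Cluster a conformer set when it is large
#'
#' Applies the SOM reduction only when the set holds strictly more than
#' `threshold` conformations; smaller sets pass through unchanged.
#'
#' @param confs list of `Conformation`s.
#' @param threshold size gate (default 1000; strict "larger than").
#' @param rows,cols map size used when clustering triggers.
#' @param seed training seed.
#' @param ... further arguments to [train_som()].
#' @return list of conformations (the input, or the representatives).
#' @export
maybe_cluster <- function(confs, threshold = 1000L, rows = 100L, cols = 100L,
                          seed = 1L, ...) {
  if (length(confs) <= threshold) return(confs)
  vectors <- do.call(rbind, lapply(confs, encode_conformation))
  som <- train_som(vectors, rows = rows, cols = cols, seed = seed, ...)
  um <- umatrix(som)
  extract_representatives(som, um, assign_bmu(som, vectors), confs)
}
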