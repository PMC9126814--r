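#' Upper-triangle edge index table
#'
#' Enumerates all region pairs (i, j) with i < j in row-major order
#' (sorted by i, then j). This single ordering is used everywhere a
#' connectome is vectorised, so edge vectors from different stages always
#' align. For R regions the table has R(R-1)/2 rows.
#'
#' @param nRegions number of regions.
#' @return integer matrix with columns \code{i} and \code{j}.
#' @export
#' @examples
#' edgeIndexTable(4)
edgeIndexTable <- function(nRegions) {
  stopifnot(is.numeric(nRegions), length(nRegions) == 1L, nRegions >= 2)
  R <- as.integer(nRegions)
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L)
  j <- sequence((R - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Vectorise the upper triangle of a symmetric matrix
#'
#' @param mat square matrix.
#' @param idx optional precomputed index table from [edgeIndexTable()].
#' @return numeric vector of length R(R-1)/2 in row-major (i<j) order.
#' @export
vecUpper <- function(mat, idx = NULL) {
  if (is.null(idx)) idx <- edgeIndexTable(nrow(mat))
  mat[idx]
}

#' Rebuild a symmetric matrix from an upper-triangle edge vector
#'
#' @param vec edge vector in the [edgeIndexTable()] ordering.
#' @param nRegions number of regions.
#' @param diagValue value placed on the diagonal (default 0).
#' @return symmetric \code{nRegions x nRegions} matrix.
#' @export
unvecUpper <- function(vec, nRegions, diagValue = 0) {
  idx <- edgeIndexTable(nRegions)
  stopifnot(length(vec) == nrow(idx))
  m <- matrix(diagValue, nRegions, nRegions)
  m[idx] <- vec
  m[idx[, 2:1, drop = FALSE]] <- vec
  diag(m) <- diagValue
  m
}

#' Fisher z-transform with a cap for perfect correlations
#'
#' atanh(r) diverges as |r| -> 1; downstream averaging needs finite
#' arithmetic, so |z| is capped (default 6, i.e. r ~ 0.99999).
#'
#' @param r correlations in \[-1, 1\].
#' @param cap maximum |z|.
#' @return capped Fisher z values; non-finite inputs are left as-is.
#' @export
fisherZ <- function(r, cap = 6) {
  z <- atanh(pmin(pmax(r, -1), 1))
  pmin(pmax(z, -cap), cap)
}

## Run expr with a fixed RNG seed, restoring global RNG state afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Map an edge matrix (i,j rows) to positions in the canonical edge ordering.
edgeRowsToPos <- function(edges, nRegions) {
  edges <- normalizeEdges(edges)
  i <- edges[, 1L]; j <- edges[, 2L]
  if (any(j > nRegions)) stop("edge references region beyond atlas size ", nRegions)
  ## row-major position: edges before row i, plus offset within row i
  as.integer((i - 1L) * nRegions - i * (i - 1L) / 2 + (j - i))
}

## Ensure i<j orientation and integer storage; drop duplicates.
normalizeEdges <- function(edges) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loop edge (i == j) is not a valid connection")
  storage.mode(edges) <- "integer"
  unique(edges)
}
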