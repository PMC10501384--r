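#' Manhattan (L1) distance between two feature vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return Nonnegative scalar `sum(|u - v|)`.
#' @export
manhattan <- function(u, v) {
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v))
  }
  sum(abs(u - v))
}

#' Pairwise Manhattan distance matrix over a sequence set
#'
#' Builds the m x m matrix whose (i, j) entry is the L1 distance between
#' rows i and j of the feature matrix (typically the normalized 3-mer
#' frequency encoding, for which every entry is bounded by 2).
#'
#' @param X numeric matrix, one row per sequence.
#' @return Symmetric m x m matrix with zero diagonal, row/column names
#'   taken from `rownames(X)`.
#' @export
kmer_distance_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 sequences, got ", nrow(X))
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Convert a distance matrix to a [0, 1] affinity matrix
#'
#' The learned graph operations aggregate over neighbors, so large entries
#' must mean "related"; raw L1 distances orient the other way. Two
#' order-reversing transforms are provided:
#' \describe{
#'   \item{rbf}{`exp(-d / sigma)` with `sigma` the median off-diagonal
#'     distance (falling back to the mean, then to 1, when degenerate).}
#'   \item{max_complement}{`1 - d / max(d)`.}
#' }
#' Both give a symmetric matrix with unit diagonal and entries in [0, 1].
#'
#' @param D symmetric nonnegative distance matrix.
#' @param mode affinity transform, `"rbf"` (default) or `"max_complement"`.
#' @return Similarity matrix with attributes `mode` and (for rbf) `sigma`.
#' @export
distance_to_similarity <- function(D, mode = c("rbf", "max_complement")) {
  mode <- match.arg(mode)
  D <- as.matrix(D)
  if (any(D < 0)) stop("distances must be nonnegative")
  off <- D[upper.tri(D)]
  if (mode == "rbf") {
    sigma <- stats::median(off)
    if (!is.finite(sigma) || sigma == 0) sigma <- mean(off)
    if (!is.finite(sigma) || sigma == 0) sigma <- 1
    S <- exp(-D / sigma)
    attr(S, "sigma") <- sigma
  } else {
    mx <- max(off, 0)
    if (mx == 0) {
      warning("all pairwise distances are zero; returning all-ones affinity")
      S <- matrix(1, nrow(D), ncol(D), dimnames = dimnames(D))
    } else {
      S <- 1 - D / mx
    }
  }
  diag(S) <- 1
  attr(S, "mode") <- mode
  S
}

#' Write a matrix with a JSON metadata sidecar
#'
#' Serializes a dense matrix as TSV (row names in the first column when
#' present) plus a `<path>.json` sidecar recording dimensions, column
#' order and any extra metadata.
#'
#' @param M matrix to write.
#' @param path output TSV path.
#' @param meta named list of extra metadata fields.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path, meta = list()) {
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(M)),
                     col.names = !is.null(colnames(M)))
  side <- c(list(nrow = nrow(M), ncol = ncol(M),
                 columns = colnames(M)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
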