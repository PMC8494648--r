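#' Library-size normalization
#'
#' Scales each cell to `scale_factor` total counts. With `log = TRUE`
#' (default) returns log1p of the scaled values, the working space for
#' differential expression, PCA and signature scoring throughout the
#' package.
#'
#' @param counts sparse genes x cells count matrix or an [expr_matrix()].
#' @param scale_factor target total per cell (default 1e4).
#' @param log log1p-transform after scaling.
#' @return sparse `dgCMatrix` of normalized values.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4, log = TRUE) {
  if (inherits(counts, "expr_matrix")) counts <- counts$counts
  totals <- Matrix::colSums(counts)
  totals[totals == 0] <- 1
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  dimnames(norm) <- dimnames(counts)
  if (log) norm@x <- log1p(norm@x)
  methods::as(norm, "CsparseMatrix")
}

#' Select highly variable genes
#'
#' Ranks genes by variance of the normalized log expression and returns the
#' top `n`. Constant genes are never selected.
#'
#' @param norm normalized (log1p) genes x cells matrix.
#' @param n number of genes to keep.
#' @return character vector of gene names, ordered by decreasing variance.
#' @export
variable_genes <- function(norm, n = 2000) {
  mu <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- pmax(ex2 - mu^2, 0)
  keep <- which(v > .Machine$double.eps)
  ord <- keep[order(v[keep], decreasing = TRUE)]
  rownames(norm)[utils::head(ord, n)]
}

#' Principal-component embedding
#'
#' Centers and unit-variance scales each gene, then computes the top
#' `n_pcs` principal components of the cells via truncated SVD. The sign of
#' each component is fixed (largest-magnitude loading positive) so the
#' embedding is reproducible.
#'
#' @param norm normalized genes x cells matrix (typically restricted to
#'   variable genes).
#' @param n_pcs number of components.
#' @param seed seed for the iterative SVD.
#' @return cells x `n_pcs` matrix of scores.
#' @export
pca_embed <- function(norm, n_pcs = 50, seed = 1) {
  x <- t(as.matrix(norm))               # cells x genes
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  mu <- colMeans(x)
  sdv <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  keep <- sdv > .Machine$double.eps
  x <- scale(x[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  n_pcs <- min(n_pcs, ncol(x))
  set.seed(seed)
  if (n_pcs >= 0.5 * min(dim(x)) || min(dim(x)) < 10L) {
    sv <- svd(x, nu = n_pcs, nv = n_pcs)
    scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
    v <- sv$v
  } else {
    sv <- irlba::irlba(x, nv = n_pcs)
    scores <- sv$u %*% diag(sv$d, n_pcs)
    v <- sv$v
  }
  # deterministic sign: largest |loading| per component is positive
  for (k in seq_len(ncol(scores))) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- rownames(x)
  scores
}

#' Exact k-nearest neighbours by blocked brute force
#'
#' Computes, for every row of `x`, the indices of its `k` nearest other
#' rows under Euclidean distance. Distances are evaluated exactly in blocks
#' so memory stays bounded; ties at the k-th distance are broken by lower
#' row index, making the result fully deterministic.
#'
#' @param x numeric matrix, observations in rows.
#' @param k neighbours per observation (`k < nrow(x)`).
#' @param block rows per block.
#' @return integer matrix `nrow(x)` x `k` of neighbour indices, nearest
#'   first.
#' @export
knn_exact <- function(x, k, block = 512L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of observations")
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    # squared distances, clamped at 0 for numerical safety
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    for (r in seq_along(idx)) {
      i <- idx[r]
      di <- d2[r, ]
      di[i] <- Inf
      # order by (distance, index): radix order is stable on ties
      out[i, ] <- order(di, seq_len(n), method = "radix")[seq_len(k)]
    }
  }
  out
}
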