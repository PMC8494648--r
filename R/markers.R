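#' Two-sided Wilcoxon rank-sum p-value
#'
#' The marker-detection test statistic. For `min(n, m) <= exact_max` the
#' two-sided p-value is computed by exact enumeration of all
#' `choose(n+m, n)` group assignments of the (tie-averaged) ranks —
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))` — which is correct under
#' ties. Larger groups — or small groups against a huge complement, where
#' the number of arrangements is intractable — use the normal
#' approximation with tie correction, a 0.5 continuity correction and an
#' Edgeworth kurtosis refinement.
#'
#' @param x_in,x_out numeric vectors for the group and its complement.
#' @param exact_max largest `min(n, m)` for which exact enumeration is used
#'   (provided `choose(n + m, min(n, m))` stays below ~2 million).
#' @return two-sided p-value in (0, 1].
#' @export
rank_sum_p <- function(x_in, x_out, exact_max = 8) {
  n <- length(x_in); m <- length(x_out)
  if (n == 0 || m == 0) stop("both groups must be nonempty")
  r <- rank(c(x_in, x_out))
  w <- sum(r[seq_len(n)])
  if (.ranksum_exact_feasible(n, m, exact_max)) {
    cmb <- utils::combn(n + m, n)
    ws <- colSums(matrix(r[cmb], nrow = n))
    eps <- 1e-9
    min(1, 2 * min(mean(ws <= w + eps), mean(ws >= w - eps)))
  } else {
    .ranksum_normal_p(w, n, m, r)
  }
}

.ranksum_exact_feasible <- function(n, m, exact_max = 8) {
  min(n, m) <= exact_max && choose(n + m, min(n, m)) <= 2^21
}

## tie-corrected normal approximation with continuity correction and an
## Edgeworth kurtosis refinement. The excess kurtosis of the null rank sum
## (no ties) is -(6/5)(n^2 + m^2 + nm + N)/(nm(N+1)); the fourth-order term
## phi(z)(z^3 - 3z) g2/24 sharpens the tail enough that the approximation
## tracks the exact two-sided p to a few 1e-3 already at n = m = 8.
.ranksum_normal_p <- function(w, n, m, ranks) {
  N <- n + m
  mu <- n * (N + 1) / 2
  ties <- table(ranks)
  sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  .ranksum_p_from_z(w, n, m, mu, sqrt(sig2))
}

.ranksum_p_from_z <- function(w, n, m, mu, sigma) {
  N <- n + m
  z <- pmax((abs(w - mu) - 0.5) / sigma, 0)
  g2 <- -6 / 5 * (n^2 + m^2 + n * m + N) / (n * m * (N + 1))
  tail <- stats::pnorm(-z) + stats::dnorm(z) * (z^3 - 3 * z) * g2 / 24
  pmin(1, pmax(2 * tail, .Machine$double.xmin))
}

#' Gene score: marker-specificity statistic
#'
#' `gene_score = avg_logFC * pct_in / max(pct_out, eps)`: the average log
#' fold-change times the enrichment ratio (fraction of cells expressing the
#' gene in the group of interest divided by the fraction expressing in the
#' complement). The `eps` floor keeps scores finite when no complement cell
#' expresses the gene.
#'
#' @param avg_logFC natural-log fold change of group vs complement means.
#' @param pct_in,pct_out fractions of expressing cells, in \[0, 1\].
#' @param eps floor for `pct_out` (default 0.001).
#' @return numeric score (vectorized).
#' @export
gene_score <- function(avg_logFC, pct_in, pct_out, eps = 0.001) {
  stopifnot(all(pct_in >= 0 & pct_in <= 1), all(pct_out >= 0 & pct_out <= 1))
  avg_logFC * pct_in / pmax(pct_out, eps)
}

#' Wilcoxon rank-sum differential expression for one group
#'
#' Compares cells of `group` against all other cells, gene by gene, on
#' library-size-normalized log1p expression. Reports for every gene the
#' natural-log fold change `log1p(mean_in) - log1p(mean_out)` of the
#' normalized (pre-log) group means, the expressing fractions
#' (`count > 0`), the two-sided rank-sum p-value, the Bonferroni-adjusted
#' p over all features, the enrichment ratio and the gene score. A gene is
#' `significant` at `p_adj <= 0.05`; all-zero genes get `p = 1`,
#' `avg_logFC = 0`.
#'
#' @param mat an [expr_matrix()] or raw genes x cells count matrix.
#' @param labels per-cell group labels.
#' @param group the label defining the in-group.
#' @param norm optional precomputed [normalize_counts()] output (log1p).
#' @param eps `pct_out` floor for the gene score.
#' @return data.frame with one row per gene: `gene`, `group`, `avg_logFC`,
#'   `pct_in`, `pct_out`, `p_value`, `p_adj`, `enrichment_ratio`,
#'   `gene_score`, `significant`.
#' @export
wilcoxon_de <- function(mat, labels, group, norm = NULL, eps = 0.001) {
  counts <- if (inherits(mat, "expr_matrix")) mat$counts else mat
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(counts))
  in_idx <- which(labels == group)
  if (length(in_idx) == 0) stop("group has no cells")
  if (length(in_idx) == ncol(counts)) stop("complement has no cells")
  if (is.null(norm)) norm <- normalize_counts(counts)
  .wilcoxon_de_core(counts, norm, in_idx, group, eps)
}

## internal: one-vs-rest for many groups with one rank pass
.find_markers_shared <- function(counts, norm, labels, eps = 0.001) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  rs <- .rank_stats(norm)
  out <- lapply(groups, function(g) {
    in_idx <- which(labels == g)
    if (length(in_idx) == 0 || length(in_idx) == ncol(counts)) return(NULL)
    .wilcoxon_de_core(counts, norm, in_idx, g, eps, rank_stats = rs)
  })
  do.call(rbind, out)
}

## per-gene ranks over all cells plus the tie term of the rank-sum
## variance; computed once per matrix and reused for every one-vs-rest test
.rank_stats <- function(norm) {
  dense <- as.matrix(norm)
  ranks <- t(apply(dense, 1, rank))
  N <- ncol(dense)
  tie_term <- apply(ranks, 1, function(r) {
    t <- tabulate(as.integer(round(2 * r)))   # half-ranks are integers
    t <- t[t > 1]
    sum(t^3 - t)
  })
  list(ranks = ranks, tie_term = tie_term, N = N)
}

## shared-rank core: W for the in-group is the sum of its per-gene ranks
.wilcoxon_de_core <- function(counts, norm, in_idx, group, eps,
                              rank_stats = NULL) {
  n <- length(in_idx); m <- ncol(counts) - n
  n_genes <- nrow(counts)
  p <- numeric(n_genes)
  if (.ranksum_exact_feasible(n, m)) {
    dense <- as.matrix(norm)
    for (g in seq_len(n_genes)) {
      v <- dense[g, ]
      if (all(v == 0)) { p[g] <- 1; next }
      p[g] <- rank_sum_p(v[in_idx], v[-in_idx])
    }
  } else {
    if (is.null(rank_stats)) rank_stats <- .rank_stats(norm)
    N <- rank_stats$N
    w <- rowSums(rank_stats$ranks[, in_idx, drop = FALSE])
    mu <- n * (N + 1) / 2
    sig2 <- n * m / 12 *
      ((N + 1) - rank_stats$tie_term / (N * (N - 1)))
    p <- .ranksum_p_from_z(w, n, m, mu, sqrt(pmax(sig2, .Machine$double.eps)))
    p[sig2 <= 0] <- 1
  }
  mean_in <- Matrix::rowMeans(expm1(norm[, in_idx, drop = FALSE]))
  mean_out <- Matrix::rowMeans(expm1(norm[, -in_idx, drop = FALSE]))
  lfc <- log1p(mean_in) - log1p(mean_out)
  all_zero <- Matrix::rowSums(counts != 0) == 0
  lfc[all_zero] <- 0
  pct_in <- Matrix::rowSums(counts[, in_idx, drop = FALSE] > 0) / n
  pct_out <- Matrix::rowSums(counts[, -in_idx, drop = FALSE] > 0) / m
  p_adj <- pmin(1, p * n_genes)
  p_adj[all_zero] <- 1
  data.frame(gene = rownames(counts), group = group,
             avg_logFC = lfc, pct_in = pct_in, pct_out = pct_out,
             p_value = p, p_adj = p_adj,
             enrichment_ratio = pct_in / pmax(pct_out, eps),
             gene_score = gene_score(lfc, pct_in, pct_out, eps),
             significant = p_adj <= 0.05 & !all_zero,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-sum markers for every group
#'
#' Runs [wilcoxon_de()] one-vs-rest for each label, sharing one
#' normalization pass.
#' @inheritParams wilcoxon_de
#' @return row-bound data.frame of per-group marker records.
#' @export
find_all_markers <- function(mat, labels, norm = NULL, eps = 0.001) {
  counts <- if (inherits(mat, "expr_matrix")) mat$counts else mat
  if (is.null(norm)) norm <- normalize_counts(counts)
  .find_markers_shared(counts, norm, labels, eps)
}

#' Bin gestational weeks into developmental stages
#'
#' Fixed mapping of the sampled second-trimester weeks: early = GW14, 16,
#' 17; middle = GW18, 19, 20; late = GW22, 25. Unsampled weeks are an
#' error, never interpolated.
#'
#' @param gw integer vector of gestational weeks.
#' @return factor with levels early, middle, late.
#' @export
stage_bin <- function(gw) {
  map <- c(`14` = "early", `16` = "early", `17` = "early",
           `18` = "middle", `19` = "middle", `20` = "middle",
           `22` = "late", `25` = "late")
  key <- as.character(gw)
  bad <- setdiff(unique(key), names(map))
  if (length(bad))
    stop("gestational week(s) not in the sampled set: ",
         paste(bad, collapse = ", "))
  factor(unname(map[key]), levels = c("early", "middle", "late"))
}

#' Restrict a marker table to transcription factors
#'
#' Keeps records whose gene symbol appears in a transcription-factor list
#' (case-insensitive symbol match), e.g. the 1,632-entry human TF catalogue
#' distributed by AnimalTFDB as one symbol per line.
#'
#' @param markers marker data.frame with a `gene` column.
#' @param tf_list character vector of TF symbols, or path to a
#'   one-symbol-per-line text file.
#' @return the matching subset; warns (does not error) when empty.
#' @export
annotate_tfs <- function(markers, tf_list) {
  if (length(tf_list) == 1 && file.exists(tf_list))
    tf_list <- readLines(tf_list, warn = FALSE)
  tf_list <- toupper(trimws(tf_list))
  tf_list <- tf_list[nzchar(tf_list)]
  if (!length(tf_list)) stop("tf_list is empty")
  out <- markers[toupper(markers$gene) %in% tf_list, , drop = FALSE]
  if (nrow(markers) > 0 && nrow(out) == 0)
    warning("no marker genes found in the transcription factor list")
  rownames(out) <- NULL
  out
}

#' Group-scaled mean expression for dot plots
#'
#' For each gene, takes the mean normalized expression over *non-zero*
#' cells within each group, then z-scores those means across groups with
#' the `scale()` convention (sample SD, denominator n - 1; two groups with
#' means 1 and 3 score -0.707/+0.707). A group with no expressing cells
#' contributes a pre-scaling mean of 0 and is flagged; a gene with equal
#' means in all groups has zero variance and is reported as all-zero
#' z-scores, also flagged. The fraction of expressing cells per group is
#' reported alongside.
#'
#' @param mat an [expr_matrix()] or genes x cells count matrix.
#' @param genes genes to tabulate.
#' @param grouping per-cell group labels (>= 2 groups).
#' @param norm optional precomputed [normalize_counts()] output.
#' @return list with matrices `z`, `mean_nonzero`, `pct` (genes x groups)
#'   and logical `flagged` (genes x groups marks empty groups; attribute
#'   `zero_variance` marks flat genes).
#' @export
group_scaled_means <- function(mat, genes, grouping, norm = NULL) {
  counts <- if (inherits(mat, "expr_matrix")) mat$counts else mat
  grouping <- as.character(grouping)
  groups <- sort(unique(grouping))
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(norm)) norm <- normalize_counts(counts)
  genes <- intersect(genes, rownames(counts))
  mz <- pct <- matrix(0, length(genes), length(groups),
                      dimnames = list(genes, groups))
  flagged <- matrix(FALSE, length(genes), length(groups),
                    dimnames = list(genes, groups))
  for (j in seq_along(groups)) {
    idx <- which(grouping == groups[j])
    sub <- norm[genes, idx, drop = FALSE]
    nnz <- Matrix::rowSums(sub > 0)
    tot <- Matrix::rowSums(sub)
    mz[, j] <- ifelse(nnz > 0, tot / pmax(nnz, 1), 0)
    flagged[, j] <- nnz == 0
    pct[, j] <- Matrix::rowSums(counts[genes, idx, drop = FALSE] > 0) /
      length(idx)
  }
  mu <- rowMeans(mz)
  sdp <- sqrt(rowSums((mz - mu)^2) / (ncol(mz) - 1))   # scale() convention
  z <- (mz - mu) / ifelse(sdp > 0, sdp, 1)
  z[sdp == 0, ] <- 0
  structure(list(z = z, mean_nonzero = mz, pct = pct, flagged = flagged),
            zero_variance = rownames(z)[sdp == 0])
}

#' Module eigengene: first-PC signature score
#'
#' Scores every cell for the activity of a gene set as the first principal
#' component of the standardized expression of the genes in the set that
#' are expressed (count > 0) in the scored cells. When more than
#' `max_cells` cells are present, a seeded random subset of `max_cells`
#' cells is scored. The score has unit variance over the scored cells and
#' its sign is oriented so that it correlates non-negatively with the mean
#' standardized expression of the set.
#'
#' @param mat an [expr_matrix()] or genes x cells count matrix.
#' @param gene_set character vector of gene symbols (the signature).
#' @param max_cells subsample ceiling (default 10000).
#' @param seed seed for the subsample.
#' @param norm optional precomputed [normalize_counts()] output.
#' @return list of class `signature_score`: `score` (named numeric over the
#'   scored cells), `genes_used`, `cells_used`, `sign`.
#' @export
module_eigengene <- function(mat, gene_set, max_cells = 10000, seed = 1,
                             norm = NULL) {
  counts <- if (inherits(mat, "expr_matrix")) mat$counts else mat
  if (is.null(norm)) norm <- normalize_counts(counts)
  cells <- colnames(counts)
  if (length(cells) > max_cells) {
    set.seed(seed)
    cells <- sort(sample(cells, max_cells))
  }
  expressed <- rownames(counts)[
    Matrix::rowSums(counts[, cells, drop = FALSE] > 0) > 0]
  genes_used <- intersect(gene_set, expressed)
  if (!length(genes_used))
    stop("signature has no genes expressed in the scored cells")
  x <- t(as.matrix(norm[genes_used, cells, drop = FALSE]))  # cells x genes
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  sv <- svd(x, nu = 1, nv = 1)
  score <- drop(sv$u[, 1])
  sgn <- 1
  avg <- rowMeans(x)
  if (stats::sd(score) > 0 && stats::sd(avg) > 0 &&
      stats::cor(score, avg) < 0) sgn <- -1
  score <- sgn * score
  score <- score / stats::sd(score)       # unit variance over scored cells
  names(score) <- cells
  structure(list(score = score, genes_used = genes_used,
                 cells_used = cells, sign = sgn),
            class = "signature_score")
}

#' @method print signature_score
#' @export
print.signature_score <- function(x, ...) {
  cat(sprintf("signature_score: %d cells, %d genes used (sign %+d)\n",
              length(x$score), length(x$genes_used), x$sign))
  invisible(x)
}
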