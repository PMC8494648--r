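#' Quality-control configuration
#'
#' Thresholds for the stringent cell-filtering stage: a cell is kept when
#' it has at least `min_genes_per_cell` detected genes (>= 750 by
#' default), at most `max_mito_fraction` of its counts from mitochondrial
#' genes (cells with more than 10% are removed), and a simulated-doublet
#' score below `doublet_score_threshold`.
#'
#' @param min_genes_per_cell minimum detected genes (count > 0) to keep a
#'   cell; the boundary value itself is kept.
#' @param max_mito_fraction maximum mitochondrial count fraction; the
#'   boundary value itself is kept (strictly greater is removed).
#' @param doublet_score_threshold cells with score >= this are removed.
#' @param n_simulated_doublets simulated doublets per lane; `NULL` means
#'   one per observed cell.
#' @param knn_k neighbours used for the doublet score.
#' @param n_pcs principal components for the doublet embedding.
#' @param seed seed for doublet simulation.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_genes_per_cell = 750,
                      max_mito_fraction = 0.10,
                      doublet_score_threshold = 0.25,
                      n_simulated_doublets = NULL,
                      knn_k = 30,
                      n_pcs = 30,
                      seed = 1) {
  stopifnot(min_genes_per_cell >= 1,
            max_mito_fraction > 0, max_mito_fraction < 1,
            doublet_score_threshold >= 0, doublet_score_threshold <= 1,
            knn_k >= 1, n_pcs >= 1)
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 max_mito_fraction = max_mito_fraction,
                 doublet_score_threshold = doublet_score_threshold,
                 n_simulated_doublets = n_simulated_doublets,
                 knn_k = as.integer(knn_k), n_pcs = as.integer(n_pcs),
                 seed = seed),
            class = "qc_config")
}

#' Simulated-doublet score for one capture lane
#'
#' Synthesizes artificial doublets by summing random pairs of observed
#' cells, embeds observed and simulated cells together (library-size
#' normalize, log1p, top 2,000 variable genes, `n_pcs` PCs), and scores
#' each observed cell as the fraction of its `knn_k` nearest neighbours
#' (among the other observed cells and all simulated doublets) that are
#' simulated. Deterministic per `config$seed`; run one lane (individual)
#' at a time.
#'
#' @param mat an [expr_matrix()] or genes x cells count matrix for a
#'   single lane.
#' @param config a [qc_config()].
#' @return numeric vector of scores in \[0, 1\], one per cell.
#' @export
doublet_score <- function(mat, config = qc_config()) {
  counts <- if (inherits(mat, "expr_matrix")) mat$counts else mat
  n <- ncol(counts)
  if (n == 0) stop("empty matrix")
  if (n < config$knn_k + 1)
    stop("need more cells than knn_k to score doublets")
  n_sim <- if (is.null(config$n_simulated_doublets)) n else
    config$n_simulated_doublets
  if (n_sim < 1) stop("n_simulated_doublets must be >= 1")
  set.seed(config$seed)
  p1 <- sample.int(n, n_sim, replace = TRUE)
  p2 <- (p1 + sample.int(n - 1L, n_sim, replace = TRUE) - 1L) %% n + 1L
  sim <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  colnames(sim) <- sprintf("sim%06d", seq_len(n_sim))
  combined <- cbind(counts, sim)
  norm <- normalize_counts(combined)
  hvg <- variable_genes(norm, 2000)
  pcs <- pca_embed(norm[hvg, , drop = FALSE], n_pcs = config$n_pcs,
                   seed = config$seed)
  nn <- knn_exact(pcs, config$knn_k)
  is_sim <- c(rep(FALSE, n), rep(TRUE, n_sim))
  scores <- rowMeans(matrix(is_sim[nn[seq_len(n), ]], nrow = n))
  names(scores) <- colnames(counts)
  scores
}

#' Filter cells on doublet score, detected genes and mitochondrial content
#'
#' Applies the three QC filters per lane (individual), doublet scoring
#' first, then the gene and mitochondrial thresholds. Semantics are
#' pinned to the filtering contract: a cell is retained iff
#' `genes_detected >= min_genes_per_cell` AND
#' `mito_fraction <= max_mito_fraction` AND
#' `doublet_score < doublet_score_threshold`.
#'
#' @param mat an [expr_matrix()] whose `genes` metadata flags mitochondrial
#'   genes (`mito` column) and whose `cells` metadata carries `individual`
#'   (lane) labels; a bare matrix is treated as one lane with no mito genes.
#' @param config a [qc_config()].
#' @param doublet_scores optional precomputed per-cell scores (named or in
#'   column order); when `NULL` they are computed per lane with
#'   [doublet_score()].
#' @return list with `matrix` (the filtered [expr_matrix()]) and `report`
#'   (class `qc_report`): per-cell `genes_detected`, `mito_fraction`,
#'   `doublet_score`, `pass` and failure reasons, plus a `summary` count
#'   per filter.
#' @export
filter_cells <- function(mat, config = qc_config(), doublet_scores = NULL) {
  if (!inherits(mat, "expr_matrix")) {
    counts <- mat
    mat <- expr_matrix(counts,
                       data.frame(cell_id = colnames(counts),
                                  individual = "lane1"),
                       data.frame(gene_id = rownames(counts), mito = FALSE))
  }
  counts <- mat$counts
  if (ncol(counts) == 0) stop("empty matrix")
  lane <- if ("individual" %in% names(mat$cells))
    as.character(mat$cells$individual) else rep("lane1", ncol(counts))
  if (is.null(doublet_scores)) {
    doublet_scores <- numeric(ncol(counts))
    for (l in unique(lane)) {
      idx <- which(lane == l)
      doublet_scores[idx] <- doublet_score(counts[, idx, drop = FALSE], config)
    }
  } else if (!is.null(names(doublet_scores))) {
    doublet_scores <- doublet_scores[colnames(counts)]
  }
  genes_detected <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  mito_counts <- Matrix::colSums(counts[mat$genes$mito, , drop = FALSE])
  mito_fraction <- ifelse(totals > 0, mito_counts / totals, 0)

  fail_doublet <- doublet_scores >= config$doublet_score_threshold
  fail_genes <- genes_detected < config$min_genes_per_cell
  fail_mito <- mito_fraction > config$max_mito_fraction
  pass <- !(fail_doublet | fail_genes | fail_mito)
  reasons <- mapply(function(d, g, m) paste(
    c("doublet"[d], "low_genes"[g], "high_mito"[m]), collapse = ";"),
    fail_doublet, fail_genes, fail_mito)
  report <- structure(list(
    cells = data.frame(cell_id = colnames(counts), individual = lane,
                       genes_detected = as.integer(genes_detected),
                       mito_fraction = mito_fraction,
                       doublet_score = unname(doublet_scores),
                       pass = pass, reasons = unname(reasons),
                       stringsAsFactors = FALSE),
    summary = c(n_input = ncol(counts),
                n_fail_doublet = sum(fail_doublet),
                n_fail_genes = sum(fail_genes),
                n_fail_mito = sum(fail_mito),
                n_retained = sum(pass)),
    config = config), class = "qc_report")
  if (!any(pass)) stop("empty after QC: no cells pass all filters")
  list(matrix = mat[, which(pass)], report = report)
}

#' @method print qc_report
#' @export
print.qc_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "qc_report: %d cells in, %d retained (%d doublet, %d low-gene, %d high-mito failures)\n",
    s["n_input"], s["n_retained"], s["n_fail_doublet"],
    s["n_fail_genes"], s["n_fail_mito"]))
  invisible(x)
}
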