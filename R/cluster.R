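#' Jaccard-weighted shared-nearest-neighbour graph
#'
#' Builds the Louvain-Jaccard cluster graph: for each cell the `k` nearest
#' neighbours in PC space (self excluded, ties broken by cell index), then
#' an undirected edge between every pair of cells sharing neighbourhood,
#' weighted by the Jaccard overlap of their k-neighbour sets,
#' `|N(i) & N(j)| / |N(i) | N(j)|`.
#'
#' @param pc_coords cells x PCs numeric matrix.
#' @param k neighbours per cell (`k < n_cells`).
#' @return an [igraph::graph] with `weight` edge attribute in \[0, 1\]; a
#'   `knn` attribute carries the neighbour-index matrix.
#' @export
build_knn_jaccard_graph <- function(pc_coords, k) {
  pc_coords <- as.matrix(pc_coords)
  if (any(!is.finite(pc_coords))) stop("PC coordinates must be finite")
  n <- nrow(pc_coords)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- knn_exact(pc_coords, k)
  ## sparse cell x cell neighbour indicator; shared counts via crossprod
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)                   # |N(i) & N(j)|
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j & shared@x > 0
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L
  inter <- shared@x[keep]
  jac <- inter / (2 * k - inter)
  g <- igraph::graph_from_data_frame(
    data.frame(from = i, to = j, weight = jac),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  if (!is.null(rownames(pc_coords)))
    igraph::V(g)$cell <- rownames(pc_coords)
  g$knn <- nn
  g
}

#' Louvain community detection on the Jaccard graph
#'
#' Modularity maximization (multi-level Louvain) on the Jaccard-weighted
#' graph. Seeded so repeated runs give bitwise-identical labels; isolated
#' cells become singleton communities.
#'
#' @param graph graph from [build_knn_jaccard_graph()].
#' @param resolution Louvain resolution (smaller = coarser; default 1).
#' @param seed RNG seed.
#' @return integer vector of 1-based contiguous community labels, one per
#'   vertex.
#' @export
louvain_cluster <- function(graph, resolution = 1, seed = 1) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  labels <- as.integer(igraph::membership(cl))
  match(labels, sort(unique(labels)))
}

#' Annotate clusters with cell types from a canonical marker panel
#'
#' Assigns each cluster the cell type whose panel genes are most highly
#' expressed in it: per panel gene, mean normalized expression per cluster
#' is z-scored across clusters; a cluster's type is the argmax of the mean
#' z over each type's panel.
#'
#' @param mat an [expr_matrix()] or genes x cells count matrix.
#' @param labels per-cell cluster labels.
#' @param panel named list: cell type -> character vector of marker genes.
#' @param norm optional precomputed [normalize_counts()] output.
#' @return named character vector: cluster label -> cell type.
#' @export
annotate_celltypes <- function(mat, labels, panel, norm = NULL) {
  counts <- if (inherits(mat, "expr_matrix")) mat$counts else mat
  if (is.null(norm)) norm <- normalize_counts(counts)
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  genes <- intersect(unique(unlist(panel)), rownames(counts))
  if (!length(genes)) stop("no panel genes present in the matrix")
  means <- sapply(clusters, function(cl)
    Matrix::rowMeans(norm[genes, labels == cl, drop = FALSE]))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, clusters))
  z <- t(scale(t(means)))
  z[!is.finite(z)] <- 0
  ann <- vapply(clusters, function(cl) {
    sc <- vapply(names(panel), function(tt) {
      gg <- intersect(panel[[tt]], genes)
      if (!length(gg)) return(-Inf)
      mean(z[gg, cl])
    }, numeric(1))
    names(panel)[which.max(sc)]
  }, character(1))
  names(ann) <- clusters
  ann
}

#' Clustering parameters for the recursive workflow
#'
#' @param n_hvg variable genes per clustering run.
#' @param n_pcs principal components per run.
#' @param knn_k neighbours for the Jaccard graph.
#' @param resolution Louvain resolution.
#' @param min_cells cell types smaller than this skip subclustering.
#' @param merge_threshold Pearson correlation at or above which cluster
#'   gene-score profiles are merged. The single most consequential free
#'   parameter of the merge stage.
#' @param prune_jaccard Jaccard weights at or below this are dropped from
#'   the cluster graph before community detection (default 1/15, the
#'   conventional shared-nearest-neighbour pruning cutoff at k = 15;
#'   spurious weak links between well-separated populations otherwise
#'   blur community boundaries).
#' @param seed seed for every stochastic step.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(n_hvg = 2000, n_pcs = 50, knn_k = 15,
                           resolution = 1, min_cells = 50,
                           merge_threshold = 0.7, prune_jaccard = 1 / 15,
                           seed = 1) {
  stopifnot(n_hvg >= 2, n_pcs >= 2, knn_k >= 1,
            resolution > 0, min_cells >= 2,
            merge_threshold > 0, merge_threshold < 1,
            prune_jaccard >= 0, prune_jaccard < 1)
  structure(list(n_hvg = n_hvg, n_pcs = n_pcs, knn_k = knn_k,
                 resolution = resolution, min_cells = min_cells,
                 merge_threshold = merge_threshold,
                 prune_jaccard = prune_jaccard, seed = seed),
            class = "cluster_params")
}

## one Louvain-Jaccard run: normalize -> HVG -> PCA -> kNN Jaccard -> Louvain
.cluster_once <- function(counts, params) {
  n <- ncol(counts)
  if (n < 3) return(rep(1L, n))
  norm <- normalize_counts(counts)
  hvg <- variable_genes(norm, params$n_hvg)
  if (length(hvg) < 2) return(rep(1L, n))
  k <- min(params$knn_k, n - 1L)
  pcs <- pca_embed(norm[hvg, , drop = FALSE],
                   n_pcs = min(params$n_pcs, n - 1L, length(hvg)),
                   seed = params$seed)
  g <- build_knn_jaccard_graph(pcs, k)
  if (params$prune_jaccard > 0)
    g <- igraph::delete_edges(
      g, igraph::E(g)[igraph::E(g)$weight <= params$prune_jaccard])
  louvain_cluster(g, params$resolution, params$seed)
}

#' Recursive per-individual clustering with cell-type subclustering
#'
#' Level 1: Louvain-Jaccard clustering run independently within each
#' individual, minimizing batch effects and keeping rare populations
#' detectable. Level-1 clusters are annotated with cell types by
#' [annotate_celltypes()] against `panel`. Level 2: the cells of each
#' (individual, cell type) with at least `min_cells` cells are re-embedded
#' and re-clustered; smaller groups keep a single subcluster.
#'
#' @param mat an [expr_matrix()] with an `individual` cell column.
#' @param panel named list: cell type -> canonical marker genes.
#' @param params a [cluster_params()].
#' @return data.frame of class `cluster_table`: `cell_id`, `individual`,
#'   `level1` (individual-prefixed cluster), `celltype`, `level2`
#'   (individual- and type-prefixed subcluster).
#' @export
recursive_cluster <- function(mat, panel, params = cluster_params()) {
  stopifnot(inherits(mat, "expr_matrix"),
            "individual" %in% names(mat$cells))
  cells <- mat$cells
  out <- data.frame(cell_id = cells$cell_id,
                    individual = as.character(cells$individual),
                    level1 = NA_character_, celltype = NA_character_,
                    level2 = NA_character_, stringsAsFactors = FALSE)
  for (ind in unique(out$individual)) {
    idx <- which(out$individual == ind)
    sub <- mat$counts[, idx, drop = FALSE]
    l1 <- .cluster_once(sub, params)
    ann <- annotate_celltypes(sub, l1, panel)
    out$level1[idx] <- sprintf("%s.%d", ind, l1)
    out$celltype[idx] <- ann[as.character(l1)]
    for (tt in unique(out$celltype[idx])) {
      tidx <- idx[out$celltype[idx] == tt]
      if (length(tidx) < params$min_cells) {
        out$level2[tidx] <- sprintf("%s.%s.1", ind, tt)
        next
      }
      l2 <- .cluster_once(mat$counts[, tidx, drop = FALSE], params)
      out$level2[tidx] <- sprintf("%s.%s.%d", ind, tt, l2)
    }
  }
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Gene-score profiles of clusters
#'
#' One-vs-rest rank-sum markers per cluster (within the stated background)
#' summarized as a clusters x genes matrix of gene scores: the score where
#' the gene is a significant (adjusted p <= 0.05) up-regulated marker of
#' the cluster, 0 elsewhere. Columns span the union of all clusters'
#' marker genes. Used to correlate and merge clusters across individuals
#' and to build cluster dendrograms.
#'
#' @param mat an [expr_matrix()] or genes x cells count matrix.
#' @param labels per-cell cluster labels.
#' @param per_individual when TRUE (and `mat` carries `individual`
#'   metadata), each cluster is tested against the other cells of its own
#'   individual only, bridging batch effects as the merge stage expects.
#' @return matrix of class `gene_score_profiles` (clusters x marker-gene
#'   union).
#' @export
gene_score_profiles <- function(mat, labels, per_individual = FALSE) {
  counts <- if (inherits(mat, "expr_matrix")) mat$counts else mat
  labels <- as.character(labels)
  if (per_individual && inherits(mat, "expr_matrix") &&
      "individual" %in% names(mat$cells)) {
    ind <- as.character(mat$cells$individual)
    recs <- do.call(rbind, lapply(unique(ind), function(ii) {
      idx <- which(ind == ii)
      sub <- counts[, idx, drop = FALSE]
      .find_markers_shared(sub, normalize_counts(sub), labels[idx])
    }))
  } else {
    recs <- .find_markers_shared(counts, normalize_counts(counts), labels)
  }
  recs <- recs[recs$significant & recs$avg_logFC > 0, , drop = FALSE]
  clusters <- sort(unique(labels))
  genes <- sort(unique(recs$gene))
  prof <- matrix(0, length(clusters), length(genes),
                 dimnames = list(clusters, genes))
  if (nrow(recs))
    prof[cbind(match(recs$group, clusters), match(recs$gene, genes))] <-
      recs$gene_score
  class(prof) <- c("gene_score_profiles", "matrix", "array")
  prof
}

## single-linkage grouping at a correlation threshold: connected components
## of the graph joining profile pairs with Pearson r >= threshold
.merge_components <- function(prof, threshold) {
  n <- nrow(prof)
  if (n == 1) return(1L)
  sds <- apply(prof, 1, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate))
    warning("zero-variance gene-score profile(s) treated as unmergeable: ",
            paste(rownames(prof)[degenerate], collapse = ", "))
  r <- matrix(-1, n, n)
  ok <- which(!degenerate)
  if (length(ok) > 1) r[ok, ok] <- stats::cor(t(prof[ok, , drop = FALSE]))
  adj <- r >= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max", diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Correlate and merge clusters across individuals
#'
#' The batch-bridging step: clusters whose gene-score profiles correlate
#' at Pearson `r >= merge_threshold` are combined by single-linkage
#' grouping (connected components of the thresholded correlation graph).
#' Round 1 merges within each cell type across individuals; the merged
#' clusters' profiles are then recomputed from their pooled cells and
#' round 2 merges across all clusters from all individuals and cell types.
#' Zero-variance profiles are unmergeable and kept as their own cluster
#' (with a warning).
#'
#' @param profiles a [gene_score_profiles()] matrix over level-2 clusters.
#' @param merge_threshold correlation threshold in (0, 1).
#' @param rounds 1 (profile-only, single pass) or 2 (the full iterative
#'   combination; requires `mat` and `table`).
#' @param mat the [expr_matrix()] the clusters came from (rounds = 2).
#' @param table the `cluster_table` from [recursive_cluster()] (rounds = 2);
#'   row clusters of `profiles` must match its `level2` labels.
#' @return named character vector: level-2 cluster -> merged level-3 label
#'   (`m1`, `m2`, ...; labelled in order of first appearance of their
#'   members, sorted by input cluster name).
#' @export
correlate_and_merge <- function(profiles, merge_threshold = 0.7, rounds = 2,
                                mat = NULL, table = NULL) {
  stopifnot(merge_threshold > 0, merge_threshold < 1, rounds %in% 1:2)
  prof <- unclass(profiles)
  l2 <- rownames(prof)
  if (rounds == 1 || is.null(mat) || is.null(table)) {
    comp <- .merge_components(prof, merge_threshold)
    return(stats::setNames(sprintf("m%d", comp), l2))
  }
  stopifnot(inherits(table, "cluster_table"), all(table$level2 %in% l2) ||
              all(l2 %in% table$level2))
  ctype <- vapply(l2, function(x)
    table$celltype[match(x, table$level2)], character(1))
  ## round 1: within cell type, across individuals
  group1 <- stats::setNames(rep(NA_character_, length(l2)), l2)
  for (tt in unique(ctype)) {
    rows <- which(ctype == tt)
    comp <- .merge_components(prof[rows, , drop = FALSE], merge_threshold)
    group1[rows] <- sprintf("%s#%d", tt, comp)
  }
  ## recompute profiles from pooled cells of the round-1 groups
  lab1 <- unname(group1[table$level2])
  prof1 <- gene_score_profiles(mat, lab1)
  ## round 2: across everything
  comp2 <- .merge_components(unclass(prof1), merge_threshold)
  final1 <- stats::setNames(sprintf("m%d", comp2), rownames(prof1))
  out <- stats::setNames(unname(final1[group1]), l2)
  ## relabel in deterministic order of first appearance
  lev <- unique(out[order(names(out))])
  stats::setNames(sprintf("m%d", match(out, lev)), names(out))
}

#' Attach merged level-3 labels to a cluster table
#'
#' Convenience wrapper running [gene_score_profiles()] (per individual) on
#' the level-2 clusters and [correlate_and_merge()] with two rounds.
#'
#' @param mat the [expr_matrix()].
#' @param table `cluster_table` from [recursive_cluster()].
#' @param params a [cluster_params()] (uses `merge_threshold`).
#' @return the table with a `level3` column added.
#' @export
merge_clusters <- function(mat, table, params = cluster_params()) {
  prof <- gene_score_profiles(mat, table$level2, per_individual = TRUE)
  map <- correlate_and_merge(prof, params$merge_threshold, rounds = 2,
                             mat = mat, table = table)
  table$level3 <- unname(map[table$level2])
  table
}

#' Cluster dendrogram on one-minus-Pearson distances
#'
#' Agglomerative (average linkage) tree over cluster gene-score profiles
#' with distance `d = 1 - r`. Rows are ordered by label before clustering
#' so ties resolve deterministically.
#'
#' @param profiles a [gene_score_profiles()] matrix (>= 2 clusters).
#' @return an [stats::hclust] tree; convert with [ape::as.phylo()] to
#'   write Newick.
#' @export
cluster_dendrogram <- function(profiles) {
  prof <- unclass(profiles)
  if (nrow(prof) < 2) stop("need at least 2 clusters")
  prof <- prof[order(rownames(prof)), , drop = FALSE]
  sds <- apply(prof, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene-score profile for cluster(s): ",
         paste(rownames(prof)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(prof)))
  stats::hclust(d, method = "average")
}

#' Write a cluster dendrogram as Newick
#'
#' @param hc an [stats::hclust] tree (e.g. from [cluster_dendrogram()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
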