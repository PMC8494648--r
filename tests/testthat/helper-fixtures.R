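# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

# a small but structured atlas: 2 individuals, 4 types, 3 areas
tiny_atlas_config <- function(seed = 101, ...) {
  args <- list(
    n_individuals = 2, gestational_weeks = c(16, 19),
    areas = c("PFC", "motor", "V1"),
    cell_types = c("RG", "IPC", "neuron", "microglia"),
    n_cells_per_individual = 400, n_genes = 400,
    marker_fold_change = 4, n_markers_per_celltype = 20,
    n_markers_per_area_by_celltype = c(RG = 2, IPC = 3, neuron = 4,
                                       microglia = 1),
    gradient_gene_count = 3, batch_sigma = 0.2,
    mito_gene_fraction = 0.05, doublet_rate = 0, dispersion = 2,
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(atlas_config, args)
}

# deterministic dense count matrix wrapped as expr_matrix
make_counts <- function(n_genes, n_cells, fill = 1, mito_rows = integer()) {
  counts <- matrix(fill, n_genes, n_cells,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("c%03d", seq_len(n_cells))))
  mito <- seq_len(n_genes) %in% mito_rows
  expr_matrix(counts,
              data.frame(cell_id = colnames(counts), individual = "lane1"),
              data.frame(gene_id = rownames(counts), mito = mito))
}

# exhaustive kNN by full pairwise distances (independent of knn_exact)
brute_knn <- function(x, k) {
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row, seq_along(row))[seq_len(k)]))
}

# independent two-sided exact rank-sum p: enumerate subsets, statistic is
# the Mann-Whitney U from pairwise comparisons (not a rank sum)
brute_ranksum_p <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  u_of <- function(idx) {
    a <- pool[idx]; b <- pool[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n))
  us <- apply(utils::combn(length(pool), n), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# hand-rolled average-linkage agglomeration returning the merge order as
# sets of leaf labels (independent of hclust)
brute_average_linkage <- function(d) {
  labs <- attr(d, "Labels")
  dm <- as.matrix(d)
  clusters <- as.list(labs)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        h <- mean(dm[clusters[[i]], clusters[[j]]])
        if (h < best[1] - 1e-12) best <- c(h, i, j)
      }
    i <- best[2]; j <- best[3]
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[i]], clusters[[j]]))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  merges
}

# merge order of an hclust tree as sets of leaf labels
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  members <- function(k) {
    if (k < 0) hc$labels[-k] else sets[[k]]
  }
  for (i in seq_len(nrow(hc$merge))) {
    sets[[i]] <- sort(c(members(hc$merge[i, 1]), members(hc$merge[i, 2])))
  }
  sets
}

# full-pipeline run on the default atlas, computed once per test session
.acceptance_cache <- new.env(parent = emptyenv())
default_pipeline <- function(seed = 7) {
  key <- paste0("run", seed)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  cfg <- atlas_config(seed = seed)
  atl <- generate_atlas(cfg)
  qc <- filter_cells(atl$matrix, qc_config())
  roles <- atl$truth$gene_roles
  panel <- split(roles$gene_id[roles$role == "celltype_marker"],
                 roles$owner_type[roles$role == "celltype_marker"])
  tab <- recursive_cluster(qc$matrix, panel, cluster_params(seed = seed))
  tab <- merge_clusters(qc$matrix, tab, cluster_params(seed = seed))
  out <- list(config = cfg, atlas = atl, qc = qc, table = tab)
  .acceptance_cache[[key]] <- out
  out
}
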