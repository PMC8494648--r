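test_that("Jaccard graph weights match an exhaustive set-overlap oracle", {
  set.seed(31)
  x <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(sprintf("c%02d", 1:20), NULL))
  k <- 5
  g <- build_knn_jaccard_graph(x, k)
  nn <- brute_knn(x, k)
  el <- igraph::as_data_frame(g, "edges")
  # every emitted weight equals |intersection| / |union| of neighbour sets
  for (r in seq_len(nrow(el))) {
    i <- as.integer(el$from[r]); j <- as.integer(el$to[r])
    inter <- length(intersect(nn[i, ], nn[j, ]))
    expect_equal(el$weight[r], inter / (2 * k - inter))
  }
  # and every sharing pair is present
  n_sharing <- sum(vapply(seq_len(19), function(i) sum(vapply((i + 1):20,
    function(j) length(intersect(nn[i, ], nn[j, ])) > 0, logical(1))),
    integer(1)))
  expect_equal(nrow(el), n_sharing)
  # weights symmetric and bounded
  expect_true(all(el$weight > 0 & el$weight <= 1))
})

test_that("identical and disjoint neighbour sets give weight 1 and no edge", {
  # identical sets: both i and j are nearest to {a, b} and far from each
  # other -> Jaccard 1
  x <- rbind(i = c(0, 1), j = c(0, -1), a = c(0, 0.1), b = c(0, -0.1))
  g <- build_knn_jaccard_graph(x, 2)
  el <- igraph::as_data_frame(g, "edges")
  wij <- el$weight[(el$from == "1" & el$to == "2") |
                     (el$from == "2" & el$to == "1")]
  expect_equal(wij, 1)
  # disjoint sets: mutual nearest pairs at k = 1 share nothing -> no edge
  x2 <- cbind(c(0, 0.001, 100), 0)
  g2 <- build_knn_jaccard_graph(x2, 1)
  el2 <- igraph::as_data_frame(g2, "edges")
  expect_false(any((el2$from == "1" & el2$to == "2") |
                     (el2$from == "2" & el2$to == "1")))
  # partial overlap: N(c1)={c2,c3}, N(c2)={c1,c3} -> 1/3
  x3 <- cbind(c(0, 1, 50), 0)
  g3 <- build_knn_jaccard_graph(x3, 2)
  el3 <- igraph::as_data_frame(g3, "edges")
  w12 <- el3$weight[(el3$from == "1" & el3$to == "2")]
  expect_equal(w12, 1 / 3)
})

test_that("louvain separates two cliques joined by a weak bridge", {
  # two 6-cliques with strong internal weights, one epsilon bridge
  edges <- NULL
  for (i in 1:5) for (j in (i + 1):6) edges <- rbind(edges, c(i, j, 1))
  for (i in 7:11) for (j in (i + 1):12) edges <- rbind(edges, c(i, j, 1))
  edges <- rbind(edges, c(6, 7, 0.01))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = edges[, 3]),
    directed = FALSE)
  lab <- louvain_cluster(g, resolution = 1, seed = 4)
  expect_equal(length(unique(lab)), 2)
  v <- as.integer(igraph::V(g)$name)
  expect_equal(length(unique(lab[v <= 6])), 1)
  expect_equal(length(unique(lab[v >= 7])), 1)
  # exhaustive check: no 2-partition has higher modularity than the
  # returned one
  best <- -Inf
  for (mask in 0:(2^11 - 1)) {
    mem <- c(1L, as.integer(intToBits(mask))[1:11] + 1L)
    best <- max(best, igraph::modularity(g, mem,
                                         weights = igraph::E(g)$weight))
  }
  got <- igraph::modularity(g, lab, weights = igraph::E(g)$weight)
  expect_gte(got + 1e-12, best)
})

test_that("louvain is seed-deterministic and coarsens at low resolution", {
  set.seed(8)
  x <- matrix(rnorm(80 * 3), 80, 3)
  g <- build_knn_jaccard_graph(x, 6)
  l1 <- louvain_cluster(g, 1, seed = 7)
  l2 <- louvain_cluster(g, 1, seed = 7)
  expect_identical(l1, l2)
  lc <- louvain_cluster(g, resolution = 1e-4, seed = 7)
  comp <- igraph::components(g)
  expect_lte(length(unique(lc)), comp$no)
  # partition beats all-singletons modularity
  w <- igraph::E(g)$weight
  expect_gte(igraph::modularity(g, l1, weights = w),
             igraph::modularity(g, seq_len(igraph::vcount(g)), weights = w))
})

test_that("graph construction is equivariant under cell permutation", {
  set.seed(12)
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(paste0("c", 1:40), NULL))
  perm <- sample(40)
  g1 <- build_knn_jaccard_graph(x, 5)
  g2 <- build_knn_jaccard_graph(x[perm, ], 5)
  w1 <- igraph::as_data_frame(g1, "edges")
  w2 <- igraph::as_data_frame(g2, "edges")
  key1 <- apply(cbind(pmin(as.integer(w1$from), as.integer(w1$to)),
                      pmax(as.integer(w1$from), as.integer(w1$to))), 1,
                paste, collapse = "-")
  ## map g2 vertex ids back through the permutation
  f2 <- perm[as.integer(w2$from)]; t2 <- perm[as.integer(w2$to)]
  key2 <- apply(cbind(pmin(f2, t2), pmax(f2, t2)), 1, paste, collapse = "-")
  expect_setequal(key1, key2)
  expect_equal(sort(w1$weight), sort(w2$weight))
})

test_that("cluster annotation is exact when each type has an exclusive marker", {
  # noiseless means: type t expresses marker mk_t at 10, others at 0
  types <- c("RG", "IPC", "neuron")
  counts <- matrix(0, 4, 90,
                   dimnames = list(c("SOX2", "EOMES", "NEUROD6", "HK"),
                                   sprintf("c%02d", 1:90)))
  truth <- rep(types, each = 30)
  counts["SOX2", truth == "RG"] <- 10
  counts["EOMES", truth == "IPC"] <- 10
  counts["NEUROD6", truth == "neuron"] <- 10
  counts["HK", ] <- 5
  labels <- rep(1:3, each = 30)
  panel <- list(RG = "SOX2", IPC = "EOMES", neuron = "NEUROD6")
  ann <- annotate_celltypes(counts, labels, panel)
  expect_identical(unname(ann), types)
})

test_that("recursive clustering recovers planted types within individuals", {
  cfg <- tiny_atlas_config(n_cells_per_individual = 600, seed = 23)
  atl <- generate_atlas(cfg)
  roles <- atl$truth$gene_roles
  panel <- split(roles$gene_id[roles$role == "celltype_marker"],
                 roles$owner_type[roles$role == "celltype_marker"])
  tab <- recursive_cluster(atl$matrix, panel,
                           cluster_params(min_cells = 40))
  truth <- atl$matrix$cells$true_type
  expect_gte(mclust::adjustedRandIndex(tab$celltype, truth), 0.8)
  # level-2 labels nest within (individual, cell type)
  key <- paste(tab$individual, tab$celltype)
  split_l2 <- split(key, tab$level2)
  expect_true(all(vapply(split_l2, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("single individual, single cell type degenerates to one subclustering", {
  cfg <- tiny_atlas_config(n_individuals = 1, cell_types = "RG",
                           n_markers_per_area_by_celltype = c(RG = 2),
                           n_cells_per_individual = 150, seed = 9)
  atl <- generate_atlas(cfg)
  panel <- list(RG = atl$truth$gene_roles$gene_id[
    atl$truth$gene_roles$role == "celltype_marker"][1:3])
  params <- cluster_params(min_cells = 40)
  tab <- recursive_cluster(atl$matrix, panel, params)
  expect_true(all(tab$celltype == "RG"))
  direct <- cortexatlas:::.cluster_once(atl$matrix$counts, params)
  expect_equal(length(unique(tab$level2)), length(unique(direct)))
})

test_that("identical profiles merge and orthogonal profiles never do", {
  prof <- rbind(a = c(1, 2, 3, 0, 0, 0),
                b = c(1, 2, 3, 0, 0, 0),
                c = c(0, 0, 0, 3, 2, 1))
  class(prof) <- c("gene_score_profiles", "matrix", "array")
  map <- correlate_and_merge(prof, merge_threshold = 0.7, rounds = 1)
  expect_equal(map[["a"]], map[["b"]])
  expect_false(map[["a"]] == map[["c"]])
  # anti-correlated pair stays apart at any positive threshold
  prof2 <- rbind(u = c(1, 2, 3), v = c(3, 2, 1))
  class(prof2) <- class(prof)
  map2 <- correlate_and_merge(prof2, merge_threshold = 0.1, rounds = 1)
  expect_false(map2[["u"]] == map2[["v"]])
})

test_that("zero-variance profiles are unmergeable and flagged", {
  prof <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(1.1, 2, 3))
  class(prof) <- c("gene_score_profiles", "matrix", "array")
  expect_warning(map <- correlate_and_merge(prof, 0.7, rounds = 1),
                 "unmergeable")
  expect_false(map[["a"]] == map[["b"]])
  expect_equal(map[["b"]], map[["c"]])
})

test_that("lowering the merge threshold never increases cluster count", {
  set.seed(41)
  prof <- matrix(rexp(12 * 30), 12, 30,
                 dimnames = list(paste0("cl", 1:12), NULL))
  class(prof) <- c("gene_score_profiles", "matrix", "array")
  ks <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(th)
    length(unique(correlate_and_merge(prof, th, rounds = 1))), numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("batch-split planted types reunite after the two merge rounds", {
  cfg <- tiny_atlas_config(n_individuals = 3, gestational_weeks = c(16, 19, 22),
                           n_cells_per_individual = 800, batch_sigma = 0.3,
                           seed = 37)
  atl <- generate_atlas(cfg)
  roles <- atl$truth$gene_roles
  panel <- split(roles$gene_id[roles$role == "celltype_marker"],
                 roles$owner_type[roles$role == "celltype_marker"])
  tab <- recursive_cluster(atl$matrix, panel, cluster_params(min_cells = 40))
  tab <- merge_clusters(atl$matrix, tab, cluster_params(min_cells = 40))
  truth <- atl$matrix$cells$true_type
  expect_gte(mclust::adjustedRandIndex(tab$level3, truth), 0.8)
  # the bulk of cells land in merged clusters spanning individuals
  spans <- tapply(tab$individual, tab$level3, function(v) length(unique(v)))
  sizes <- table(tab$level3)
  bridged <- sum(sizes[names(spans)[spans > 1]]) / sum(sizes)
  expect_gte(bridged, 0.8)
})

test_that("dendrogram uses one-minus-Pearson distance with average linkage", {
  prof <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4.1),
                c = c(4, 3, 2, 1), d = c(2, 1, 4, 3),
                e = c(1.2, 2.2, 2.9, 4.2))
  class(prof) <- c("gene_score_profiles", "matrix", "array")
  hc <- cluster_dendrogram(prof)
  # identical-ish profiles merge first
  first <- hclust_merge_sets(hc)[[1]]
  expect_true(all(c("a", "b") %in% first) || all(c("a", "e") %in% first))
  # merge order equals a brute-force average-linkage oracle
  d <- stats::as.dist(1 - cor(t(unclass(prof))))
  expect_identical(hclust_merge_sets(hc), brute_average_linkage(d))
  # anti-correlated profiles sit at distance 2 and join last
  prof3 <- rbind(x = c(1, 2, 3), y = c(3, 2, 1), z = c(1.1, 2, 3.2))
  class(prof3) <- class(prof)
  hc3 <- cluster_dendrogram(prof3)
  sets3 <- hclust_merge_sets(hc3)
  expect_setequal(sets3[[1]], c("x", "z"))
  expect_equal(max(hc3$height), mean(c(1 - cor(c(1,2,3), c(3,2,1)),
                                       1 - cor(c(1.1,2,3.2), c(3,2,1)))))
  expect_error(cluster_dendrogram(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant")
})
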