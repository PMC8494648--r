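#' Directed cross-group neighbour fractions
#'
#' The constellation edge statistic: the `knn_k` nearest neighbours of
#' every cell are found in PC space (self excluded, exact search, ties by
#' cell index); for each ordered group pair (A, B) the fraction is the
#' share of A's pooled neighbour slots (`knn_k * |A|`) occupied by B
#' cells. With `mode = "cell"` the alternative definition is used: the
#' fraction of A's cells having at least one neighbour in B.
#'
#' @param pc_coords cells x PCs matrix (typically PCs 1:50).
#' @param labels per-cell group labels (total, no NAs).
#' @param knn_k neighbours per cell (default 15).
#' @param mode `"slot"` (pooled neighbour slots, default) or `"cell"`.
#' @return data.frame `from`, `to`, `fraction` for all ordered pairs with
#'   `from != to`; attributes `group_sizes` and `out_fraction` (per-group
#'   total out-of-group fraction) and `small_groups` (groups of < 2 cells,
#'   flagged, fractions still computed).
#' @export
neighbor_fractions <- function(pc_coords, labels, knn_k = 15,
                               mode = c("slot", "cell")) {
  mode <- match.arg(mode)
  pc_coords <- as.matrix(pc_coords)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(pc_coords), !anyNA(labels))
  n <- nrow(pc_coords)
  if (n < knn_k + 1) stop("need at least knn_k + 1 cells")
  groups <- sort(unique(labels))
  sizes <- table(factor(labels, groups))
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("group(s) with < 2 cells, fractions flagged: ",
            paste(small, collapse = ", "))
  nn <- knn_exact(pc_coords, knn_k)
  nb_lab <- matrix(labels[nn], nrow = n)
  out <- expand.grid(from = groups, to = groups, stringsAsFactors = FALSE)
  out <- out[out$from != out$to, , drop = FALSE]
  frac <- numeric(nrow(out))
  for (r in seq_len(nrow(out))) {
    rows <- which(labels == out$from[r])
    hits <- nb_lab[rows, , drop = FALSE] == out$to[r]
    frac[r] <- if (mode == "slot") mean(hits) else mean(rowSums(hits) > 0)
  }
  out$fraction <- frac
  rownames(out) <- NULL
  out_frac <- vapply(groups, function(g) {
    rows <- which(labels == g)
    mean(nb_lab[rows, , drop = FALSE] != g)
  }, numeric(1))
  structure(out, group_sizes = as.integer(sizes),
            out_fraction = stats::setNames(out_frac, groups),
            small_groups = small, knn_k = knn_k, mode = mode)
}

#' Build a constellation graph
#'
#' Nodes are cell groups at the centroid of their 2-D embedding
#' coordinates, sized by member count. An undirected edge joins groups A
#' and B iff `f(A->B) > edge_threshold` or `f(B->A) > edge_threshold`
#' (strictly greater; default threshold 0.05 means more than 5% of a
#' group's neighbour slots in the other group). Edge end-widths are the
#' directed fractions divided by the normalization constant, the maximum
#' out-of-group fraction across all groups, so the best-connected group's
#' width is 100%.
#'
#' @param fractions output of [neighbor_fractions()].
#' @param embedding cells x 2 coordinate matrix (e.g. UMAP; computed
#'   externally).
#' @param labels per-cell group labels matching those used for `fractions`.
#' @param edge_threshold strict lower bound on the fraction (default 0.05).
#' @return `constellation` object: `nodes` (group, x, y, size), `edges`
#'   (from, to, fraction_from_to, fraction_to_from, width_from, width_to,
#'   with from < to), `normalization`, `edge_threshold`.
#' @export
build_constellation <- function(fractions, embedding, labels,
                                edge_threshold = 0.05) {
  labels <- as.character(labels)
  embedding <- as.matrix(embedding)
  stopifnot(ncol(embedding) == 2, nrow(embedding) == length(labels),
            edge_threshold > 0, edge_threshold < 1)
  groups <- sort(unique(labels))
  fr_groups <- sort(unique(c(fractions$from, fractions$to)))
  if (!identical(groups, fr_groups))
    stop("label sets of fractions and embedding disagree")
  nodes <- data.frame(
    group = groups,
    x = vapply(groups, function(g) mean(embedding[labels == g, 1]), 0),
    y = vapply(groups, function(g) mean(embedding[labels == g, 2]), 0),
    size = vapply(groups, function(g) sum(labels == g), 0L),
    row.names = NULL)
  f <- function(a, b) {
    v <- fractions$fraction[fractions$from == a & fractions$to == b]
    if (length(v)) v else 0
  }
  norm_const <- max(fractions$fraction)
  edges <- list()
  if (length(groups) > 1) {
    for (ai in seq_along(groups)[-length(groups)])
      for (bi in (ai + 1):length(groups)) {
        a <- groups[ai]; b <- groups[bi]
        fab <- f(a, b); fba <- f(b, a)
        if (fab > edge_threshold || fba > edge_threshold)
          edges[[length(edges) + 1L]] <- data.frame(
            from = a, to = b,
            fraction_from_to = fab, fraction_to_from = fba,
            width_from = if (norm_const > 0) fab / norm_const else 0,
            width_to = if (norm_const > 0) fba / norm_const else 0)
      }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               fraction_from_to = numeric(), fraction_to_from = numeric(),
               width_from = numeric(), width_to = numeric())
  structure(list(nodes = nodes, edges = edges,
                 normalization = norm_const,
                 edge_threshold = edge_threshold),
            class = "constellation")
}

#' @method print constellation
#' @export
print.constellation <- function(x, ...) {
  cat(sprintf("constellation: %d nodes, %d edges (threshold %g)\n",
              nrow(x$nodes), nrow(x$edges), x$edge_threshold))
  invisible(x)
}

#' Connectivity index between two node collections
#'
#' Summarizes the transcriptional proximity of two collections of
#' constellation nodes: the number of graph edges joining the collections
#' multiplied by the mean of the threshold-passing endpoint fractions on
#' those edges. Zero when no edges join them; symmetric in its arguments.
#'
#' @param graph a [build_constellation()] object.
#' @param collection_a,collection_b disjoint character vectors of node ids.
#' @return nonnegative scalar.
#' @export
connectivity_index <- function(graph, collection_a, collection_b) {
  stopifnot(inherits(graph, "constellation"))
  unknown <- setdiff(c(collection_a, collection_b), graph$nodes$group)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(collection_a, collection_b)))
    stop("collections must be disjoint")
  e <- graph$edges
  sel <- (e$from %in% collection_a & e$to %in% collection_b) |
    (e$from %in% collection_b & e$to %in% collection_a)
  if (!any(sel)) return(0)
  e <- e[sel, , drop = FALSE]
  passing <- c(e$fraction_from_to[e$fraction_from_to > graph$edge_threshold],
               e$fraction_to_from[e$fraction_to_from > graph$edge_threshold])
  nrow(e) * mean(passing)
}

#' Connectivity-index matrix over a node partition
#'
#' @param graph a [build_constellation()] object.
#' @param collections named list of disjoint node-id vectors.
#' @return symmetric matrix of [connectivity_index()] values (diagonal NA).
#' @export
connectivity_matrix <- function(graph, collections) {
  k <- length(collections)
  m <- matrix(NA_real_, k, k,
              dimnames = list(names(collections), names(collections)))
  if (k < 2) return(m)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- connectivity_index(graph, collections[[i]], collections[[j]])
    m[i, j] <- m[j, i] <- v
  }
  m
}

#' Write a constellation graph as JSON and an edge-list TSV
#'
#' Emits `constellation.json` (nodes, edges, normalization, threshold) and
#' `edges.tsv` into `dir`.
#'
#' @param graph a [build_constellation()] object.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_constellation <- function(graph, dir) {
  stopifnot(inherits(graph, "constellation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(nodes = graph$nodes, edges = graph$edges,
         normalization = graph$normalization,
         edge_threshold = graph$edge_threshold),
    file.path(dir, "constellation.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(graph$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
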