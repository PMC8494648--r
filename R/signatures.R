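#' Marker-signature overlap matrix
#'
#' Row-normalized overlap between marker-gene signatures: entry (i, j) is
#' the proportion of node i's genes shared with node j,
#' `|genes_i & genes_j| / |genes_i|`. Asymmetric by construction; diagonal
#' is 1. With `symmetric = TRUE` the Jaccard index
#' `|i & j| / |i | j|` is returned instead.
#'
#' @param nodes named list of nonempty character vectors (signature id ->
#'   marker genes), e.g. one per cell type x area x stage.
#' @param symmetric return Jaccard instead of row proportions.
#' @return square matrix with node ids as dimnames.
#' @export
signature_overlap <- function(nodes, symmetric = FALSE) {
  if (length(nodes) < 2) stop("need at least 2 signature nodes")
  if (is.null(names(nodes)) || anyDuplicated(names(nodes)))
    stop("nodes must have unique names")
  sizes <- lengths(lapply(nodes, unique))
  empty <- names(nodes)[sizes == 0]
  if (length(empty))
    stop("empty gene set for node(s): ", paste(empty, collapse = ", "))
  nodes <- lapply(nodes, unique)
  k <- length(nodes)
  m <- matrix(0, k, k, dimnames = list(names(nodes), names(nodes)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    inter <- length(intersect(nodes[[i]], nodes[[j]]))
    m[i, j] <- if (symmetric)
      inter / length(union(nodes[[i]], nodes[[j]]))
    else inter / length(nodes[[i]])
  }
  m
}

#' Hierarchy of signature nodes by shared-gene proportions
#'
#' Clusters signature nodes hierarchically on the Euclidean distances
#' between their rows of the overlap matrix (their profiles of shared-gene
#' proportions against every node), with average linkage. Rows are sorted
#' by id first so the tree is deterministic.
#'
#' @param overlap a [signature_overlap()] matrix.
#' @return an [stats::hclust] tree.
#' @export
overlap_hierarchy <- function(overlap) {
  stopifnot(is.matrix(overlap), nrow(overlap) >= 2,
            identical(rownames(overlap), colnames(overlap)))
  ord <- order(rownames(overlap))
  m <- overlap[ord, ord, drop = FALSE]
  stats::hclust(stats::dist(m), method = "average")
}

#' Sankey link table between consecutive stages
#'
#' For signatures grouped by developmental stage, builds the links of a
#' Sankey diagram: one row per (source node, target node) pair in adjacent
#' stages (early -> middle, middle -> late) whose gene sets intersect,
#' weighted by the intersection size. Zero-weight links are omitted.
#'
#' @param nodes named list of signature gene sets.
#' @param stages factor/character vector, one stage per node, in
#'   `stage_order`.
#' @param stage_order the stage ordering (default early, middle, late).
#' @return data.frame `source`, `target`, `weight`; empty (with a warning)
#'   when fewer than 2 stages are present.
#' @export
sankey_links <- function(nodes, stages,
                         stage_order = c("early", "middle", "late")) {
  stopifnot(length(stages) == length(nodes), !is.null(names(nodes)))
  stages <- as.character(stages)
  present <- stage_order[stage_order %in% stages]
  empty <- data.frame(source = character(), target = character(),
                      weight = integer())
  if (length(present) < 2) {
    warning("fewer than 2 stages present; no links")
    return(empty)
  }
  links <- list()
  for (s in seq_len(length(stage_order) - 1)) {
    src <- which(stages == stage_order[s])
    tgt <- which(stages == stage_order[s + 1])
    for (i in src) for (j in tgt) {
      w <- length(intersect(nodes[[i]], nodes[[j]]))
      if (w > 0)
        links[[length(links) + 1L]] <- data.frame(
          source = names(nodes)[i], target = names(nodes)[j], weight = w)
    }
  }
  if (length(links)) do.call(rbind, links) else empty
}
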