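#' Assign smFISH spots to cells by maximum distance
#'
#' Each spot is assigned to the nucleus with the smallest boundary
#' distance — Euclidean distance from the spot to the nucleus centroid
#' minus the nuclear radius, floored at 0 — provided that distance is at
#' most `max_dist`; otherwise the spot is left unassigned. Equidistant
#' nuclei are broken by lower nucleus id, making assignment deterministic.
#'
#' @param spots data.frame with `gene`, `x`, `y` (and typically
#'   `intensity`) columns.
#' @param nuclei data.frame with `id`, `x`, `y`, `radius` columns (unique
#'   ids, positive radii).
#' @param max_dist maximum boundary distance (um, default 15).
#' @return `cell_feature_matrix` object: `counts` (cells x genes integer
#'   matrix), `cells` (id, x, y, radius, total), `assignment` (per-spot
#'   nucleus id, NA when unassigned), `unassigned` (spot row indices).
#' @export
assign_spots <- function(spots, nuclei, max_dist = 15) {
  stopifnot(max_dist > 0)
  n_spots <- nrow(spots)
  if (nrow(nuclei) == 0) {
    warning("empty nuclei table: all spots unassigned")
    assignment <- rep(NA_integer_, n_spots)
  } else {
    stopifnot(!anyDuplicated(nuclei$id), all(nuclei$radius > 0))
    ord <- order(nuclei$id)
    nuclei <- nuclei[ord, , drop = FALSE]
    assignment <- rep(NA_integer_, n_spots)
    if (n_spots > 0) {
      block <- 4096L
      for (start in seq(1L, n_spots, by = block)) {
        idx <- start:min(start + block - 1L, n_spots)
        dx <- outer(spots$x[idx], nuclei$x, "-")
        dy <- outer(spots$y[idx], nuclei$y, "-")
        bd <- pmax(sqrt(dx^2 + dy^2) -
                     matrix(nuclei$radius, length(idx), nrow(nuclei),
                            byrow = TRUE), 0)
        best <- max.col(-bd, ties.method = "first")  # lowest id on ties
        dmin <- bd[cbind(seq_along(idx), best)]
        assignment[idx] <- ifelse(dmin <= max_dist, nuclei$id[best],
                                  NA_integer_)
      }
    }
  }
  genes <- sort(unique(as.character(spots$gene)))
  ids <- if (nrow(nuclei)) sort(nuclei$id) else integer()
  counts <- matrix(0L, length(ids), length(genes),
                   dimnames = list(as.character(ids), genes))
  assigned <- which(!is.na(assignment))
  if (length(assigned)) {
    tab <- table(factor(assignment[assigned], ids),
                 factor(as.character(spots$gene)[assigned], genes))
    counts[] <- as.integer(tab)
  }
  cells <- if (nrow(nuclei))
    data.frame(id = nuclei$id, x = nuclei$x, y = nuclei$y,
               radius = nuclei$radius, total = rowSums(counts))
  else data.frame(id = integer(), x = numeric(), y = numeric(),
                  radius = numeric(), total = numeric())
  structure(list(counts = counts, cells = cells, assignment = assignment,
                 unassigned = which(is.na(assignment))),
            class = "cell_feature_matrix")
}

#' @method print cell_feature_matrix
#' @export
print.cell_feature_matrix <- function(x, ...) {
  cat(sprintf(
    "cell_feature_matrix: %d cells x %d genes (%d spots assigned, %d unassigned)\n",
    nrow(x$counts), ncol(x$counts),
    length(x$assignment) - length(x$unassigned), length(x$unassigned)))
  invisible(x)
}

#' Remove low-signal cells from a cell-feature matrix
#'
#' Eliminates cells whose total assigned spot count is below `min_counts`
#' (default: fewer than ten counts of signal). The cutoff is inclusive on
#' the keep side: a cell with exactly `min_counts` is retained.
#'
#' @param cfm a [assign_spots()] result.
#' @param min_counts minimum total spots to keep a cell (default 10).
#' @return the filtered `cell_feature_matrix`.
#' @export
filter_spatial_cells <- function(cfm, min_counts = 10) {
  stopifnot(inherits(cfm, "cell_feature_matrix"))
  if (nrow(cfm$counts) == 0) stop("empty cell-feature matrix")
  keep <- cfm$cells$total >= min_counts
  if (!any(keep)) stop("all cells removed by the min_counts filter")
  cfm$counts <- cfm$counts[keep, , drop = FALSE]
  cfm$cells <- cfm$cells[keep, , drop = FALSE]
  rownames(cfm$cells) <- NULL
  cfm
}

#' Laminar kernel-density profile of a gene's spots
#'
#' Gaussian KDE of spot positions: the 1-D laminar marginal over y
#' (density across the cortical wall from ventricular zone to cortical
#' plate), optionally with the 2-D density surface. The per-gene
#' quantification scalar is total intensity divided by spot count. With a
#' single spot the bandwidth falls back to `min_bandwidth`; with zero
#' spots the quantification is undefined and the function errors.
#'
#' @param spots data.frame of one gene's spots (`x`, `y`, `intensity`).
#' @param bandwidth y bandwidth; `NULL` uses [stats::bw.nrd0()].
#' @param y_range optional reporting range; the evaluation grid always
#'   extends 8 bandwidths past the data so the density integrates to 1.
#' @param n_grid grid points (odd, for Simpson quadrature downstream).
#' @param d2 also compute the 2-D density surface ([MASS::kde2d]).
#' @param min_bandwidth floor on the bandwidth (um).
#' @return `laminar_kde` object: `y`, `density` (the 1-D profile),
#'   `bandwidth`, `quantification`, `n_spots`, `mode_y` (profile peak),
#'   and optionally `surface`.
#' @export
laminar_kde <- function(spots, bandwidth = NULL, y_range = NULL,
                        n_grid = 4097L, d2 = FALSE, min_bandwidth = 1) {
  if (nrow(spots) == 0)
    stop("no spots for this gene: quantification undefined")
  ys <- spots$y
  if (is.null(bandwidth))
    bandwidth <- if (length(ys) > 1 && stats::sd(ys) > 0)
      stats::bw.nrd0(ys) else min_bandwidth
  bandwidth <- max(bandwidth, min_bandwidth)
  lo <- min(c(ys, y_range)) - 8 * bandwidth
  hi <- max(c(ys, y_range)) + 8 * bandwidth
  grid <- seq(lo, hi, length.out = n_grid)
  ## exact Gaussian mixture evaluation, one kernel per spot
  dens <- rowMeans(vapply(ys, function(y0)
    stats::dnorm(grid, y0, bandwidth), numeric(n_grid)))
  quant <- if ("intensity" %in% names(spots))
    sum(spots$intensity) / nrow(spots) else NA_real_
  out <- list(y = grid, density = dens, bandwidth = bandwidth,
              quantification = quant, n_spots = nrow(spots),
              mode_y = grid[which.max(dens)])
  if (d2)
    out$surface <- MASS::kde2d(spots$x, ys, n = 101,
                               h = c(max(MASS::bandwidth.nrd(spots$x),
                                         min_bandwidth),
                                     max(MASS::bandwidth.nrd(ys),
                                         min_bandwidth)))
  structure(out, class = "laminar_kde")
}

#' @method print laminar_kde
#' @export
print.laminar_kde <- function(x, ...) {
  cat(sprintf(
    "laminar_kde: %d spots, bandwidth %.2f, mode at y = %.1f, intensity/spot = %.2f\n",
    x$n_spots, x$bandwidth, x$mode_y, x$quantification))
  invisible(x)
}

#' Gene-gene co-expression network from spatial counts
#'
#' Pearson correlations across genes on the per-cell assigned spot counts
#' of a filtered cell-feature matrix. Self-correlations are dropped, the
#' exclusion set (positive control and non-excitatory cell-type markers,
#' by default POLR2A, SOX2, EOMES and DLX6) is removed before computing,
#' and undirected edges with `r >= r_min` (inclusive, default 0.05) are
#' kept. `method = "binary"` correlates detection (count > 0) instead of
#' counts.
#'
#' @param cfm a [filter_spatial_cells()] result.
#' @param exclude genes removed before the analysis.
#' @param r_min inclusive correlation threshold.
#' @param method `"counts"` (raw assigned counts, default) or `"binary"`.
#' @return data.frame `gene1`, `gene2`, `r` with `gene1 < gene2`.
#' @export
coexpression_network <- function(cfm,
                                 exclude = c("POLR2A", "SOX2", "EOMES", "DLX6"),
                                 r_min = 0.05,
                                 method = c("counts", "binary")) {
  method <- match.arg(method)
  stopifnot(inherits(cfm, "cell_feature_matrix"))
  x <- cfm$counts[, !colnames(cfm$counts) %in% exclude, drop = FALSE]
  if (ncol(x) < 2)
    stop("fewer than 2 genes remain after exclusion")
  if (method == "binary") x <- (x > 0) * 1
  r <- suppressWarnings(stats::cor(x))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(gene1 = rownames(r)[ut[, 1]],
                    gene2 = colnames(r)[ut[, 2]],
                    r = r[ut])
  ## inclusive threshold; the 1e-12 guard keeps boundary correlations that
  ## only float rounding pushes below r_min
  out <- out[!is.na(out$r) & out$r >= r_min - 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  out
}
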