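#' Configuration for the synthetic smFISH scene generator
#'
#' Describes a laminar cortical-wall scene: ordered zones (ventricular zone
#' at the bottom through cortical plate at the top) tiling the y-range,
#' nuclei scattered in the tissue, and a gene panel with per-zone relative
#' spot densities and mean spot intensities, plus uniform background spots.
#'
#' @param zones data.frame with columns `zone`, `ymin`, `ymax`; extents
#'   must tile the y-range without overlap, bottom first. Default: five
#'   100-um bands VZ, SVZ, IZ, SP, CP.
#' @param x_range horizontal extent (um), length-2 numeric.
#' @param n_nuclei number of nuclei.
#' @param nucleus_radius nuclear radius (um), one value for all nuclei.
#' @param genes data.frame with columns `gene`, `mean_intensity`, and one
#'   `dens_<zone>` column per zone giving the relative spot density of the
#'   gene in that zone (nonnegative, not all zero per gene). The per-cell
#'   spot count for gene g in zone z is Poisson with mean
#'   `spots_per_cell_mean * dens_g(z)`.
#' @param spots_per_cell_mean baseline expected spots per cell at density 1.
#' @param coexpr_groups optional named list of gene sets; genes within a
#'   set share one per-cell lognormal rate factor (SD
#'   `coexpr_factor_sd` on the log scale), planting positive gene-gene
#'   co-expression; all other genes get independent factors.
#' @param coexpr_factor_sd log-scale SD of the per-cell rate factors
#'   (default 0.5; 0 disables rate heterogeneity).
#' @param background_spot_rate expected background spots per um^2 per gene.
#' @param spot_jitter_sd SD (um) of the isotropic Gaussian jitter of a spot
#'   around its owning nucleus centroid.
#' @param max_assign_distance default maximum boundary distance (um) used
#'   downstream by [assign_spots()].
#' @param seed root seed.
#' @return a `spatial_config` list.
#' @export
spatial_config <- function(zones = data.frame(
                             zone = c("VZ", "SVZ", "IZ", "SP", "CP"),
                             ymin = c(0, 100, 200, 300, 400),
                             ymax = c(100, 200, 300, 400, 500)),
                           x_range = c(0, 500),
                           n_nuclei = 500,
                           nucleus_radius = 5,
                           genes = NULL,
                           spots_per_cell_mean = 20,
                           coexpr_groups = NULL,
                           coexpr_factor_sd = 0.5,
                           background_spot_rate = 0,
                           spot_jitter_sd = 2,
                           max_assign_distance = 15,
                           seed = 1) {
  stopifnot(is.data.frame(zones), all(c("zone", "ymin", "ymax") %in% names(zones)),
            n_nuclei >= 1, nucleus_radius > 0, spots_per_cell_mean > 0,
            background_spot_rate >= 0, spot_jitter_sd >= 0,
            max_assign_distance > 0)
  zones <- zones[order(zones$ymin), , drop = FALSE]
  if (any(zones$ymax <= zones$ymin))
    stop("each zone needs ymax > ymin")
  if (nrow(zones) > 1 &&
      any(abs(zones$ymin[-1] - zones$ymax[-nrow(zones)]) > 1e-9))
    stop("zone extents must tile the y-range without gaps or overlap")
  if (is.null(genes)) {
    dens <- diag(nrow(zones))            # one zone-restricted gene per zone
    genes <- data.frame(gene = paste0("SP_", zones$zone),
                        mean_intensity = 100)
    genes[paste0("dens_", zones$zone)] <- as.data.frame(dens)
  }
  dcols <- paste0("dens_", zones$zone)
  if (!all(dcols %in% names(genes)))
    stop("genes needs a dens_<zone> column for every zone")
  dens <- as.matrix(genes[, dcols, drop = FALSE])
  if (any(dens < 0)) stop("densities must be nonnegative")
  if (any(rowSums(dens) == 0))
    stop("every gene needs a positive density in at least one zone")
  if (!is.null(coexpr_groups)) {
    stopifnot(is.list(coexpr_groups),
              all(unlist(coexpr_groups) %in% genes$gene))
    if (anyDuplicated(unlist(coexpr_groups)))
      stop("a gene may belong to at most one coexpression group")
  }
  stopifnot(coexpr_factor_sd >= 0)
  structure(list(zones = zones, x_range = x_range, n_nuclei = n_nuclei,
                 nucleus_radius = nucleus_radius, genes = genes,
                 coexpr_groups = coexpr_groups,
                 coexpr_factor_sd = coexpr_factor_sd,
                 spots_per_cell_mean = spots_per_cell_mean,
                 background_spot_rate = background_spot_rate,
                 spot_jitter_sd = spot_jitter_sd,
                 max_assign_distance = max_assign_distance, seed = seed),
            class = "spatial_config")
}

#' Generate a synthetic smFISH scene with spot-level ground truth
#'
#' Places nuclei uniformly over the tissue rectangle, draws per-(cell,
#' gene) Poisson spot counts with the zone-dependent rate
#' `spots_per_cell_mean * dens_gene(zone)`, jitters each spot around its
#' owning nucleus centroid, and adds uniform background spots. Intensities
#' are lognormal around the gene's `mean_intensity`. Deterministic per
#' `config$seed`.
#'
#' @param config a [spatial_config()].
#' @return list with `nuclei` (id, x, y, radius, zone), `spots` (gene, x,
#'   y, intensity, `truth_nucleus`: owning nucleus id, or `NA` for
#'   background spots), and `zones`.
#' @export
generate_spatial <- function(config) {
  stopifnot(inherits(config, "spatial_config"))
  cfg <- config
  set.seed(cfg$seed)
  zn <- cfg$zones
  y_lo <- min(zn$ymin); y_hi <- max(zn$ymax)
  nuclei <- data.frame(
    id = seq_len(cfg$n_nuclei),
    x = stats::runif(cfg$n_nuclei, cfg$x_range[1], cfg$x_range[2]),
    y = stats::runif(cfg$n_nuclei, y_lo, y_hi),
    radius = cfg$nucleus_radius)
  nuclei$zone <- zn$zone[findInterval(nuclei$y, zn$ymin,
                                      rightmost.closed = TRUE)]
  dens <- as.matrix(cfg$genes[, paste0("dens_", zn$zone), drop = FALSE])
  rownames(dens) <- cfg$genes$gene
  zi <- match(nuclei$zone, zn$zone)

  ## per-cell rate factors: genes of a coexpression group share one factor
  n_genes <- nrow(cfg$genes)
  factor_of <- seq_len(n_genes)               # default: one factor per gene
  if (!is.null(cfg$coexpr_groups)) {
    for (k in seq_along(cfg$coexpr_groups)) {
      gi <- match(cfg$coexpr_groups[[k]], cfg$genes$gene)
      factor_of[gi] <- gi[1]
    }
  }
  fac <- matrix(1, n_genes, cfg$n_nuclei)
  if (cfg$coexpr_factor_sd > 0) {
    for (u in unique(factor_of)) {
      f <- stats::rlnorm(cfg$n_nuclei, meanlog = 0,
                         sdlog = cfg$coexpr_factor_sd)
      fac[factor_of == u, ] <- rep(f, each = sum(factor_of == u))
    }
  }

  spot_list <- list()
  for (g in seq_len(n_genes)) {
    lam <- cfg$spots_per_cell_mean * dens[g, zi] * fac[g, ]
    k <- stats::rpois(cfg$n_nuclei, lam)
    owner <- rep.int(nuclei$id, k)
    if (length(owner)) {
      spot_list[[length(spot_list) + 1L]] <- data.frame(
        gene = cfg$genes$gene[g],
        x = nuclei$x[owner] + stats::rnorm(length(owner), sd = cfg$spot_jitter_sd),
        y = nuclei$y[owner] + stats::rnorm(length(owner), sd = cfg$spot_jitter_sd),
        intensity = stats::rlnorm(length(owner),
                                  meanlog = log(cfg$genes$mean_intensity[g]),
                                  sdlog = 0.25),
        truth_nucleus = owner)
    }
    ## background: uniform over the tissue rectangle
    if (cfg$background_spot_rate > 0) {
      area <- diff(cfg$x_range) * (y_hi - y_lo)
      nb <- stats::rpois(1, cfg$background_spot_rate * area)
      if (nb > 0) {
        spot_list[[length(spot_list) + 1L]] <- data.frame(
          gene = cfg$genes$gene[g],
          x = stats::runif(nb, cfg$x_range[1], cfg$x_range[2]),
          y = stats::runif(nb, y_lo, y_hi),
          intensity = stats::rlnorm(nb,
                                    meanlog = log(cfg$genes$mean_intensity[g]),
                                    sdlog = 0.25),
          truth_nucleus = NA_integer_)
      }
    }
  }
  spots <- if (length(spot_list)) do.call(rbind, spot_list) else
    data.frame(gene = character(), x = numeric(), y = numeric(),
               intensity = numeric(), truth_nucleus = integer())
  rownames(spots) <- NULL
  list(nuclei = nuclei, spots = spots, zones = zn)
}

#' Write a spatial scene as plain-text CSVs
#' @param scene result of [generate_spatial()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_spatial_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(scene$nuclei, file.path(dir, "nuclei.csv"), row.names = FALSE)
  utils::write.csv(scene$spots, file.path(dir, "spots.csv"), row.names = FALSE)
  invisible(dir)
}
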