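#' Configuration for the synthetic atlas generator
#'
#' Describes a multi-individual, multi-area developing-cortex atlas with
#' planted structure: per-cell-type marker programs, per-(cell type, area)
#' areal marker programs whose abundance increases along the excitatory
#' lineage (radial glia -> IPC -> neuron), a posterior-high/anterior-low
#' gradient gene set on the rostro-caudal area order (PFC < motor <
#' somatosensory < parietal < temporal < V1), per-individual batch shifts,
#' mitochondrial genes and heterotypic doublets.
#'
#' Counts are negative binomial with `variance = mean + mean^2/dispersion`.
#' A planted marker multiplies the baseline mean of its gene by
#' `marker_fold_change` inside its owning group; a gradient gene's mean is
#' scaled by `marker_fold_change^(rank/(n_areas-1))` where rank runs 0 (PFC)
#' to `n_areas-1` (V1), i.e. log-mean linear in area rank.
#'
#' @param n_individuals number of individuals.
#' @param gestational_weeks gestational week per individual, each in the
#'   sampled set {14,16,17,18,19,20,22,25}; recycled to `n_individuals`.
#' @param areas cortical area labels in rostro-caudal order.
#' @param cell_types cell type labels.
#' @param n_cells_per_individual singlet cells per individual.
#' @param n_genes total genes.
#' @param marker_fold_change multiplicative effect of a planted marker on
#'   its group's mean (1 = null).
#' @param n_markers_per_celltype planted markers per cell type.
#' @param n_markers_per_area_by_celltype named integer vector, areal markers
#'   per (cell type, area); names must cover `cell_types`.
#' @param gradient_gene_count number of gradient genes.
#' @param shared_lineage_signal fraction (in \[0, 1\]) of the log marker
#'   effect that an areal marker owned by one excitatory-lineage type (RG,
#'   IPC or neuron) also exerts in the *other* lineage types of the same
#'   area. Models areal signatures that are detectable in radial glia but
#'   strengthen as cells differentiate; 0 makes areal programs fully
#'   type-private.
#' @param batch_sigma SD of the per-(individual, gene) normal shift on the
#'   log mean.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial.
#' @param doublet_rate doublets appended per individual as a fraction of
#'   `n_cells_per_individual` (must be < 0.5).
#' @param dispersion negative-binomial size parameter.
#' @param seed root seed; all randomness in [generate_atlas()] flows from it.
#' @return an `atlas_config` list.
#' @export
atlas_config <- function(n_individuals = 3,
                         gestational_weeks = c(16, 19, 22),
                         areas = c("PFC", "motor", "somatosensory",
                                   "parietal", "temporal", "V1"),
                         cell_types = c("RG", "IPC", "neuron",
                                        "inhibitory", "microglia", "vascular"),
                         n_cells_per_individual = 3000,
                         n_genes = 2000,
                         marker_fold_change = 4,
                         n_markers_per_celltype = 20,
                         n_markers_per_area_by_celltype = c(
                           RG = 3, IPC = 5, neuron = 8,
                           inhibitory = 2, microglia = 2, vascular = 2),
                         gradient_gene_count = 5,
                         shared_lineage_signal = 0.5,
                         batch_sigma = 0.2,
                         mito_gene_fraction = 0.05,
                         doublet_rate = 0.05,
                         dispersion = 2,
                         seed = 1) {
  sampled_gw <- c(14, 16, 17, 18, 19, 20, 22, 25)
  gestational_weeks <- rep_len(gestational_weeks, n_individuals)
  stopifnot(n_individuals >= 1, n_cells_per_individual >= 1, n_genes >= 1,
            marker_fold_change > 0, n_markers_per_celltype >= 0,
            gradient_gene_count >= 0, batch_sigma >= 0,
            shared_lineage_signal >= 0, shared_lineage_signal <= 1,
            mito_gene_fraction > 0, mito_gene_fraction < 1,
            doublet_rate >= 0, doublet_rate < 0.5, dispersion > 0)
  if (!all(gestational_weeks %in% sampled_gw))
    stop("gestational_weeks must lie in the sampled set: ",
         paste(sampled_gw, collapse = ", "))
  if (length(areas) < 1 || length(cell_types) < 1)
    stop("areas and cell_types must be nonempty")
  if (is.null(names(n_markers_per_area_by_celltype)) ||
      !all(cell_types %in% names(n_markers_per_area_by_celltype)))
    stop("n_markers_per_area_by_celltype must be named for every cell type")
  n_markers_per_area_by_celltype <-
    n_markers_per_area_by_celltype[cell_types]
  n_planted <- round(n_genes * mito_gene_fraction) +
    n_markers_per_celltype * length(cell_types) +
    sum(n_markers_per_area_by_celltype) * length(areas) +
    gradient_gene_count
  if (n_planted > n_genes)
    stop("requested marker/mito/gradient genes (", n_planted,
         ") exceed n_genes (", n_genes, ")")
  structure(list(n_individuals = n_individuals,
                 gestational_weeks = gestational_weeks,
                 areas = areas, cell_types = cell_types,
                 n_cells_per_individual = n_cells_per_individual,
                 n_genes = n_genes,
                 marker_fold_change = marker_fold_change,
                 n_markers_per_celltype = n_markers_per_celltype,
                 n_markers_per_area_by_celltype = n_markers_per_area_by_celltype,
                 gradient_gene_count = gradient_gene_count,
                 shared_lineage_signal = shared_lineage_signal,
                 batch_sigma = batch_sigma,
                 mito_gene_fraction = mito_gene_fraction,
                 doublet_rate = doublet_rate,
                 dispersion = dispersion, seed = seed),
            class = "atlas_config")
}

#' Generate a synthetic atlas with planted ground truth
#'
#' Draws a seeded negative-binomial gene x cell count matrix whose log mean
#' decomposes as baseline + cell-type marker effect + areal marker effect +
#' gradient term + per-individual batch shift, then appends doublet columns
#' that are exact sums of two random same-individual singlets.
#'
#' Randomness flows from `config$seed` through one sequential stream in a
#' fixed documented order (gene baselines and roles, then per-individual
#' batch shifts, cell assignments, counts, and doublet pairs), so identical
#' configs give bitwise-identical output.
#'
#' @param config an [atlas_config()].
#' @return list with `matrix` (an [expr_matrix()]; `cells` carries the
#'   truth columns `true_type`, `true_area`, `is_doublet`, `parent1`,
#'   `parent2`) and `truth` (list with per-gene `gene_roles`
#'   data.frame: `role` in background/celltype_marker/area_marker/
#'   gradient/mito, `owner_type`, `owner_area`).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "atlas_config"))
  cfg <- config
  set.seed(cfg$seed)
  K_t <- length(cfg$cell_types); K_a <- length(cfg$areas)

  ## --- gene roles -----------------------------------------------------
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  role <- rep("background", cfg$n_genes)
  owner_type <- rep(NA_character_, cfg$n_genes)
  owner_area <- rep(NA_character_, cfg$n_genes)
  pool <- seq_len(cfg$n_genes)
  take <- function(n) {
    picked <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    picked
  }
  mito_idx <- take(round(cfg$n_genes * cfg$mito_gene_fraction))
  role[mito_idx] <- "mito"
  for (tt in cfg$cell_types) {
    idx <- take(cfg$n_markers_per_celltype)
    role[idx] <- "celltype_marker"; owner_type[idx] <- tt
  }
  for (tt in cfg$cell_types) {
    n_a <- cfg$n_markers_per_area_by_celltype[[tt]]
    for (aa in cfg$areas) {
      if (n_a > 0) {
        idx <- take(n_a)
        role[idx] <- "area_marker"; owner_type[idx] <- tt; owner_area[idx] <- aa
      }
    }
  }
  grad_idx <- take(cfg$gradient_gene_count)
  role[grad_idx] <- "gradient"
  genes[mito_idx] <- sprintf("MT-G%04d", mito_idx)

  ## baseline means: lognormal, median 1 count per cell
  base_mean <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
  lfc <- log(cfg$marker_fold_change)
  area_rank <- (seq_len(K_a) - 1) / max(K_a - 1, 1)   # 0 at PFC end, 1 at V1

  ## per-(individual, gene) batch shifts
  batch <- matrix(stats::rnorm(cfg$n_individuals * cfg$n_genes,
                               sd = cfg$batch_sigma),
                  nrow = cfg$n_genes)

  ## --- cells ----------------------------------------------------------
  n <- cfg$n_cells_per_individual
  counts_list <- vector("list", cfg$n_individuals)
  cells_list <- vector("list", cfg$n_individuals)
  for (i in seq_len(cfg$n_individuals)) {
    type_i <- sample(cfg$cell_types, n, replace = TRUE)
    area_i <- sample(cfg$areas, n, replace = TRUE)
    logmu <- matrix(log(base_mean) + batch[, i], cfg$n_genes, n)
    for (ti in seq_len(K_t)) {
      sel <- which(type_i == cfg$cell_types[ti])
      if (!length(sel)) next
      gidx <- which(role == "celltype_marker" & owner_type == cfg$cell_types[ti])
      logmu[gidx, sel] <- logmu[gidx, sel] + lfc
    }
    lineage <- intersect(c("RG", "IPC", "neuron"), cfg$cell_types)
    for (ti in seq_len(K_t)) for (ai in seq_len(K_a)) {
      tt <- cfg$cell_types[ti]
      sel <- which(type_i == tt & area_i == cfg$areas[ai])
      if (!length(sel)) next
      gidx <- which(role == "area_marker" &
                      owner_type == tt &
                      owner_area == cfg$areas[ai])
      logmu[gidx, sel] <- logmu[gidx, sel] + lfc
      ## shared areal signature across the excitatory lineage, at reduced
      ## strength in the non-owning types
      if (cfg$shared_lineage_signal > 0 && tt %in% lineage) {
        gshared <- which(role == "area_marker" &
                           owner_type %in% setdiff(lineage, tt) &
                           owner_area == cfg$areas[ai])
        logmu[gshared, sel] <- logmu[gshared, sel] +
          cfg$shared_lineage_signal * lfc
      }
    }
    for (ai in seq_len(K_a)) {
      sel <- which(area_i == cfg$areas[ai])
      if (!length(sel)) next
      logmu[grad_idx, sel] <- logmu[grad_idx, sel] + lfc * area_rank[ai]
    }
    mu <- exp(logmu)
    cnt <- matrix(stats::rnbinom(length(mu), size = cfg$dispersion, mu = mu),
                  cfg$n_genes, n)
    ## doublets: exact sums of two distinct random singlets of this individual
    n_doub <- round(cfg$doublet_rate * n)
    parent1 <- parent2 <- rep(NA_character_, n)
    is_doub <- rep(FALSE, n)
    cell_ids <- sprintf("I%02d_C%05d", i, seq_len(n))
    if (n_doub > 0) {
      p1 <- sample.int(n, n_doub, replace = TRUE)
      p2 <- (p1 + sample.int(n - 1L, n_doub, replace = TRUE) - 1L) %% n + 1L
      dcnt <- cnt[, p1, drop = FALSE] + cnt[, p2, drop = FALSE]
      cnt <- cbind(cnt, dcnt)
      is_doub <- c(is_doub, rep(TRUE, n_doub))
      parent1 <- c(parent1, cell_ids[p1])
      parent2 <- c(parent2, cell_ids[p2])
      type_i <- c(type_i, rep("doublet", n_doub))
      area_i <- c(area_i, area_i[p1])
      cell_ids <- c(cell_ids, sprintf("I%02d_D%05d", i, seq_len(n_doub)))
    }
    counts_list[[i]] <- cnt
    cells_list[[i]] <- data.frame(
      cell_id = cell_ids,
      individual = sprintf("ind%02d", i),
      area = area_i, region = "neocortex",
      gw = cfg$gestational_weeks[i],
      true_type = type_i, is_doublet = is_doub,
      parent1 = parent1, parent2 = parent2,
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, counts_list)
  cells <- do.call(rbind, cells_list)
  rownames(counts) <- genes
  colnames(counts) <- cells$cell_id
  gene_meta <- data.frame(gene_id = genes, mito = role == "mito",
                          role = role, owner_type = owner_type,
                          owner_area = owner_area, stringsAsFactors = FALSE)
  mat <- expr_matrix(methods::as(counts, "CsparseMatrix"), cells, gene_meta)
  list(matrix = mat,
       truth = list(gene_roles = gene_meta,
                    cells = cells[, c("cell_id", "true_type", "area",
                                      "is_doublet", "parent1", "parent2")]))
}

#' Simulate labelled cells at fixed group centroids
#'
#' A lightweight geometric generator for constellation studies: isotropic
#' Gaussian groups at given centres in a PC-like coordinate space. The
#' `spread`-to-centre-distance ratio is the planted mixing level — groups
#' whose centres sit many spreads apart share no neighbours (the
#' mutually-exclusive "pole" situation), adjacent groups mix.
#'
#' @param centers numeric matrix, one row per group (any dimension), or a
#'   vector of positions on a line.
#' @param n_per_group cells per group (recycled).
#' @param spread within-group standard deviation (per coordinate).
#' @param seed seed.
#' @return list: `coords` (cells x dims), `labels` (group per cell, named
#'   by rowname of `centers` or `g1`, `g2`, ...).
#' @export
simulate_group_coords <- function(centers, n_per_group, spread = 0.3,
                                  seed = 1) {
  if (is.null(dim(centers))) centers <- cbind(centers, 0)
  k <- nrow(centers)
  if (is.null(rownames(centers))) rownames(centers) <- paste0("g", seq_len(k))
  n_per_group <- rep_len(n_per_group, k)
  set.seed(seed)
  coords <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per_group[i] * ncol(centers),
                        mean = rep(centers[i, ], each = n_per_group[i]),
                        sd = spread),
           n_per_group[i], ncol(centers))
  }))
  labels <- rep(rownames(centers), n_per_group)
  rownames(coords) <- sprintf("cell%05d", seq_len(nrow(coords)))
  list(coords = coords, labels = labels)
}
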