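test_that("spot assignment uses boundary distance with a deterministic tie-break", {
  nuclei <- data.frame(id = c(2L, 1L), x = c(0, 30), y = c(0, 0),
                       radius = c(5, 5))
  spots <- data.frame(gene = "G",
                      x = c(0, 15, 100, 12), y = 0,
                      intensity = 1)
  res <- assign_spots(spots, nuclei, max_dist = 15)
  # at a centroid: boundary distance 0
  expect_equal(res$assignment[1], 2L)
  # exactly equidistant between boundaries: lower id wins
  expect_equal(res$assignment[2], 1L)
  # farther than max_dist from every nucleus: unassigned
  expect_true(is.na(res$assignment[3]))
  # nearer to nucleus 2's boundary
  expect_equal(res$assignment[4], 2L)
  expect_equal(res$unassigned, 3L)
  expect_equal(sum(res$counts), 3)
})

test_that("assignment equals an all-pairs brute-force oracle on a big scene", {
  cfg <- spatial_config(n_nuclei = 120, seed = 33, spot_jitter_sd = 4,
                        background_spot_rate = 2e-5)
  scene <- generate_spatial(cfg)
  spots <- scene$spots
  expect_gt(nrow(spots), 1000)
  res <- assign_spots(spots, scene$nuclei, max_dist = 15)
  # oracle: full distance matrix, boundary distance, argmin with id ties
  d <- sqrt(outer(spots$x, scene$nuclei$x, "-")^2 +
              outer(spots$y, scene$nuclei$y, "-")^2)
  bd <- pmax(d - matrix(scene$nuclei$radius, nrow(spots),
                        nrow(scene$nuclei), byrow = TRUE), 0)
  ord <- order(scene$nuclei$id)
  oracle <- apply(bd[, ord, drop = FALSE], 1, function(row) {
    j <- which.min(row)
    if (row[j] <= 15) scene$nuclei$id[ord][j] else NA_integer_
  })
  expect_identical(res$assignment, unname(oracle))
  # partition: assigned + unassigned covers all spots exactly once
  expect_equal(sum(res$counts) + length(res$unassigned), nrow(spots))
})

test_that("well-separated nuclei recover the generating cell for >= 99% of spots", {
  set.seed(44)
  # nuclei on a coarse grid: minimum spacing 50 um, jitter 2 um
  gx <- as.vector(outer(seq(25, 475, by = 50), rep(1, 5)))
  gy <- as.vector(outer(rep(1, 10), seq(50, 450, by = 100)))
  nuclei <- data.frame(id = seq_along(gx), x = gx, y = gy, radius = 5)
  owner <- rep(nuclei$id, each = 30)
  spots <- data.frame(gene = "G",
                      x = nuclei$x[owner] + rnorm(length(owner), sd = 2),
                      y = nuclei$y[owner] + rnorm(length(owner), sd = 2),
                      intensity = 1)
  res <- assign_spots(spots, nuclei, max_dist = 15)
  match_rate <- mean(res$assignment == owner, na.rm = TRUE)
  expect_gte(match_rate, 0.99)
})

test_that("empty nuclei table warns and leaves all spots unassigned", {
  spots <- data.frame(gene = "G", x = 1:3, y = 1:3, intensity = 1)
  expect_warning(res <- assign_spots(spots, data.frame(id = integer(),
                                                       x = numeric(),
                                                       y = numeric(),
                                                       radius = numeric()),
                                     max_dist = 10),
                 "unassigned")
  expect_equal(length(res$unassigned), 3)
})

test_that("the low-count cell filter keeps 10 and drops 9", {
  counts <- matrix(0L, 20, 2, dimnames = list(NULL, c("GA", "GB")))
  counts[, 1] <- c(10L, 9L, rep(12L, 11), rep(3L, 7))
  cfm <- structure(list(
    counts = counts,
    cells = data.frame(id = 1:20, x = 0, y = 0, radius = 5,
                       total = rowSums(counts)),
    assignment = integer(0), unassigned = integer(0)),
    class = "cell_feature_matrix")
  out <- filter_spatial_cells(cfm, min_counts = 10)
  expect_equal(nrow(out$counts), 12)        # 10-count boundary cell kept
  expect_true(1 %in% out$cells$id)
  expect_false(2 %in% out$cells$id)
  # exactly the 7 planted sub-threshold cells (3 counts) are removed,
  # plus the 9-count cell
  expect_equal(sum(!(1:20 %in% out$cells$id)), 8)
  expect_error(filter_spatial_cells(out, min_counts = 1000), "all cells")
})

test_that("laminar KDE integrates to one and localizes zone-restricted genes", {
  spots <- data.frame(gene = "G", x = runif(2, 0, 10), y = c(5, 5),
                      intensity = c(2, 4))
  k <- laminar_kde(spots)
  # quantification: total intensity / spot count
  expect_equal(k$quantification, 3.0)
  # all spots at one y: at least 99% of mass within 3 bandwidths
  inside <- abs(k$y - 5) <= 3 * k$bandwidth
  h <- diff(k$y[1:2])
  expect_gte(sum(k$density[inside]) * h, 0.99)
  # Simpson quadrature of the profile equals 1 to 1e-6
  set.seed(55)
  spots2 <- data.frame(gene = "G", x = runif(400, 0, 100),
                       y = c(rnorm(200, 100, 15), rnorm(200, 400, 30)),
                       intensity = 1)
  k2 <- laminar_kde(spots2)
  n <- length(k2$y); h2 <- diff(k2$y[1:2])
  simpson <- h2 / 3 * sum(k2$density * c(1, rep(c(4, 2), (n - 3) / 2), 4, 1))
  expect_lt(abs(simpson - 1), 1e-6)
  expect_error(laminar_kde(spots2[0, ]), "quantification undefined")
  # single spot falls back to the minimum bandwidth
  k1 <- laminar_kde(data.frame(gene = "G", x = 0, y = 10, intensity = 5))
  expect_equal(k1$bandwidth, 1)
  expect_equal(k1$quantification, 5)
})

test_that("KDE mode recovers the planted laminar zone", {
  zones <- data.frame(zone = c("VZ", "SVZ", "IZ", "SP", "CP"),
                      ymin = 0:4 * 100, ymax = 1:5 * 100)
  hits <- 0
  for (seed in 1:10) {
    cfg <- spatial_config(n_nuclei = 300, seed = seed, spot_jitter_sd = 2)
    sc <- generate_spatial(cfg)
    sp <- sc$spots[sc$spots$gene == "SP_IZ", ]
    k <- laminar_kde(sp)
    hits <- hits + (k$mode_y >= 200 && k$mode_y <= 300)
  }
  expect_gte(hits / 10, 0.95)
})

test_that("co-expression keeps r >= 0.05 inclusively and drops excluded genes", {
  # binary columns with exact rational correlations: for balanced 0/1
  # vectors of length n, cor = 4 * n11 / n - 1
  set.seed(66)
  n <- 400
  a <- rep(c(1, 0), each = 200)
  with_overlap <- function(n11) {
    v <- numeric(n)
    v[1:n11] <- 1                       # n11 ones inside a's support
    v[201:(400 - n11)] <- 1             # the rest outside
    v
  }
  counts <- cbind(A = a, B = with_overlap(105),   # cor exactly 0.05
                  C = with_overlap(104),          # cor exactly 0.04
                  D = a, SOX2 = rnorm(n), POLR2A = rnorm(n))
  cfm <- structure(list(counts = counts,
                        cells = data.frame(id = 1:n, x = 0, y = 0,
                                           radius = 5,
                                           total = rowSums(abs(counts))),
                        assignment = integer(0), unassigned = integer(0)),
                   class = "cell_feature_matrix")
  net <- coexpression_network(cfm, r_min = 0.05)
  key <- paste(net$gene1, net$gene2)
  expect_true("A B" %in% key)               # r = 0.05 exactly: kept
  expect_false("A C" %in% key)              # r = 0.049: dropped
  expect_true("A D" %in% key)               # identical vectors: r = 1
  expect_equal(net$r[net$gene1 == "A" & net$gene2 == "D"], 1)
  # default exclusion set never appears
  expect_false(any(c(net$gene1, net$gene2) %in%
                     c("POLR2A", "SOX2", "EOMES", "DLX6")))
  expect_error(coexpression_network(cfm, exclude = colnames(counts)[-1]),
               "fewer than 2")
})

test_that("planted co-expression modules surface as network edges", {
  gn <- data.frame(gene = paste0("g", 1:6), mean_intensity = 100)
  for (z in c("VZ", "SVZ", "IZ", "SP", "CP")) gn[[paste0("dens_", z)]] <- 1
  cfg <- spatial_config(n_nuclei = 400, genes = gn,
                        coexpr_groups = list(m1 = c("g1", "g2"),
                                             m2 = c("g3", "g4")),
                        spot_jitter_sd = 1, seed = 9)
  scene <- generate_spatial(cfg)
  cfm <- filter_spatial_cells(assign_spots(scene$spots, scene$nuclei, 15), 10)
  net <- coexpression_network(cfm, exclude = character(0), r_min = 0.05)
  r_of <- function(a, b) {
    hit <- net$r[(net$gene1 == a & net$gene2 == b) |
                   (net$gene1 == b & net$gene2 == a)]
    if (length(hit)) hit else 0
  }
  expect_gte(r_of("g1", "g2"), 0.5)
  expect_gte(r_of("g3", "g4"), 0.5)
  # planted pairs dominate every unplanted pair
  others <- c(r_of("g1", "g3"), r_of("g1", "g4"), r_of("g2", "g3"),
              r_of("g2", "g4"), r_of("g1", "g5"), r_of("g5", "g6"))
  expect_true(all(pmin(r_of("g1", "g2"), r_of("g3", "g4")) > max(others)))
})

test_that("independent genes stay near the null without shared factors", {
  # truth-level check without the spatial stage: independent Poisson counts
  set.seed(77)
  counts <- matrix(rpois(300 * 8, 20), 300, 8,
                   dimnames = list(NULL, paste0("g", 1:8)))
  cfm <- structure(list(counts = counts,
                        cells = data.frame(id = 1:300, x = 0, y = 0,
                                           radius = 5,
                                           total = rowSums(counts)),
                        assignment = integer(0), unassigned = integer(0)),
                   class = "cell_feature_matrix")
  net <- coexpression_network(cfm, exclude = character(0), r_min = 0.05)
  # under independence r ~ N(0, 1/sqrt(n)): edges at 0.05 are the ~20%
  # one-sided tail; allow a generous binomial margin around it
  expect_lte(nrow(net), qbinom(0.999, choose(8, 2), 0.25))
})

test_that("spatial scene writes plain-text CSVs", {
  cfg <- spatial_config(n_nuclei = 30, seed = 3)
  sc <- generate_spatial(cfg)
  dir <- file.path(tempdir(), "scene_io")
  write_spatial_scene(sc, dir)
  nuc <- read.csv(file.path(dir, "nuclei.csv"))
  sp <- read.csv(file.path(dir, "spots.csv"))
  expect_equal(nrow(nuc), 30)
  expect_equal(nrow(sp), nrow(sc$spots))
  unlink(dir, recursive = TRUE)
})
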