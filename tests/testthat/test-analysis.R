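suppressMessages(library(data.table))
suppressMessages(library(Matrix))

## block-structured synthetic count matrix: n pixels per block, disjoint
## accessible tile sets, Poisson counts, plus shared background tiles
block_matrix <- function(n_per_block = 60L, n_blocks = 2L, tiles_per_block = 40L,
                         bg_tiles = 40L, rate = 3, bg_rate = 0.3, seed = 1L) {
  set.seed(seed)
  n <- n_per_block * n_blocks
  p <- tiles_per_block * n_blocks + bg_tiles
  m <- matrix(rpois(n * p, bg_rate), n, p)
  for (b in seq_len(n_blocks)) {
    rows <- (b - 1L) * n_per_block + seq_len(n_per_block)
    cols <- (b - 1L) * tiles_per_block + seq_len(tiles_per_block)
    m[rows, cols] <- rpois(length(rows) * length(cols), rate)
  }
  rownames(m) <- sprintf("px%03d", seq_len(n))
  colnames(m) <- sprintf("tile%03d", seq_len(p))
  list(mat = as(Matrix(m, sparse = TRUE), "CsparseMatrix"),
       truth = rep(seq_len(n_blocks), each = n_per_block))
}

test_that("LSI separates two disjoint accessibility blocks on one component", {
  bm <- block_matrix(seed = 5L)
  emb <- suppressWarnings(iterative_lsi(bm$mat, var_features = 500L,
                                        dims = 10L, seed = 2L))
  ## some retained component separates the blocks perfectly (sign-invariant)
  sep <- apply(emb$coords, 2L, function(v) {
    s1 <- v[bm$truth == 1]; s2 <- v[bm$truth == 2]
    max(min(s1) - max(s2), min(s2) - max(s1))
  })
  expect_gt(max(sep), 0)
  expect_false(emb$degenerate)
})

test_that("LSI flags identical-row matrices as degenerate", {
  m <- Matrix(matrix(rep(c(1, 0, 2, 0, 1), each = 20), nrow = 20), sparse = TRUE)
  rownames(m) <- sprintf("px%02d", 1:20)
  colnames(m) <- sprintf("t%02d", 1:5)
  emb <- suppressWarnings(iterative_lsi(m, var_features = 5L, dims = 3L,
                                        iterations = 1L, seed = 1L))
  expect_true(emb$degenerate)
})

test_that("LSI embeddings are bit-identical under a fixed seed", {
  bm <- block_matrix(seed = 6L)
  e1 <- suppressWarnings(iterative_lsi(bm$mat, var_features = 120L, seed = 42L))
  e2 <- suppressWarnings(iterative_lsi(bm$mat, var_features = 120L, seed = 42L))
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$features, e2$features)
})

test_that("LSI is robust to doubling one pixel's depth", {
  bm <- block_matrix(seed = 8L)
  m2 <- bm$mat
  m2[1, ] <- 2 * m2[1, ]
  e1 <- suppressWarnings(iterative_lsi(bm$mat, var_features = 120L, seed = 3L))
  e2 <- suppressWarnings(iterative_lsi(m2, var_features = 120L, seed = 3L))
  ## the doubled pixel stays near its block's centroid in retained space
  d <- min(ncol(e1$coords), ncol(e2$coords))
  cent <- colMeans(e2$coords[bm$truth == 1, seq_len(d), drop = FALSE])
  spread <- mean(sqrt(rowSums(sweep(
    e2$coords[bm$truth == 1, seq_len(d), drop = FALSE], 2, cent)^2)))
  d1 <- sqrt(sum((e2$coords[1, seq_len(d)] - cent)^2))
  expect_lt(d1, 3 * spread)
})

test_that("graph clustering recovers well-separated blocks exactly", {
  bm <- block_matrix(n_blocks = 3L, seed = 9L)
  emb <- suppressWarnings(iterative_lsi(bm$mat, var_features = 160L, seed = 4L))
  cl <- cluster_graph(emb, resolution = 0.5, seed = 4L)
  expect_gte(ari(cl$label, bm$truth), 0.9)
  expect_identical(sort(unique(cl$label)), seq_along(unique(cl$label)) - 1L)

  ## resolution -> 0 collapses a connected homogeneous population to one
  ## cluster (disconnected SNN components can never merge)
  set.seed(20)
  hom <- Matrix(matrix(rpois(80 * 50, 2), 80, 50), sparse = TRUE)
  rownames(hom) <- sprintf("h%02d", 1:80)
  colnames(hom) <- sprintf("t%02d", 1:50)
  ehom <- suppressWarnings(iterative_lsi(hom, var_features = 50L,
                                         iterations = 1L, seed = 4L))
  cl0 <- cluster_graph(ehom, resolution = 1e-5, seed = 4L)
  expect_identical(length(unique(cl0$label)), 1L)

  ## permuting pixel order leaves the partition unchanged up to relabeling
  perm <- sample(nrow(bm$mat))
  clp <- cluster_graph(emb$coords[perm, ], resolution = 0.5, seed = 4L)
  expect_gte(ari(clp$label[match(cl$barcode, clp$barcode)], cl$label), 0.999)
})

test_that("UMAP is seeded and separates block structure", {
  bm <- block_matrix(n_blocks = 3L, seed = 10L)
  emb <- suppressWarnings(iterative_lsi(bm$mat, var_features = 160L, seed = 5L))
  u1 <- umap_embed(emb, n_neighbors = 15L, seed = 11L)
  u2 <- umap_embed(emb, n_neighbors = 15L, seed = 11L)
  expect_identical(u1, u2)
  sil <- cluster::silhouette(bm$truth, dist(u1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(umap_embed(matrix(1, 10, 3)), "degenerate")
})

test_that("Wilcoxon markers recover planted features and stay quiet on null", {
  bm <- block_matrix(n_blocks = 2L, seed = 12L)
  labels <- data.table(barcode = rownames(bm$mat), label = bm$truth - 1L)
  mk <- marker_features(bm$mat, labels)
  ## block-1 tiles are markers of cluster 0 with large fold changes
  m0 <- mk[cluster == 0L]
  expect_gte(sum(sprintf("tile%03d", 1:40) %in% m0$feature), 36L)
  expect_true(all(m0[feature %in% sprintf("tile%03d", 1:40), log2FC] > 1))
  expect_true(all(mk$FDR >= mk$p))

  ## permuted labels: essentially no FDR-passing markers
  set.seed(13)
  perm_lab <- data.table(barcode = rownames(bm$mat),
                         label = sample(bm$truth - 1L))
  mk_null <- marker_features(bm$mat, perm_lab)
  expect_lte(nrow(mk_null), 2L)

  ## identical clusters -> empty table
  same <- Matrix(matrix(rpois(400, 1), 20, 20), sparse = TRUE)
  rownames(same) <- sprintf("p%02d", 1:20)
  colnames(same) <- sprintf("f%02d", 1:20)
  lab2 <- data.table(barcode = rownames(same), label = rep(0:1, each = 10L))
  ## same distribution in both clusters: nothing should pass
  expect_lte(nrow(marker_features(same, lab2)), 1L)
  expect_error(marker_features(same, data.table(barcode = rownames(same),
                                                label = 0L)), ">= 2 clusters")
})

test_that("pseudotime respects segment geometry and backbone order", {
  ## two point-clusters with one pixel exactly at the midpoint
  emb <- rbind(matrix(rep(c(0, 0), each = 20), 20, 2) + rnorm(40, sd = 1e-3),
               c(5, 0),
               matrix(rep(c(10, 0), each = 20), 20, 2) + rnorm(40, sd = 1e-3))
  rownames(emb) <- sprintf("p%02d", seq_len(nrow(emb)))
  lab <- c(rep(0L, 21L), rep(1L, 20L))
  tr <- backbone_pseudotime(emb, lab, backbone = c(0L, 1L))
  expect_equal(tr$pseudotime[21], 50, tolerance = 1)
  ## cluster means increase along the backbone
  expect_lt(mean(tr$pseudotime[lab == 0L]), mean(tr$pseudotime[lab == 1L]))
  expect_true(all(tr$pseudotime >= 0 & tr$pseudotime <= 100))

  ## pixels outside backbone clusters are excluded with NA pseudotime
  lab3 <- lab; lab3[1:5] <- 2L
  tr3 <- backbone_pseudotime(emb, lab3, backbone = c(0L, 1L))
  expect_true(all(is.na(tr3$pseudotime[lab3 == 2L])))
  expect_false(any(tr3$in_backbone[lab3 == 2L]))
  expect_error(backbone_pseudotime(emb, lab, backbone = c(0L, 7L)),
               "no pixels")
})

test_that("feature dynamics along pseudotime bin and smooth correctly", {
  set.seed(14)
  n <- 90L
  emb <- cbind(seq(0, 10, length.out = n) + rnorm(n, sd = 0.1), rnorm(n, sd = 0.1))
  rownames(emb) <- sprintf("p%03d", seq_len(n))
  lab <- rep(0:2, each = 30L)
  tr <- backbone_pseudotime(emb, lab, backbone = 0:2)
  ## a feature linear in the latent position has monotone binned means
  mat <- cbind(lin = seq_len(n) + rnorm(n, sd = 2), flat = rep(5, n))
  rownames(mat) <- rownames(emb)
  fb <- feature_along_pseudotime(mat, tr, "lin", n_bins = 9L)
  expect_identical(sum(fb$n), n)
  expect_gt(cor(fb$bin, fb$smoothed, method = "spearman"), 0.95)
  ## constant feature gives a flat curve
  fc <- feature_along_pseudotime(mat, tr, "flat", n_bins = 9L)
  expect_true(all(abs(fc$smoothed - 5) < 1e-9))
  expect_error(feature_along_pseudotime(mat, tr, "lin", n_bins = 200L),
               "exceeds")
})

test_that("gradient-layout simulation yields pseudotime tracking the truth axis", {
  genome <- small_genome()
  cfg <- sim_config(n_a = 20L, n_b = 10L, depth = 150)
  tissue <- make_tissue(cfg, layout = "gradient", seed = 121L)
  fr <- simulate_fragments(genome, tissue, cfg, seed = 122L)
  tm <- build_tile_matrix(fr, genome$contig_sizes)
  emb <- suppressWarnings(iterative_lsi(tm, var_features = 200L, seed = 123L))
  ## order backbone clusters by their mean truth coordinate
  g <- tissue$gradient[match(rownames(tm), tissue$barcode)]
  reg <- tissue$region[match(rownames(tm), tissue$barcode)]
  cl <- data.table(barcode = rownames(tm), label = reg - 1L)
  tr <- backbone_pseudotime(emb, cl, backbone = 0:2)
  rho <- cor(tr$pseudotime, g[match(tr$barcode, rownames(tm))],
             method = "spearman")
  expect_gte(abs(rho), 0.8)
})
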