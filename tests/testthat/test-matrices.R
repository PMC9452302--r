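suppressMessages(library(data.table))
suppressMessages(library(Matrix))

test_that("tile matrix places both insertions of a fragment correctly", {
  sizes <- c(chr1 = 1000000L)
  fr <- data.table(contig = "chr1", start = 104L, end = 195L,
                   barcode = "P1", dup_count = 1L)
  tm <- build_tile_matrix(fr, sizes)
  expect_identical(ncol(tm), 200L)  # 1 Mb at 5-kb tiles
  expect_equal(unname(tm["P1", 1]), 2)  # both insertions in tile 0
  expect_equal(sum(tm), 2)

  ## fragment spanning a tile boundary: one insertion in each tile
  fr2 <- data.table(contig = "chr1", start = 4998L, end = 5003L,
                    barcode = "P1", dup_count = 1L)
  tm2 <- build_tile_matrix(fr2, sizes)
  expect_equal(unname(tm2["P1", 1]), 1)
  expect_equal(unname(tm2["P1", 2]), 1)

  ## mitochondrial fragments are excluded; unknown contigs error
  frm <- rbind(fr, data.table(contig = "chrM", start = 1L, end = 50L,
                              barcode = "P1", dup_count = 1L))
  expect_equal(sum(build_tile_matrix(frm, c(sizes, chrM = 16000L))), 2)
  expect_error(build_tile_matrix(
    data.table(contig = "chrX", start = 1L, end = 5L, barcode = "P", dup_count = 1L),
    sizes), "absent from contig_sizes")
  expect_error(build_tile_matrix(
    data.table(contig = "chr1", start = 999998L, end = 1000050L,
               barcode = "P", dup_count = 1L), sizes), "beyond")
})

test_that("tile counts conserve 2 x unique nuclear fragments", {
  run <- small_run()
  fr <- deduplicate_fragments(
    run$fragments[, .(contig, start, end, barcode, dup_count)],
    names(run$genome$contig_sizes))
  tm <- build_tile_matrix(fr, run$genome$contig_sizes)
  qc <- unique_per_pixel(fr)
  expect_equal(sum(tm), 2 * sum(qc$unique_nuclear))
  ## tile partition covers each contig exactly
  map <- attr(tm, "tile_map")
  widths <- map[, .(tot = sum(end - start)), by = contig]
  nuc <- run$genome$contig_sizes[widths$contig]
  expect_equal(widths$tot, unname(nuc))
})

test_that("gene scores follow the exponential-decay model", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 60000),
                                  strand = "+")
  names(genes) <- "g1"
  ## insertions inside the gene body: weight 1 each, score = count
  fr <- data.table(contig = "chr1", start = c(52000L, 55000L),
                   end = c(52100L, 55100L), barcode = "P1", dup_count = 1L)
  gs <- build_gene_scores(fr, genes)
  expect_equal(unname(gs["P1", "g1"]), 4)  # 2 fragments x 2 insertions

  ## single insertion at distance 5000 bp downstream of the body: weight e^-1
  ## (one fragment has both cut sites at the same offset scale; use a 1-bp
  ##  fragment so both insertions coincide at end-1 = start)
  fr2 <- data.table(contig = "chr1", start = 64999L, end = 65000L,
                    barcode = "P1", dup_count = 1L)
  gs2 <- build_gene_scores(fr2, genes)
  expect_equal(unname(gs2["P1", "g1"]), 2 * exp(-1), tolerance = 1e-6)

  ## insertions beyond max_dist contribute nothing
  fr3 <- data.table(contig = "chr1", start = 300000L, end = 300001L,
                    barcode = "P1", dup_count = 1L)
  expect_equal(sum(build_gene_scores(fr3, genes)), 0)

  ## upstream extension is strand-aware: 5 kb upstream of a "+" gene
  ## still has weight 1
  fr4 <- data.table(contig = "chr1", start = 46000L, end = 46001L,
                    barcode = "P1", dup_count = 1L)
  expect_equal(unname(build_gene_scores(fr4, genes)["P1", "g1"]), 2)

  ## monotone: adding a nearby insertion never lowers the score
  gs_both <- build_gene_scores(rbind(fr, fr2), genes)
  expect_gte(gs_both["P1", "g1"], gs["P1", "g1"])
})

test_that("region-enriched promoters yield higher gene scores in-region", {
  ## sparse genome: promoter peaks ~45 kb apart, far beyond the 5-kb decay,
  ## so each gene's score isolates its own promoter's accessibility
  genome <- make_genome(contig_lengths = c(chr1 = 200000L, chr2 = 200000L),
                        n_peaks = 9L, n_genes = 9L, seed = 7L)
  cfg <- small_config(depth = 200)
  tissue <- make_tissue(cfg, seed = 111L)
  fr <- simulate_fragments(genome, tissue, cfg, seed = 112L)
  gs <- build_gene_scores(fr, genome$genes)
  sets <- attr(spatac:::region_peak_weights(length(genome$peaks), 3L, 0.8),
               "sets")
  pk_of_gene <- GenomicRanges::findOverlaps(genome$tss, genome$peaks,
                                            select = "first")
  reg <- tissue$region[match(rownames(gs), tissue$barcode)]
  ## every promoter gene scores highest in the region whose peak set
  ## contains its promoter, with a clear in/out contrast
  for (s in 1:3) {
    for (g in which(pk_of_gene %in% sets[[s]])) {
      m <- vapply(1:3, function(r) mean(gs[reg == r, g]), numeric(1))
      expect_identical(which.max(m), s)
      expect_gt(m[s] / mean(m[-s]), 3)
    }
  }
})

test_that("masking keeps on-tissue pixels and reports removals", {
  run <- small_run()
  fr <- deduplicate_fragments(
    run$fragments[, .(contig, start, end, barcode, dup_count)],
    names(run$genome$contig_sizes))
  tm <- build_tile_matrix(fr, run$genome$contig_sizes)
  ## full-grid mask is the identity on rows
  suppressMessages(full <- apply_mask(tm, run$tissue))
  expect_identical(rownames(full), rownames(tm))
  ## restricted mask keeps only the requested pixels
  sub <- run$tissue$barcode[1:10]
  suppressMessages(m10 <- apply_mask(tm, sub))
  expect_lte(nrow(m10), 10L)
  expect_identical(attr(m10, "n_removed"), nrow(tm) - nrow(m10))
  ## disjoint mask errors
  expect_error(suppressMessages(apply_mask(tm, "NOT_A_BARCODE")),
               "does not intersect")
  ## single-nucleus subsetting: matrix rows = selected pixels present
  sn <- single_nucleus_pixels(run$tissue)
  suppressMessages(msn <- apply_mask(tm, sn$barcode))
  expect_identical(sort(rownames(msn)),
                   sort(intersect(sn$barcode, rownames(tm))))
})

test_that("sparse matrix export/import round-trips losslessly", {
  run <- small_run()
  fr <- deduplicate_fragments(
    run$fragments[, .(contig, start, end, barcode, dup_count)],
    names(run$genome$contig_sizes))
  tm <- build_tile_matrix(fr, run$genome$contig_sizes)
  prefix <- tempfile("mat")
  export_matrix(tm, prefix)
  back <- import_matrix(prefix)
  expect_equal(sum(back), sum(tm))
  expect_identical(dimnames(back), dimnames(tm))
  expect_equal(max(abs(back - tm)), 0)

  ## reordering triplet lines yields an equal matrix
  mtx <- readLines(paste0(prefix, ".mtx"))
  body <- mtx[-(1:2)]
  writeLines(c(mtx[1:2], rev(body)), paste0(prefix, ".mtx"))
  expect_equal(max(abs(import_matrix(prefix) - tm)), 0)

  ## corrupt triplet and mismatched sidecars error
  writeLines(c(mtx[1:2], "not a triplet"), paste0(prefix, ".mtx"))
  expect_error(import_matrix(prefix), "cannot parse")
  writeLines(mtx, paste0(prefix, ".mtx"))
  writeLines("only-one-row", paste0(prefix, ".rows.txt"))
  expect_error(import_matrix(prefix), "sidecar")
})
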