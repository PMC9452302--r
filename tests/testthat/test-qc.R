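suppressMessages(library(data.table))

mk_frags <- function(contig, start, end, barcode = "P1") {
  data.table(contig = contig, start = as.integer(start), end = as.integer(end),
             barcode = barcode, dup_count = 1L)
}

test_that("per-pixel unique and mitochondrial accounting", {
  fr <- mk_frags(c(rep("chr1", 5), rep("chrM", 2)),
                 seq(100, 700, by = 100), seq(200, 800, by = 100))
  up <- unique_per_pixel(fr)
  expect_identical(up$unique_nuclear, 5L)
  expect_identical(up$total_fragments, 7L)
  expect_equal(up$mito_fraction, 2 / 7)
  expect_warning(unique_per_pixel(mk_frags("chr1", 1, 10), mito_contig = "MT"),
                 "not present")
})

test_that("TSS fraction matches the interval-overlap oracle on uniform data", {
  set.seed(4)
  L <- 1000000L
  tssg <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(seq(50000L, 950000L, by = 90000L),
                                                  width = 1L), strand = "+")
  ## all fragments inside windows -> 1.0
  inside <- mk_frags("chr1", GenomicRanges::start(tssg) - 100L,
                     GenomicRanges::start(tssg) + 100L)
  expect_equal(tss_fraction(inside, tssg)$tss_frac, 1.0)
  ## fragment touching a window edge by exactly 1 bp counts
  edge_start0 <- GenomicRanges::start(tssg)[1] - 1L - 2000L - 99L  # end = window start
  touch <- mk_frags("chr1", edge_start0, edge_start0 + 100L)
  expect_equal(tss_fraction(touch, tssg)$tss_frac, 1.0)
  miss <- mk_frags("chr1", edge_start0 - 1L, edge_start0 + 99L)
  expect_equal(tss_fraction(miss, tssg)$tss_frac, 0)

  ## uniform fragments: fraction ~ covered length / chromosome length,
  ## checked against a direct coverage computation
  n <- 20000L
  st <- as.integer(runif(n, 0, L - 300L))
  fr <- mk_frags("chr1", st, st + 100L)
  frac <- tss_fraction(fr, tssg)$tss_frac
  win <- GenomicRanges::reduce(GenomicRanges::resize(tssg, 4001L, fix = "center"))
  ## probability a 100-bp fragment overlaps a window (fragment start uniform)
  p_overlap <- sum(GenomicRanges::width(win) + 100L - 1L) / (L - 300L)
  expect_equal(frac, p_overlap, tolerance = 0.08)
  expect_error(tss_fraction(fr, tssg[0]), "empty TSS")
})

test_that("TSS enrichment is ~1 under a uniform null and recovers planted 10x", {
  genome <- small_genome()
  ## uniform null: background only, no peaks, no TSS boost, depth >= 1e5 pooled
  cfg <- small_config(depth = 1600, peak_weight = 0, tss_multiplier = 1,
                      mito_fraction = 0, min_per_pixel = 0L)
  tissue <- make_tissue(cfg, seed = 71L)
  fr <- simulate_fragments(genome, tissue, cfg, seed = 72L)
  expect_gt(nrow(fr), 1e5)
  te <- tss_enrichment(fr, genome$tss)
  expect_gt(te$pooled, 0.9); expect_lt(te$pooled, 1.1)

  ## planted 10x insertion rate at TSS cores
  cfg10 <- small_config(depth = 1600, peak_weight = 0, tss_multiplier = 10,
                        mito_fraction = 0, min_per_pixel = 0L)
  fr10 <- simulate_fragments(genome, make_tissue(cfg10, seed = 73L), cfg10,
                             seed = 74L)
  te10 <- tss_enrichment(fr10, genome$tss)
  expect_gte(te10$pooled, 8); expect_lte(te10$pooled, 12)

  ## no fragments -> degenerate flagged scores
  te0 <- tss_enrichment(fr[0], genome$tss)
  expect_identical(nrow(te0$per_pixel), 0L)
})

test_that("FRiP matches configured peak mixture and never exceeds 1", {
  genome <- small_genome()
  ## peaks covering everything -> FRiP 1
  fr <- mk_frags("chr1", c(100, 5000), c(300, 5100))
  allpk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200000))
  expect_equal(frip(fr, allpk)$frip, 1.0)
  ## duplicated/adjacent peaks do not double-count fragments
  twopk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 150), c(149, 400)))
  expect_lte(max(frip(fr, twopk)$frip), 1.0)
  expect_error(frip(fr, allpk[0]), "empty peak")

  ## simulator with 80% of nuclear fragments from peaks -> pooled FRiP ~ 0.8
  cfg <- small_config(depth = 400, peak_weight = 0.8, mito_fraction = 0,
                      tss_multiplier = 1)
  sim <- simulate_fragments(genome, make_tissue(cfg, seed = 81L), cfg, seed = 82L)
  fp <- frip(sim, genome$peaks)
  pooled <- sum(fp$n_in_peaks) / sum(fp$n_fragments)
  expect_equal(pooled, 0.8, tolerance = 0.06)
})

test_that("insert-size histogram conserves counts", {
  fr <- mk_frags("chr1", rep(100L, 4), rep(200L, 4),
                 barcode = paste0("P", 1:4))
  h <- insert_size_hist(fr, max_len = 150L)
  expect_identical(sum(h$counts), 4L)
  expect_identical(which(h$counts > 0), 100L)  # single bin at length 100
  h2 <- insert_size_hist(fr, max_len = 50L)   # all lengths beyond range
  expect_identical(h2$n_within, 0L)
})

test_that("on/off-tissue depth difference is detected; degenerate cases typed", {
  genome <- small_genome()
  cfg <- small_config(depth = 100, off_depth_frac = 0.01)
  tissue <- make_tissue(cfg, ring_width = 1L, seed = 91L)
  fr <- simulate_fragments(genome, tissue, cfg, seed = 92L)
  qc <- pixel_qc(fr, genome$tss, genome$peaks, mask = tissue)
  cmp <- on_off_tissue_compare(qc)
  expect_true(cmp$defined)
  expect_gt(cmp$median_on, cmp$median_off)
  expect_lt(cmp$p_value, 0.01)
  ## all-on-tissue -> undefined, typed result (not an error)
  cmp0 <- on_off_tissue_compare(qc[on_tissue == TRUE])
  expect_false(cmp0$defined)
  expect_true(is.na(cmp0$p_value))
})

test_that("single-nucleus pixel selection", {
  m <- data.table(canonical_id = pixel_id(1:4, 1L, 10L, 10L),
                  barcode = paste0("B", 1:4),
                  nucleus_count = c(0L, 1L, 2L, 1L))
  sel <- single_nucleus_pixels(m)
  expect_identical(nrow(sel), 2L)
  expect_identical(sel$barcode, c("B2", "B4"))
  expect_identical(nrow(single_nucleus_pixels(m[nucleus_count == 0L])), 0L)
  expect_error(single_nucleus_pixels(m[, .(barcode)]), "nucleus_count")
})

test_that("naive peak calling recovers strongly enriched simulator peaks", {
  genome <- small_genome()
  cfg <- small_config(depth = 400, peak_weight = 0.8, mito_fraction = 0,
                      tss_multiplier = 1)
  fr <- simulate_fragments(genome, make_tissue(cfg, seed = 101L), cfg, seed = 102L)
  called <- call_peaks_naive(fr, threshold = 30, min_width = 100L,
                             contig_sizes = genome$contig_sizes)
  ## >= 90% of truth peaks overlapped by a called peak
  hits <- GenomicRanges::countOverlaps(genome$peaks, called)
  expect_gte(mean(hits > 0), 0.9)
  ## zero fragments -> empty result
  expect_identical(length(call_peaks_naive(fr[0], threshold = 1)), 0L)
  ## threshold 0 -> one peak per covered contig region
  t0 <- call_peaks_naive(fr, threshold = 0, min_width = 1L,
                         contig_sizes = genome$contig_sizes)
  expect_lte(length(t0), length(genome$nuclear_contigs))
})

test_that("QC fractions always lie in [0, 1] and aggregate consistently", {
  run <- small_run()
  fr <- deduplicate_fragments(
    run$fragments[, .(contig, start, end, barcode, dup_count)],
    names(run$genome$contig_sizes))
  qc <- pixel_qc(fr, run$genome$tss, run$genome$peaks)
  for (cl in c("tss_frac", "frip", "mito_fraction")) {
    expect_true(all(qc[[cl]] >= 0 & qc[[cl]] <= 1), info = cl)
  }
  expect_true(all(qc$unique_nuclear <= qc$total_fragments))
  ## pooled counts equal the sum over disjoint pixel subsets
  expect_identical(sum(qc$total_fragments), nrow(fr))
})
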