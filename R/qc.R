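## helpers ------------------------------------------------------------------

as_bed_granges <- function(x, what = "features") {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(rtracklayer::import(x))
  stop("expected a GRanges or a BED file path for ", what)
}

## fragment intervals as GRanges (1-based closed, as IRanges expects)
fragments_granges <- function(frags) {
  GenomicRanges::GRanges(frags$contig,
                         IRanges::IRanges(frags$start + 1L, frags$end))
}

#' Tn5 insertion sites of a fragment table
#'
#' Each fragment contributes two insertions: its start and its `end - 1`
#' position (0-based), i.e. the two Tn5 cut sites.
#' @param frags fragment table.
#' @return data.table `contig`, `pos` (0-based), `barcode`.
#' @export
fragment_insertions <- function(frags) {
  frags <- as.data.table(frags)
  data.table(contig = rep(frags$contig, 2L),
             pos = c(frags$start, frags$end - 1L),
             barcode = rep(frags$barcode, 2L))
}

insertion_granges <- function(ins) {
  GenomicRanges::GRanges(ins$contig, IRanges::IRanges(ins$pos + 1L, width = 1L))
}

## QC operations -------------------------------------------------------------

#' Unique nuclear fragments and mitochondrial fraction per pixel
#'
#' Counts unique fragments per pixel, excluding the mitochondrial contig
#' from the nuclear count and reporting the mitochondrial fraction over
#' all unique fragments.
#'
#' @param frags fragment table (deduplicated).
#' @param mito_contig mitochondrial contig name (default `"chrM"`); if it
#'   is absent from the data a warning is emitted and mito counts are 0.
#' @return data.table `barcode`, `total_fragments`, `unique_nuclear`,
#'   `mito_fraction`.
#' @export
unique_per_pixel <- function(frags, mito_contig = "chrM") {
  frags <- as.data.table(frags)
  if (nrow(frags) > 0L && !mito_contig %in% frags$contig)
    warning("mitochondrial contig '", mito_contig,
            "' not present in fragments; mito counts will be zero")
  out <- frags[, .(total_fragments = .N,
                   unique_nuclear = sum(contig != mito_contig)),
               by = barcode]
  out[, mito_fraction := ifelse(total_fragments > 0,
                                (total_fragments - unique_nuclear) / total_fragments,
                                0)]
  out[]
}

#' Fraction of fragments in TSS windows, per pixel
#'
#' A fragment counts when it overlaps any TSS +/- `window_bp` window by at
#' least 1 bp. The denominator is the pixel's unique nuclear fragments.
#'
#' @param frags fragment table.
#' @param tss GRanges (width-1, stranded) or BED path of TSS positions.
#' @param window_bp half-window around each TSS (default 2000).
#' @param mito_contig excluded from the denominator.
#' @return data.table `barcode`, `n_tss`, `n_nuclear`, `tss_frac`.
#' @export
tss_fraction <- function(frags, tss, window_bp = 2000L, mito_contig = "chrM") {
  tss <- as_bed_granges(tss, "TSS")
  if (length(tss) == 0L) stop("empty TSS set: TSS fraction is undefined")
  frags <- as.data.table(frags)[contig != mito_contig]
  win <- GenomicRanges::resize(tss, 2L * window_bp + 1L, fix = "center")
  hit <- rep(FALSE, nrow(frags))
  if (nrow(frags) > 0L) {
    ov <- GenomicRanges::findOverlaps(fragments_granges(frags), win)
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  out <- data.table(barcode = frags$barcode, hit = hit)[
    , .(n_tss = sum(hit), n_nuclear = .N), by = barcode]
  out[, tss_frac := n_tss / n_nuclear]
  out[]
}

#' TSS enrichment score per pixel and pooled
#'
#' The score is the mean per-base Tn5 insertion depth in the TSS +/- 50 bp
#' core, aggregated over all TSSs, divided by the mean per-base depth in
#' the distal flanks (positions 1,901-2,000 bp on both sides, 200 bases
#' total), with a pseudocount of one insertion added to the flank count.
#' TSS strand flips window orientation (the windows used here are
#' symmetric, so this only matters for asymmetric settings). Uniform
#' insertions give a score near 1; promoter-enriched libraries score well
#' above it.
#'
#' @param frags fragment table.
#' @param tss GRanges or BED path of TSS positions.
#' @param core_half half-width of the core window (default 50).
#' @param flank_range distance range of each flank (default `c(1901, 2000)`).
#' @param pseudocount insertions added to the flank count (default 1).
#' @param mito_contig excluded contig.
#' @return list with `pooled` (single score), `per_pixel` (data.table
#'   `barcode`, `core`, `flank`, `tss_enrichment`, `degenerate` flag for
#'   pixels with zero flank coverage), and the window metadata.
#' @export
tss_enrichment <- function(frags, tss, core_half = 50L,
                           flank_range = c(1901L, 2000L), pseudocount = 1,
                           mito_contig = "chrM") {
  tss <- as_bed_granges(tss, "TSS")
  if (length(tss) == 0L) stop("empty TSS set: enrichment is undefined")
  frags <- as.data.table(frags)[contig != mito_contig]
  ins <- fragment_insertions(frags)
  reach <- flank_range[2]
  win <- GenomicRanges::resize(tss, 2L * reach + 1L, fix = "center")
  n_core_bases <- (2L * core_half + 1L) * length(tss)
  n_flank_bases <- 2L * (flank_range[2] - flank_range[1] + 1L) * length(tss)

  core_flank <- function(sel_ins) {
    if (nrow(sel_ins) == 0L)
      return(data.table(barcode = character(), core = integer(),
                        flank = integer()))
    ov <- GenomicRanges::findOverlaps(insertion_granges(sel_ins), win)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    tss_pos <- GenomicRanges::start(tss)[si] - 1L  # 0-based
    sgn <- ifelse(as.character(GenomicRanges::strand(tss))[si] == "-", -1L, 1L)
    rel <- (sel_ins$pos[qi] - tss_pos) * sgn
    dt <- data.table(barcode = sel_ins$barcode[qi], rel = rel)
    dt[, .(core = sum(abs(rel) <= core_half),
           flank = sum(abs(rel) >= flank_range[1] & abs(rel) <= flank_range[2])),
       by = barcode]
  }

  per_tss <- core_flank(ins)
  all_px <- data.table(barcode = unique(frags$barcode))
  per_px <- merge(all_px, per_tss, by = "barcode", all.x = TRUE)
  per_px[is.na(core), `:=`(core = 0L, flank = 0L)]
  score <- function(core, flank)
    (core / n_core_bases) / ((flank + pseudocount) / n_flank_bases)
  per_px[, tss_enrichment := score(core, flank)]
  per_px[, degenerate := flank == 0L]
  pooled_core <- sum(per_px$core); pooled_flank <- sum(per_px$flank)
  list(pooled = score(pooled_core, pooled_flank),
       per_pixel = per_px[],
       windows = list(core_half = core_half, flank_range = flank_range,
                      pseudocount = pseudocount))
}

#' Fraction of fragments in peaks (FRiP), per pixel
#'
#' Fraction of a pixel's unique fragments overlapping at least one peak by
#' at least 1 bp; overlapping several peaks counts once.
#'
#' @param frags fragment table (deduplicated).
#' @param peaks GRanges or BED path.
#' @return data.table `barcode`, `n_in_peaks`, `n_fragments`, `frip`.
#' @export
frip <- function(frags, peaks) {
  peaks <- as_bed_granges(peaks, "peaks")
  if (length(peaks) == 0L) stop("empty peak set: FRiP is undefined")
  frags <- as.data.table(frags)
  hit <- rep(FALSE, nrow(frags))
  if (nrow(frags) > 0L) {
    ov <- GenomicRanges::findOverlaps(fragments_granges(frags), peaks)
    hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  out <- data.table(barcode = frags$barcode, hit = hit)[
    , .(n_in_peaks = sum(hit), n_fragments = .N), by = barcode]
  out[, frip := n_in_peaks / n_fragments]
  out[]
}

#' Insert-size histogram of unique fragments
#'
#' @param frags fragment table (deduplicated; duplicates counted once).
#' @param max_len maximum length considered (default 600).
#' @return list with `counts` (integer vector indexed by length 1..max_len),
#'   `max_len`, and `n_within` = sum of counts.
#' @export
insert_size_hist <- function(frags, max_len = 600L) {
  len <- as.data.table(frags)[, end - start]
  len <- len[len >= 1L & len <= max_len]
  counts <- tabulate(len, nbins = max_len)
  list(counts = counts, max_len = max_len, n_within = sum(counts))
}

#' Compare unique nuclear fragments on vs off tissue
#'
#' Wilcoxon rank-sum comparison of per-pixel unique nuclear fragment
#' counts between on- and off-tissue pixels.
#'
#' @param qc per-pixel QC table with `unique_nuclear` and `on_tissue`.
#' @return list with `defined`, medians, `n_on`, `n_off` and `p_value`
#'   (rank-sum, two-sided). When all pixels fall on one side the
#'   comparison is reported as undefined rather than erroring.
#' @export
on_off_tissue_compare <- function(qc) {
  qc <- as.data.table(qc)
  stopifnot(all(c("unique_nuclear", "on_tissue") %in% names(qc)))
  on <- qc$unique_nuclear[qc$on_tissue %in% TRUE]
  off <- qc$unique_nuclear[qc$on_tissue %in% FALSE]
  if (length(on) == 0L || length(off) == 0L)
    return(list(defined = FALSE, n_on = length(on), n_off = length(off),
                median_on = NA_real_, median_off = NA_real_,
                p_value = NA_real_))
  wt <- wilcox.test(on, off, exact = FALSE)
  list(defined = TRUE, n_on = length(on), n_off = length(off),
       median_on = median(on), median_off = median(off),
       p_value = wt$p.value)
}

#' Select pixels containing exactly one nucleus
#'
#' Imaging-derived nucleus counts (consumed from the mask CSV) identify
#' pixels whose signal comes from a single cell, usable to subset any
#' pixel-by-feature matrix to near single-cell resolution.
#'
#' @param mask table with `nucleus_count` and `canonical_id` (and
#'   optionally `barcode`).
#' @return the subset of rows with `nucleus_count == 1`.
#' @export
single_nucleus_pixels <- function(mask) {
  mask <- as.data.table(mask)
  if (!"nucleus_count" %in% names(mask))
    stop("mask table lacks a 'nucleus_count' column")
  mask[nucleus_count == 1L]
}

#' Naive threshold peak caller on pooled insertion coverage
#'
#' A deterministic substitute for a model-based peak caller, intended for
#' synthetic data: pooled Tn5 insertion events are smoothed by counting
#' insertions within a `smooth_bp` window, and maximal runs of smoothed
#' coverage `>= threshold` wider than `min_width` are reported.
#'
#' @param frags fragment table.
#' @param threshold minimum smoothed insertion count.
#' @param min_width minimum peak width (default 100 bp).
#' @param smooth_bp smoothing window (default 200 bp).
#' @param contig_sizes optional named lengths (peaks clipped to them).
#' @param mito_contig excluded contig.
#' @return GRanges of peaks.
#' @export
call_peaks_naive <- function(frags, threshold, min_width = 100L,
                             smooth_bp = 200L, contig_sizes = NULL,
                             mito_contig = "chrM") {
  frags <- as.data.table(frags)[contig != mito_contig]
  if (nrow(frags) == 0L) return(GenomicRanges::GRanges())
  ins <- fragment_insertions(frags)
  gr <- GenomicRanges::resize(insertion_granges(ins), smooth_bp, fix = "center")
  st <- pmax(1L, GenomicRanges::start(gr))
  en <- GenomicRanges::end(gr)
  if (!is.null(contig_sizes))
    en <- pmin(en, unname(contig_sizes[as.character(GenomicRanges::seqnames(gr))]))
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                               IRanges::IRanges(st, pmax(st, en)))
  if (!is.null(contig_sizes)) {
    lv <- names(contig_sizes)[names(contig_sizes) != mito_contig]
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr), lv)
    GenomeInfoDb::seqlengths(gr)[lv] <- unname(contig_sizes[lv])
  }
  cov <- GenomicRanges::coverage(gr)
  sl <- IRanges::slice(cov, lower = threshold, includeLower = TRUE,
                       rangesOnly = TRUE)
  out <- GenomicRanges::GRanges(sl)
  out[GenomicRanges::width(out) >= min_width]
}

#' Full per-pixel QC table
#'
#' Joins unique/mito counts, TSS fraction, TSS enrichment and FRiP, plus
#' on-tissue flags and nucleus counts from an optional mask.
#'
#' @param frags deduplicated fragment table.
#' @param tss,peaks GRanges or BED paths.
#' @param mask optional mask table (from [read_mask()]) with `barcode`,
#'   `on_tissue`, `nucleus_count`.
#' @param mito_contig mitochondrial contig name.
#' @param tss_window_bp window for the TSS fraction.
#' @return data.table, one row per pixel with data.
#' @export
pixel_qc <- function(frags, tss, peaks, mask = NULL, mito_contig = "chrM",
                     tss_window_bp = 2000L) {
  up <- unique_per_pixel(frags, mito_contig)
  tf <- tss_fraction(frags, tss, tss_window_bp, mito_contig)
  te <- tss_enrichment(frags, tss, mito_contig = mito_contig)$per_pixel
  fr <- frip(frags, peaks)
  out <- Reduce(function(a, b) merge(a, b, by = "barcode", all.x = TRUE),
                list(up,
                     tf[, .(barcode, tss_frac)],
                     te[, .(barcode, tss_enrichment)],
                     fr[, .(barcode, frip)]))
  for (cl in c("tss_frac", "tss_enrichment", "frip"))
    out[is.na(get(cl)), (cl) := 0]
  if (!is.null(mask)) {
    mask <- as.data.table(mask)
    keep <- intersect(c("barcode", "on_tissue", "nucleus_count", "canonical_id"),
                      names(mask))
    out <- merge(out, mask[, keep, with = FALSE], by = "barcode", all.x = TRUE)
  }
  out[]
}
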