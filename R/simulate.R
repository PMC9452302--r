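#' Simulation configuration
#'
#' Bundles every tunable of the synthetic spatial ATAC-seq generator. The
#' defaults describe a desk-scale run of the assay: a 50 x 50 microfluidic
#' barcode grid (2,500 pixels), a bimodal Tn5 fragment-length mixture
#' (subnucleosomal + mono-nucleosomal), geometric PCR duplication,
#' uniform sequencing errors, mitochondrial contamination, and
#' region-structured accessibility over a peak set.
#'
#' @param n_a,n_b grid dimensions (barcode-A and barcode-B channels).
#' @param depth mean unique fragments per on-tissue pixel (Poisson).
#' @param off_depth_frac off-tissue depth as a fraction of on-tissue depth.
#' @param min_per_pixel floor on fragments per pixel, guaranteeing grid
#'   coverage (set 0 for a pure Poisson draw).
#' @param dup_rate duplicate-read rate; copies per unique fragment are
#'   `1 + Geometric(1 - dup_rate)`, so mean copies = `1/(1 - dup_rate)`.
#' @param error_rate per-base substitution error rate in simulated reads.
#' @param mito_fraction fraction of fragments drawn from the mitochondrial
#'   contig.
#' @param peak_weight fraction of nuclear fragments drawn from peak regions
#'   (the accessible component).
#' @param tss_multiplier target fold-enrichment of insertion density at TSS
#'   cores over background; the TSS component weight is derived from it.
#' @param region_own_share fraction of a region's peak component placed on
#'   its own peak subset (the rest spreads uniformly over all peaks).
#' @param len_weights,len_means,len_sds two-mode fragment-length mixture;
#'   defaults 60% N(60, 15) + 40% N(200, 25).
#' @param len_range truncation range for fragment lengths (bp).
#' @param tn5_shifts plus/minus-strand shifts relating aligned 5' ends to
#'   the corrected fragment interval (standard +4/-5 convention).
#' @param read1_genomic,read2_len genomic bases sequenced on each mate.
#' @param nucleus_lambda Poisson mean of nuclei per on-tissue pixel.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_a = 50L, n_b = 50L,
                       depth = 150, off_depth_frac = 0.01, min_per_pixel = 1L,
                       dup_rate = 0.3, error_rate = 0.01,
                       mito_fraction = 0.05, peak_weight = 0.7,
                       tss_multiplier = 10, region_own_share = 0.8,
                       len_weights = c(0.6, 0.4),
                       len_means = c(60, 200), len_sds = c(15, 25),
                       len_range = c(20L, 600L),
                       tn5_shifts = c(4L, 5L),
                       read1_genomic = 50L, read2_len = 50L,
                       nucleus_lambda = 1.2) {
  stopifnot(dup_rate >= 0, dup_rate < 1, error_rate >= 0, error_rate <= 1,
            mito_fraction >= 0, mito_fraction < 1,
            peak_weight >= 0, peak_weight <= 1,
            abs(sum(len_weights) - 1) < 1e-8, tss_multiplier >= 1)
  structure(as.list(environment()), class = "sim_config")
}

## stratified non-overlapping placement: n intervals of `width` bp inside
## [margin, len - margin], one per equal slot, jittered within its slot
place_nonoverlapping <- function(len, n, width, margin = 3000L) {
  if (n == 0L) return(integer(0))
  usable <- len - 2L * margin
  slot <- usable / n
  if (slot < width) stop("contig too short for ", n, " features of width ", width)
  jitter <- floor(runif(n) * (slot - width))
  as.integer(margin + floor((seq_len(n) - 1L) * slot) + jitter)
}

#' Generate a synthetic genome with TSSs, peaks and genes
#'
#' Builds random-sequence contigs plus a small mitochondrial contig, a set
#' of non-overlapping accessible peak regions, and gene models whose TSSs
#' sit at the centres of a subset of peaks (promoter peaks), so promoter
#' accessibility differences propagate into gene scores.
#'
#' @param contig_lengths named integer vector of nuclear contig lengths.
#' @param mito_length length of the mitochondrial contig.
#' @param mito_contig its name.
#' @param n_peaks total peak count (split across nuclear contigs
#'   proportionally to length).
#' @param peak_width peak width in bp.
#' @param n_genes gene count (must be `<= n_peaks`).
#' @param gene_body_range min/max gene body length (bp), drawn uniformly.
#' @param seed RNG seed; the same seed reproduces the genome byte-for-byte.
#' @return a `synthetic_genome`: list with `seqs` (DNAStringSet),
#'   `contig_sizes`, `tss`, `peaks`, `genes` (GRanges) and `mito_contig`.
#' @export
make_genome <- function(contig_lengths = c(chr1 = 600000L, chr2 = 600000L,
                                           chr3 = 600000L),
                        mito_length = 16000L, mito_contig = "chrM",
                        n_peaks = 150L, peak_width = 400L,
                        n_genes = 45L, gene_body_range = c(2000L, 8000L),
                        seed = 1L) {
  stopifnot(all(contig_lengths >= 10000L), n_genes <= n_peaks)
  set.seed(seed)
  all_lens <- c(contig_lengths, setNames(mito_length, mito_contig))
  seqs <- Biostrings::DNAStringSet(vapply(all_lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), ""))
  names(seqs) <- names(all_lens)

  ## peaks: proportional allocation over nuclear contigs, stratified placement
  alloc <- floor(n_peaks * contig_lengths / sum(contig_lengths))
  rem <- n_peaks - sum(alloc)
  if (rem > 0L) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  pk <- data.table(
    contig = rep(names(contig_lengths), alloc),
    start = unlist(lapply(seq_along(contig_lengths), function(i)
      place_nonoverlapping(contig_lengths[i], alloc[i], peak_width))))
  peaks <- GenomicRanges::GRanges(pk$contig,
                                  IRanges::IRanges(pk$start + 1L, width = peak_width))
  peaks <- GenomicRanges::sort(peaks)
  names(peaks) <- sprintf("peak%03d", seq_along(peaks))

  ## genes: TSS at the centre of a random subset of peaks
  gidx <- sort(sample(length(peaks), n_genes))
  tss_pos <- as.integer((GenomicRanges::start(peaks[gidx]) +
                           GenomicRanges::end(peaks[gidx])) %/% 2)
  gstrand <- sample(c("+", "-"), n_genes, replace = TRUE)
  body_len <- as.integer(runif(n_genes, gene_body_range[1], gene_body_range[2]))
  gcontig <- as.character(GenomicRanges::seqnames(peaks[gidx]))
  gstart <- ifelse(gstrand == "+", tss_pos, pmax(1L, tss_pos - body_len))
  gend <- ifelse(gstrand == "+",
                 pmin(contig_lengths[gcontig], tss_pos + body_len), tss_pos)
  genes <- GenomicRanges::GRanges(gcontig, IRanges::IRanges(gstart, gend),
                                  strand = gstrand)
  names(genes) <- sprintf("gene%03d", seq_len(n_genes))
  genes$gene_id <- names(genes)
  tss <- GenomicRanges::GRanges(gcontig, IRanges::IRanges(tss_pos, width = 1L),
                                strand = gstrand)
  names(tss) <- names(genes)

  structure(list(seqs = seqs, contig_sizes = all_lens,
                 nuclear_contigs = names(contig_lengths),
                 tss = tss, peaks = peaks, genes = genes,
                 mito_contig = mito_contig, seed = seed),
            class = "synthetic_genome")
}

#' Serialize a synthetic genome to standard formats
#'
#' Writes `genome.fa`, `tss.bed` (6-column, stranded), `peaks.bed`,
#' `genes.bed` and `contig_sizes.tsv` into `dir`.
#' @param genome a [make_genome()] result.
#' @param dir output directory (created if needed).
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome$seqs, file.path(dir, "genome.fa"))
  rtracklayer::export(genome$tss, file.path(dir, "tss.bed"))
  rtracklayer::export(genome$peaks, file.path(dir, "peaks.bed"))
  rtracklayer::export(genome$genes, file.path(dir, "genes.bed"))
  write.table(data.frame(names(genome$contig_sizes), unname(genome$contig_sizes)),
              file.path(dir, "contig_sizes.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Generate a spatial tissue ground truth over the barcode grid
#'
#' Lays region labels over the `n_a x n_b` pixel grid. `"bands"` splits the
#' grid into `n_regions` vertical bands of contrasting accessibility;
#' `"gradient"` assigns each pixel a coordinate `g` in `[0, 1]` along the
#' A axis, with accessibility interpolating smoothly between region peak
#' sets (region labels are then the terciles of `g`). An optional
#' off-tissue ring of width `ring_width` marks border pixels off-tissue at
#' strongly reduced depth. Per-pixel nucleus counts are Poisson.
#'
#' @param config a [sim_config()].
#' @param layout `"bands"` or `"gradient"`.
#' @param n_regions number of regions (default 3).
#' @param ring_width off-tissue border width in pixels (0 = all on-tissue).
#' @param wl_a,wl_b whitelists defining pixel barcodes.
#' @param seed RNG seed.
#' @return `tissue_truth` data.table: one row per pixel with `a_index`,
#'   `b_index`, `canonical_id`, `barcode`, `region`, `gradient`,
#'   `on_tissue`, `depth`, `nucleus_count`.
#' @export
make_tissue <- function(config = sim_config(), layout = c("bands", "gradient"),
                        n_regions = 3L, ring_width = 0L,
                        wl_a = default_whitelist("A"),
                        wl_b = default_whitelist("B"), seed = 1L) {
  layout <- match.arg(layout)
  set.seed(seed)
  n_a <- config$n_a; n_b <- config$n_b
  stopifnot(n_a <= length(wl_a$entries), n_b <= length(wl_b$entries),
            n_regions >= 1L, n_a >= n_regions)
  tt <- data.table(expand.grid(a_index = seq_len(n_a), b_index = seq_len(n_b)))
  tt[, canonical_id := pixel_id(a_index, b_index, n_a, n_b)]
  tt[, barcode := pixel_barcode(a_index, b_index, wl_a, wl_b)]
  band <- ceiling(tt$a_index / (n_a / n_regions))
  tt[, gradient := if (layout == "gradient") (a_index - 1) / (n_a - 1) else NA_real_]
  tt[, region := pmin(band, n_regions)]
  if (layout == "gradient")
    tt[, region := pmin(n_regions, 1L + floor(gradient * n_regions))]
  tt[, on_tissue := a_index > ring_width & a_index <= n_a - ring_width &
       b_index > ring_width & b_index <= n_b - ring_width]
  if (!any(tt$on_tissue)) stop("ring_width leaves no on-tissue pixels")
  for (r in seq_len(n_regions))
    if (!any(tt$region == r)) stop("region ", r, " has zero pixels")
  tt[, depth := config$depth * ifelse(on_tissue, 1, config$off_depth_frac)]
  tt[, nucleus_count := ifelse(on_tissue, rpois(.N, config$nucleus_lambda), 0L)]
  setattr(tt, "layout", layout)
  setattr(tt, "n_regions", n_regions)
  setattr(tt, "class", c("tissue_truth", class(tt)))
  tt[]
}

#' Write / read the pixel metadata (mask) CSV
#'
#' The mask CSV is the interface through which imaging-derived metadata
#' (on-tissue flag, nucleus counts) enters the pipeline.
#' @param tissue a [make_tissue()] table (or any table with the same columns).
#' @param path CSV path.
#' @export
write_mask <- function(tissue, path) {
  out <- as.data.table(tissue)[, .(canonical_id, row = b_index, col = a_index,
                                   barcode, on_tissue, nucleus_count,
                                   region, gradient)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- data.table::fread(path)
  need <- c("canonical_id", "on_tissue")
  if (!all(need %in% names(m)))
    stop("mask CSV must contain columns: ", paste(need, collapse = ", "))
  parse_pixel_id(m$canonical_id)  # validates ids
  m
}

## discretised fragment-length mixture pmf on the truncation range
length_pmf <- function(config) {
  len <- seq(config$len_range[1], config$len_range[2])
  d <- rowSums(vapply(seq_along(config$len_weights), function(k)
    config$len_weights[k] * stats::dnorm(len, config$len_means[k],
                                         config$len_sds[k]),
    numeric(length(len))))
  list(len = len, p = d / sum(d))
}

## component weights (mito, tss, peak, background) derived from the config
## and the genome geometry. Each fragment deposits two insertions, so the
## background per-base insertion rate is 2*w_bg*D/L while a TSS-component
## fragment puts exactly one insertion in a 101-bp core (its second cut
## site falls back into the core with probability gamma, computable from
## the length mixture). w_tss is chosen so that the core insertion density
## is tss_multiplier times the background (= flank) density.
component_weights <- function(genome, config) {
  m <- config$mito_fraction
  nuclear <- 1 - m
  p <- config$peak_weight * nuclear
  r <- nuclear - p
  core_bases <- 101 * length(genome$tss)
  L <- sum(genome$contig_sizes[genome$nuclear_contigs])
  pmf <- length_pmf(config)
  gamma <- sum(pmf$p * pmax(0, 1 - pmf$len / 101))
  k <- 2 * (config$tss_multiplier - 1) * core_bases / (L * (1 + gamma))
  w_bg <- r / (1 + k)
  w_tss <- r - w_bg
  c(mito = m, tss = w_tss, peak = p, bg = w_bg)
}

## per-region peak selection probabilities (regions x peaks)
region_peak_weights <- function(n_peaks, n_regions, own_share) {
  sets <- split(seq_len(n_peaks), rep(seq_len(n_regions), length.out = n_peaks))
  W <- matrix((1 - own_share) / n_peaks, n_regions, n_peaks)
  for (r in seq_len(n_regions))
    W[r, sets[[r]]] <- W[r, sets[[r]]] + own_share / length(sets[[r]])
  attr(W, "sets") <- sets
  W
}

draw_lengths <- function(n, config) {
  mode <- sample.int(length(config$len_weights), n, replace = TRUE,
                     prob = config$len_weights)
  len <- round(rnorm(n, config$len_means[mode], config$len_sds[mode]))
  as.integer(pmin(pmax(len, config$len_range[1]), config$len_range[2]))
}

#' Simulate ground-truth fragments for every pixel
#'
#' Per pixel, fragment counts are Poisson at the pixel's depth and each
#' fragment is drawn from a four-component mixture: mitochondrial,
#' TSS-enriched (5' insertion uniform in the TSS +/- 50 bp core), peak
#' (fragment centred in a peak chosen by the pixel's region weights), and
#' uniform background. Lengths come from the two-mode mixture. Coordinates
#' are emitted in fragment-file convention (0-based half-open, Tn5
#' corrected). Identical coordinates drawn twice in one pixel are merged,
#' so the result is the unique ground-truth fragment set.
#'
#' @param genome a [make_genome()] result.
#' @param tissue a [make_tissue()] table.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data.table (`contig`, `start`, `end`, `barcode`, `dup_count = 1`,
#'   plus truth columns `canonical_id`, `region`, `component`, `peak_index`).
#' @export
simulate_fragments <- function(genome, tissue, config = sim_config(), seed = 1L) {
  set.seed(seed)
  n_px <- nrow(tissue)
  counts <- rpois(n_px, tissue$depth)
  counts <- pmax(counts, config$min_per_pixel)
  N <- sum(counts)
  px <- rep(seq_len(n_px), counts)
  w <- component_weights(genome, config)
  comp <- sample(names(w), N, replace = TRUE, prob = w)
  len <- draw_lengths(N, config)
  contig <- character(N); start5 <- integer(N)

  margin <- 10L
  is_mito <- comp == "mito"
  if (any(is_mito)) {
    mlen <- genome$contig_sizes[[genome$mito_contig]]
    contig[is_mito] <- genome$mito_contig
    start5[is_mito] <- as.integer(margin +
      floor(runif(sum(is_mito)) * (mlen - 2L * margin - len[is_mito])))
  }
  is_bg <- comp == "bg"
  if (any(is_bg)) {
    nl <- genome$contig_sizes[genome$nuclear_contigs]
    ct <- sample(genome$nuclear_contigs, sum(is_bg), replace = TRUE,
                 prob = nl / sum(nl))
    contig[is_bg] <- ct
    start5[is_bg] <- as.integer(margin +
      floor(runif(sum(is_bg)) * (nl[ct] - 2L * margin - len[is_bg])))
  }
  is_tss <- comp == "tss"
  if (any(is_tss)) {
    ti <- sample(length(genome$tss), sum(is_tss), replace = TRUE)
    contig[is_tss] <- as.character(GenomicRanges::seqnames(genome$tss))[ti]
    start5[is_tss] <- as.integer(GenomicRanges::start(genome$tss)[ti] - 1L +
                                   sample(-50:50, sum(is_tss), replace = TRUE))
  }
  peak_index <- rep(NA_integer_, N)
  is_pk <- comp == "peak"
  if (any(is_pk)) {
    n_regions <- attr(tissue, "n_regions") %||% max(tissue$region)
    W <- region_peak_weights(length(genome$peaks), n_regions,
                             config$region_own_share)
    which_pk <- integer(sum(is_pk))
    g <- tissue$gradient[px[is_pk]]
    if (attr(tissue, "layout") %||% "bands" == "gradient" && !all(is.na(g))) {
      ## smooth Bernstein interpolation across region peak sets
      deg <- n_regions - 1L
      bern <- sapply(0:deg, function(j) choose(deg, j) * g^j * (1 - g)^(deg - j))
      if (is.null(dim(bern))) bern <- matrix(bern, nrow = 1L)
      Wg <- bern %*% W  # per-fragment peak probabilities
      cum <- Wg %*% upper.tri(diag(ncol(W)), diag = TRUE)
      cum[, ncol(cum)] <- 1  # guard against floating-point shortfall
      u <- runif(sum(is_pk))
      which_pk <- max.col(cum >= u, ties.method = "first")
    } else {
      reg <- tissue$region[px[is_pk]]
      for (r in unique(reg)) {
        sel <- reg == r
        which_pk[sel] <- sample.int(ncol(W), sum(sel), replace = TRUE,
                                    prob = W[r, ])
      }
    }
    peak_index[is_pk] <- which_pk
    pk_start <- GenomicRanges::start(genome$peaks)[which_pk] - 1L
    pk_w <- GenomicRanges::width(genome$peaks)[which_pk]
    center <- pk_start + floor(runif(sum(is_pk)) * pk_w)
    contig[is_pk] <- as.character(GenomicRanges::seqnames(genome$peaks))[which_pk]
    start5[is_pk] <- as.integer(center - len[is_pk] %/% 2L)
  }

  ## clamp inside contig with a margin for Tn5 shifts and read extraction
  clen <- unname(genome$contig_sizes[contig])
  start5 <- pmax(start5, margin)
  endx <- pmin(start5 + len, clen - margin)
  start5 <- pmax(margin, pmin(start5, endx - config$len_range[1]))

  frags <- data.table(contig = contig, start = start5, end = endx,
                      barcode = tissue$barcode[px],
                      canonical_id = tissue$canonical_id[px],
                      region = tissue$region[px],
                      component = comp, peak_index = peak_index)
  ## merge coordinate collisions within a pixel: truth = unique fragments
  frags <- frags[, c(.(dup_count = 1L),
                     lapply(.SD, data.table::first)),
                 by = .(contig, start, end, barcode),
                 .SDcols = c("canonical_id", "region", "component", "peak_index")]
  order_fragments(frags, names(genome$contig_sizes))
}

## canonical fragment-file sort: contig order, start, end, barcode
order_fragments <- function(frags, contig_order = NULL) {
  if (is.null(contig_order)) contig_order <- sort(unique(frags$contig))
  frags[, contig := factor(contig, levels = contig_order)]
  setorder(frags, contig, start, end, barcode)
  frags[, contig := as.character(contig)]
  frags[]
}

extract_seq <- function(genome, contig, start1, end1) {
  out <- character(length(contig))
  for (ct in unique(contig)) {
    sel <- contig == ct
    v <- Biostrings::Views(genome$seqs[[ct]], start = start1[sel], end = end1[sel])
    out[sel] <- as.character(v)
  }
  out
}

#' Turn ground-truth fragments into raw barcoded reads
#'
#' Each unique fragment is expanded into `1 + Geometric(1 - dup_rate)`
#' read pairs. Read 1 is the ligation construct (barcode B, linker 2,
#' barcode A, linker 1, then the genomic insert read from the plus-strand
#' aligned 5' end); read 2 is the reverse-complemented mate read ending at
#' the minus-strand 5' end. Substitution errors are applied to both mates
#' at the configured rate. A per-read truth table and a perfectly aligned
#' SAM (via [truth_align()]) make every downstream stage checkable.
#'
#' @param frags a [simulate_fragments()] table.
#' @param genome the generating [make_genome()] result.
#' @param config a [sim_config()].
#' @param out_dir directory for `reads_R1.fastq.gz`, `reads_R2.fastq.gz`,
#'   `truth_reads.csv` and `truth.sam`.
#' @param layout,wl_a,wl_b read-1 construct definition.
#' @param seed RNG seed.
#' @return (invisibly) list with the output paths and the truth read table.
#' @export
fragments_to_reads <- function(frags, genome, config = sim_config(), out_dir,
                               layout = default_layout(),
                               wl_a = default_whitelist("A"),
                               wl_b = default_whitelist("B"), seed = 1L) {
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- config$tn5_shifts[1]; sm <- config$tn5_shifts[2]
  copies <- 1L + rgeom(nrow(frags), 1 - config$dup_rate)
  idx <- rep(seq_len(nrow(frags)), copies)
  tr <- frags[idx, .(contig, start, end, barcode, canonical_id)]
  tr[, is_duplicate := duplicated(idx)]
  tr[, read_id := sprintf("sr%08d", seq_len(.N))]
  ## aligned coordinates (1-based) undoing the Tn5 correction
  tr[, p1 := start - sp + 1L]
  tr[, p2 := end + sm]
  insert_len <- tr$p2 - tr$p1 + 1L
  tr[, gl1 := pmin(config$read1_genomic, insert_len)]
  tr[, gl2 := pmin(config$read2_len, insert_len)]

  gen1 <- extract_seq(genome, tr$contig, tr$p1, tr$p1 + tr$gl1 - 1L)
  gen2 <- revcomp(extract_seq(genome, tr$contig, tr$p2 - tr$gl2 + 1L, tr$p2))

  pidx <- parse_pixel_id(tr$canonical_id)
  parts <- lapply(seq_len(nrow(layout$segments)), function(i) {
    role <- layout$segments$role[i]
    switch(role,
           barcodeA = wl_a$entries[pidx$a_index],
           barcodeB = wl_b$entries[pidx$b_index],
           linker1 = rep(layout$linker1, nrow(tr)),
           linker2 = rep(layout$linker2, nrow(tr)),
           genomic = gen1)
  })
  r1 <- do.call(paste0, parts)
  r1 <- add_seq_errors(r1, config$error_rate)
  r2 <- add_seq_errors(gen2, config$error_rate)

  f1 <- file.path(out_dir, "reads_R1.fastq.gz")
  f2 <- file.path(out_dir, "reads_R2.fastq.gz")
  write_fastq(r1, strrep("I", nchar(r1)), tr$read_id, f1)
  write_fastq(r2, strrep("I", nchar(r2)), tr$read_id, f2)
  truth_csv <- file.path(out_dir, "truth_reads.csv")
  data.table::fwrite(tr, truth_csv)
  sam <- file.path(out_dir, "truth.sam")
  truth_align(tr, genome$contig_sizes, sam)
  invisible(list(fastq_r1 = f1, fastq_r2 = f2, truth = tr[],
                 truth_csv = truth_csv, sam = sam))
}

#' Emit perfectly aligned SAM records from the read-level truth table
#'
#' Stands in for the external aligner so the fragment-building chain is
#' testable end-to-end: every read pair is written as a proper, primary,
#' MAPQ-60 alignment at its true coordinates, with the pixel barcode in a
#' `CB:Z:` tag. Sequences are stored as `*` (alignment coordinates carry
#' all the information the fragment builder needs).
#'
#' @param truth truth read table from [fragments_to_reads()] (columns
#'   `read_id`, `contig`, `p1`, `p2`, `gl1`, `gl2`, `barcode`).
#' @param contig_sizes named contig length vector for the SAM header.
#' @param path output SAM path.
#' @export
truth_align <- function(truth, contig_sizes, path) {
  truth <- as.data.table(truth)
  need <- c("read_id", "contig", "p1", "p2", "gl1", "gl2", "barcode")
  if (!all(need %in% names(truth)))
    stop("truth table lacks column(s): ",
         paste(setdiff(need, names(truth)), collapse = ", "))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_sizes),
                   as.integer(contig_sizes)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(truth) > 0L) {
    tlen <- truth$p2 - truth$p1 + 1L
    pos2 <- truth$p2 - truth$gl2 + 1L
    l1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*\tCB:Z:%s",
                  truth$read_id, truth$contig, truth$p1, truth$gl1,
                  pos2, tlen, truth$barcode)
    l2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*\tCB:Z:%s",
                  truth$read_id, truth$contig, pos2, truth$gl2,
                  truth$p1, -tlen, truth$barcode)
    writeLines(c(rbind(l1, l2)), con)
  }
  invisible(path)
}

#' Run the full simulator: genome, tissue, fragments, reads
#'
#' Convenience wrapper writing a complete synthetic run (genome files,
#' mask CSV, truth fragments file, FASTQ pair, truth SAM, truth tables)
#' into one directory.
#'
#' @inheritParams simulate_fragments
#' @inheritParams make_tissue
#' @param out_dir output directory.
#' @param genome optional pre-built genome (default [make_genome()] with
#'   the derived seed).
#' @return list with `genome`, `tissue`, `fragments`, and the file paths
#'   from [fragments_to_reads()] plus `fragments_file` and `mask`.
#' @export
simulate_run <- function(out_dir, config = sim_config(),
                         layout = c("bands", "gradient"), n_regions = 3L,
                         ring_width = 0L, genome = NULL, seed = 1L) {
  layout_kind <- match.arg(layout)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(genome)) genome <- make_genome(seed = seed)
  tissue <- make_tissue(config, layout = layout_kind, n_regions = n_regions,
                        ring_width = ring_width, seed = seed + 1L)
  frags <- simulate_fragments(genome, tissue, config, seed = seed + 2L)
  reads <- fragments_to_reads(frags, genome, config, out_dir, seed = seed + 3L)
  write_genome(genome, file.path(out_dir, "genome"))
  mask <- file.path(out_dir, "mask.csv")
  write_mask(tissue, mask)
  ffile <- file.path(out_dir, "truth_fragments.tsv.gz")
  write_fragments(frags[, .(contig, start, end, barcode, dup_count)], ffile,
                  contig_order = names(genome$contig_sizes))
  c(list(genome = genome, tissue = tissue, fragments = frags,
         fragments_file = ffile, mask = mask), reads)
}
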