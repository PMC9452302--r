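#' Read aligned, pixel-tagged read pairs from a SAM/BAM file
#'
#' Wraps Rsamtools/GenomicAlignments: a text SAM is converted to BAM in a
#' temporary file, then alignments are loaded with their reference widths
#' and the pixel barcode tag.
#'
#' @param path SAM (text) or BAM file.
#' @param barcode_tag SAM tag holding the pixel barcode (default `"CB"`).
#' @return data.table with one row per alignment record: `qname`, `flag`,
#'   `contig`, `strand`, `pos` (1-based leftmost), `rwidth` (width along
#'   the reference), `mapq`, `cb`.
#' @export
read_sam_pairs <- function(path, barcode_tag = "CB") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    tag = barcode_tag)
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(aln)
  cb <- md[[barcode_tag]]
  if (is.null(cb)) cb <- rep(NA_character_, length(aln))
  data.table(qname = md$qname, flag = md$flag,
             contig = as.character(GenomicAlignments::seqnames(aln)),
             strand = as.character(GenomicAlignments::strand(aln)),
             pos = GenomicAlignments::start(aln),
             rwidth = GenomicAlignments::width(aln),
             mapq = md$mapq, cb = cb)
}

#' Convert aligned proper pairs into Tn5-corrected fragments
#'
#' For each proper pair the fragment interval is
#' `[plus 5' + shift_plus, minus 5' + 1 - shift_minus)` in 0-based
#' half-open coordinates; the default `(+4, -5)` shifts account for the
#' 9-bp duplication created by Tn5. Pairs are rejected (with a typed
#' reason) when not primary, not a proper pair, below the MAPQ threshold,
#' lacking a barcode, on different contigs, or yielding an empty interval.
#'
#' @param aln alignment table from [read_sam_pairs()].
#' @param shift_plus,shift_minus Tn5 shifts (default 4 and 5).
#' @param mapq_min minimum MAPQ for both mates (default 30).
#' @return list with `fragments` (data.table `contig`, `start`, `end`,
#'   `barcode`, `dup_count = 1`, one row per accepted pair) and `rejected`
#'   (named counts by reason).
#' @export
pair_to_fragments <- function(aln, shift_plus = 4L, shift_minus = 5L,
                              mapq_min = 30L) {
  aln <- as.data.table(aln)
  rejected <- c(secondary = 0L, improper = 0L, unpaired = 0L,
                low_mapq = 0L, no_barcode = 0L, bad_interval = 0L)

  sec <- bitwAnd(aln$flag, 256L) > 0L | bitwAnd(aln$flag, 2048L) > 0L
  rejected["secondary"] <- sum(sec)
  aln <- aln[!sec]
  proper <- bitwAnd(aln$flag, 1L) > 0L & bitwAnd(aln$flag, 2L) > 0L &
    bitwAnd(aln$flag, 4L) == 0L
  rejected["improper"] <- rejected["improper"] + sum(!proper)
  aln <- aln[proper]

  aln[, n_rec := .N, by = qname]
  bad_n <- aln$n_rec != 2L
  rejected["unpaired"] <- sum(bad_n)
  aln <- aln[!bad_n]

  if (nrow(aln) == 0L)
    return(list(fragments = data.table(contig = character(), start = integer(),
                                       end = integer(), barcode = character(),
                                       dup_count = integer()),
                rejected = rejected))
  setorder(aln, qname, strand)  # "+" sorts before "-", mates adjacent
  plus <- aln[seq(1L, .N, 2L)]
  minus <- aln[seq(2L, .N, 2L)]
  ok_pair <- plus$strand == "+" & minus$strand == "-" &
    plus$contig == minus$contig
  rejected["improper"] <- rejected["improper"] + 2L * sum(!ok_pair)
  plus <- plus[ok_pair]; minus <- minus[ok_pair]
  low <- plus$mapq < mapq_min | minus$mapq < mapq_min
  rejected["low_mapq"] <- 2L * sum(low)
  plus <- plus[!low]; minus <- minus[!low]
  nobc <- is.na(plus$cb) | plus$cb == ""
  rejected["no_barcode"] <- 2L * sum(nobc)
  plus <- plus[!nobc]; minus <- minus[!nobc]

  ## 0-based 5' ends
  p5 <- plus$pos - 1L
  m5 <- minus$pos + minus$rwidth - 2L
  start <- p5 + shift_plus
  end <- m5 + 1L - shift_minus
  bad <- start >= end | start < 0L
  rejected["bad_interval"] <- 2L * sum(bad)
  frags <- data.table(contig = plus$contig[!bad], start = start[!bad],
                      end = end[!bad], barcode = plus$cb[!bad],
                      dup_count = 1L)
  list(fragments = frags, rejected = rejected)
}

#' Deduplicate fragments per pixel
#'
#' Collapses records sharing `(contig, start, end, barcode)` into one with
#' `dup_count` equal to the summed multiplicity — identical coordinates in
#' different pixels stay distinct, and the assay has no UMIs so the
#' coordinate+pixel key is the duplicate definition. The total
#' `sum(dup_count)` is conserved, and the operation is idempotent.
#'
#' @param frags data.table with `contig`, `start`, `end`, `barcode` and
#'   optionally `dup_count` (assumed 1 when absent).
#' @param contig_order contig ordering for the output sort (default:
#'   alphabetical over observed contigs).
#' @return sorted deduplicated data.table.
#' @export
deduplicate_fragments <- function(frags, contig_order = NULL) {
  frags <- as.data.table(frags)
  if (nrow(frags) == 0L)
    return(data.table(contig = character(), start = integer(),
                      end = integer(), barcode = character(),
                      dup_count = integer()))
  if (!"dup_count" %in% names(frags)) frags[, dup_count := 1L]
  out <- frags[, .(dup_count = sum(dup_count)),
               by = .(contig, start, end, barcode)]
  order_fragments(out, contig_order)
}

#' Write / read a spatial fragments file
#'
#' The fragments file is the 5-column BED-like TSV of the single-cell ATAC
#' ecosystem: `contig  start  end  barcode  dup_count`, 0-based half-open,
#' sorted by (contig, start, end, barcode), optionally gzip-compressed.
#'
#' @param frags fragment data.table (the five columns above; extra columns
#'   are dropped on write).
#' @param path output path; `.gz` suffix triggers compression.
#' @param contig_order contig ordering used to verify/establish the sort.
#' @param sorted require and verify sorted input (default TRUE; unsorted
#'   input is an error rather than silently re-sorted).
#' @export
write_fragments <- function(frags, path, contig_order = NULL, sorted = TRUE) {
  frags <- as.data.table(frags)
  need <- c("contig", "start", "end", "barcode", "dup_count")
  if (!all(need %in% names(frags)))
    stop("fragment table lacks column(s): ",
         paste(setdiff(need, names(frags)), collapse = ", "))
  out <- frags[, need, with = FALSE]
  if (nrow(out) > 0L) {
    if (any(out$start < 0L) || any(out$end <= out$start))
      stop("invalid fragment interval(s): need 0 <= start < end")
    if (sorted) {
      chk <- order_fragments(copy(out), contig_order)
      if (!identical(chk$start, out$start) || !identical(chk$contig, out$contig) ||
          !identical(chk$end, out$end) || !identical(chk$barcode, out$barcode))
        stop("fragments are not sorted by (contig, start, end, barcode); ",
             "sort (e.g. via deduplicate_fragments) before writing")
    }
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' @rdname write_fragments
#' @return `read_fragments()`: the fragment data.table.
#' @export
read_fragments <- function(path) {
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "r")
      on.exit(close(con), add = TRUE)
      txt <- readLines(con)
      if (length(txt) == 0L) data.table::data.table() else
        data.table::fread(text = txt, sep = "\t", header = FALSE,
                          colClasses = list(character = c(1, 4)))
    } else {
      data.table::fread(path, sep = "\t", header = FALSE,
                        colClasses = list(character = c(1, 4)))
    }
  }, error = function(e) stop("cannot parse fragments file '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L)
    return(data.table(contig = character(), start = integer(),
                      end = integer(), barcode = character(),
                      dup_count = integer()))
  if (ncol(dt) != 5L)
    stop("fragments file must have 5 tab-separated columns, found ", ncol(dt))
  setnames(dt, c("contig", "start", "end", "barcode", "dup_count"))
  if (!is.numeric(dt$start) || !is.numeric(dt$end) || !is.numeric(dt$dup_count))
    stop("non-integer coordinates or counts in fragments file")
  bad <- which(dt$end <= dt$start | dt$start < 0 | dt$dup_count < 1)
  if (length(bad))
    stop("malformed fragment record(s) at line(s): ",
         paste(head(bad, 10L), collapse = ", "))
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  dt[, dup_count := as.integer(dup_count)]
  dt[]
}

#' Per-pixel fragment totals
#' @param frags fragment table.
#' @return data.table `barcode`, `n_fragments` (unique), `n_reads`
#'   (dup_count-weighted).
#' @export
per_pixel_totals <- function(frags) {
  as.data.table(frags)[, .(n_fragments = .N, n_reads = sum(dup_count)),
                       by = barcode]
}
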