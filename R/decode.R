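#' Match the constant linkers of read 1 at their fixed offsets
#'
#' Linkers are matched positionally by Hamming distance only — the ligation
#' chemistry yields fixed-length constructs, so no indel alignment is
#' attempted. `N` counts as a mismatch.
#'
#' @param read1 character vector of read-1 sequences.
#' @param layout a [read_layout()].
#' @param max_linker_mismatch maximum Hamming mismatches tolerated per linker.
#' @return data.table with columns `too_short`, `mm_linker1`, `mm_linker2`,
#'   `pass` (NA mismatch counts for too-short reads).
#' @export
match_linkers <- function(read1, layout, max_linker_mismatch = 3L) {
  stopifnot(inherits(layout, "read_layout"))
  n <- length(read1)
  min_len <- layout$fixed_length + 1L  # at least one genomic base
  too_short <- nchar(read1) < min_len
  mm1 <- mm2 <- rep(NA_integer_, n)
  ok <- !too_short
  if (any(ok)) {
    w1 <- segment_window(layout, "linker1")
    w2 <- segment_window(layout, "linker2")
    mm1[ok] <- hamming_to_ref(substr(read1[ok], w1["start"], w1["end"]), layout$linker1)
    mm2[ok] <- hamming_to_ref(substr(read1[ok], w2["start"], w2["end"]), layout$linker2)
  }
  data.table(too_short = too_short, mm_linker1 = mm1, mm_linker2 = mm2,
             pass = ok & mm1 <= max_linker_mismatch & mm2 <= max_linker_mismatch)
}

#' Error-correct observed barcodes against a whitelist
#'
#' Returns, per observed barcode, the unique whitelist entry within Hamming
#' distance `radius`; `ambiguous` when two or more entries tie at the
#' minimum distance within the radius (never guessed), `unmatched` when no
#' entry is within the radius.
#'
#' @param observed character vector, each of the whitelist's width.
#' @param whitelist a [barcode_whitelist()].
#' @param radius correction radius (Hamming); default 1.
#' @return data.table with `index` (NA unless matched), `distance`,
#'   `status` in `matched`/`ambiguous`/`unmatched`.
#' @export
correct_barcode <- function(observed, whitelist, radius = 1L) {
  stopifnot(inherits(whitelist, "barcode_whitelist"))
  if (length(observed) && any(nchar(observed) != whitelist$width))
    stop("observed barcode length does not match whitelist width ", whitelist$width)
  n <- length(observed)
  idx <- match(observed, whitelist$entries)
  dist <- ifelse(is.na(idx), NA_integer_, 0L)
  status <- ifelse(is.na(idx), NA_character_, "matched")
  todo <- which(is.na(idx))
  if (length(todo)) {
    D <- matrix(0L, length(todo), length(whitelist$entries))
    for (j in seq_along(whitelist$entries))
      D[, j] <- hamming_to_ref(observed[todo], whitelist$entries[j])
    dmin <- apply(D, 1L, min)
    nmin <- rowSums(D == dmin)
    within <- dmin <= radius
    status[todo] <- ifelse(!within, "unmatched",
                           ifelse(nmin > 1L, "ambiguous", "matched"))
    hit <- todo[within & nmin == 1L]
    if (length(hit))
      idx[hit] <- apply(D[within & nmin == 1L, , drop = FALSE], 1L, which.min)
    dist[todo] <- ifelse(within, dmin, NA_integer_)
  }
  idx[status != "matched"] <- NA_integer_
  data.table(index = idx, distance = dist, status = status)
}

#' Decode barcoded read-1 sequences into spatial pixels
#'
#' Vectorised core of the decoder. Each read is classified exactly once:
#' `too_short` (read shorter than the fixed prefix plus one genomic base),
#' `linker_fail` (either linker beyond `max_linker_mismatch`),
#' `barcode_unmatched` (either barcode outside the correction radius),
#' `barcode_ambiguous` (a tied minimum-distance correction), or `assigned`.
#' Unmatched takes precedence over ambiguous when the two barcodes fail
#' differently.
#'
#' @param read1 character vector of raw read-1 sequences.
#' @param layout a [read_layout()].
#' @param wl_a,wl_b barcode whitelists for rounds A and B.
#' @param max_linker_mismatch per-linker Hamming tolerance (default 3).
#' @param bc_radius barcode correction radius (default 1).
#' @return data.table with columns `status`, `a_index`, `b_index`,
#'   `canonical_id`, `barcode` (concatenated A+B sequence), `genomic_seq`,
#'   and per-segment mismatch counts.
#' @export
decode_reads <- function(read1, layout, wl_a, wl_b,
                         max_linker_mismatch = 3L, bc_radius = 1L) {
  n <- length(read1)
  lk <- match_linkers(read1, layout, max_linker_mismatch)
  status <- rep("assigned", n)
  status[!lk$pass] <- "linker_fail"
  status[lk$too_short] <- "too_short"

  a_idx <- b_idx <- rep(NA_integer_, n)
  mm_a <- mm_b <- rep(NA_integer_, n)
  cand <- which(status == "assigned")
  if (length(cand)) {
    wa <- segment_window(layout, "barcodeA")
    wb <- segment_window(layout, "barcodeB")
    ca <- correct_barcode(substr(read1[cand], wa["start"], wa["end"]), wl_a, bc_radius)
    cb <- correct_barcode(substr(read1[cand], wb["start"], wb["end"]), wl_b, bc_radius)
    unmatched <- ca$status == "unmatched" | cb$status == "unmatched"
    ambiguous <- !unmatched & (ca$status == "ambiguous" | cb$status == "ambiguous")
    status[cand[unmatched]] <- "barcode_unmatched"
    status[cand[ambiguous]] <- "barcode_ambiguous"
    okk <- !unmatched & !ambiguous
    a_idx[cand[okk]] <- ca$index[okk]
    b_idx[cand[okk]] <- cb$index[okk]
    mm_a[cand] <- ca$distance
    mm_b[cand] <- cb$distance
  }
  genomic <- substr(read1, layout$fixed_length + 1L, nchar(read1))
  genomic[status != "assigned"] <- NA_character_
  assigned <- status == "assigned"
  canon <- rep(NA_character_, n)
  bc <- rep(NA_character_, n)
  if (any(assigned)) {
    canon[assigned] <- pixel_id(a_idx[assigned], b_idx[assigned],
                                n_a = length(wl_a$entries), n_b = length(wl_b$entries))
    bc[assigned] <- pixel_barcode(a_idx[assigned], b_idx[assigned], wl_a, wl_b)
  }
  data.table(status = status, a_index = a_idx, b_index = b_idx,
             canonical_id = canon, barcode = bc, genomic_seq = genomic,
             mm_linker1 = lk$mm_linker1, mm_linker2 = lk$mm_linker2,
             mm_barcodeA = mm_a, mm_barcodeB = mm_b)
}

read_fastq_pair <- function(r1_path, r2_path) {
  rd <- function(p) {
    out <- tryCatch(
      Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ '", p, "': ", conditionMessage(e),
                               call. = FALSE))
    out
  }
  r1 <- rd(r1_path); r2 <- rd(r2_path)
  if (length(r1) != length(r2))
    stop("read 1 and read 2 FASTQ files have different record counts (",
         length(r1), " vs ", length(r2), ")")
  list(r1 = r1, r2 = r2)
}

write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(quals),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Decode a FASTQ pair end-to-end and write assigned/rejected streams
#'
#' Runs [decode_reads()] over a paired FASTQ run. Assigned reads are written
#' as a new pair: read 1 becomes the genomic portion of the construct with
#' the pixel's 16-base combined barcode appended to the read header as a
#' `CB:Z:` comment; read 2 (the genomic mate) passes through untouched.
#' Rejected reads are written unchanged to a reject pair with their failure
#' status in the header. Every input read appears in exactly one output
#' stream, and status counts sum to the input count.
#'
#' @param r1,r2 input FASTQ paths (plain or gzip).
#' @param out_prefix output prefix; writes `<prefix>_R1.fastq.gz`,
#'   `<prefix>_R2.fastq.gz`, `<prefix>_rejected_R1.fastq.gz`,
#'   `<prefix>_rejected_R2.fastq.gz`, `<prefix>_report.json` and
#'   `<prefix>_pixels.csv`.
#' @inheritParams decode_reads
#' @return (invisibly) the decode report: list with `n_input`, per-status
#'   `counts`, `assigned_fraction`, `n_distinct_pixels`, and per-channel
#'   usage histograms `usage_a`, `usage_b`.
#' @export
decode_run <- function(r1, r2, out_prefix,
                       layout = default_layout(),
                       wl_a = default_whitelist("A"),
                       wl_b = default_whitelist("B"),
                       max_linker_mismatch = 3L, bc_radius = 1L) {
  fq <- read_fastq_pair(r1, r2)
  n <- length(fq$r1)
  seqs1 <- as.character(fq$r1)
  quals1 <- as.character(S4Vectors::mcols(fq$r1)$qualities)
  seqs2 <- as.character(fq$r2)
  quals2 <- as.character(S4Vectors::mcols(fq$r2)$qualities)
  ids1 <- names(fq$r1); ids2 <- names(fq$r2)

  dec <- if (n > 0L)
    decode_reads(seqs1, layout, wl_a, wl_b, max_linker_mismatch, bc_radius)
  else
    decode_reads(character(0), layout, wl_a, wl_b, max_linker_mismatch, bc_radius)

  statuses <- c("assigned", "linker_fail", "barcode_unmatched",
                "barcode_ambiguous", "too_short")
  counts <- vapply(statuses, function(s) sum(dec$status == s), 0L)
  stopifnot(sum(counts) == n)  # conservation

  keep <- which(dec$status == "assigned")
  rej <- which(dec$status != "assigned")
  gen_qual <- substr(quals1, layout$fixed_length + 1L, nchar(quals1))
  write_fastq(dec$genomic_seq[keep], gen_qual[keep],
              sprintf("%s CB:Z:%s", ids1[keep], dec$barcode[keep]),
              paste0(out_prefix, "_R1.fastq.gz"))
  write_fastq(seqs2[keep], quals2[keep],
              sprintf("%s CB:Z:%s", ids2[keep], dec$barcode[keep]),
              paste0(out_prefix, "_R2.fastq.gz"))
  write_fastq(seqs1[rej], quals1[rej],
              sprintf("%s XS:Z:%s", ids1[rej], dec$status[rej]),
              paste0(out_prefix, "_rejected_R1.fastq.gz"))
  write_fastq(seqs2[rej], quals2[rej],
              sprintf("%s XS:Z:%s", ids2[rej], dec$status[rej]),
              paste0(out_prefix, "_rejected_R2.fastq.gz"))

  usage_a <- tabulate(dec$a_index[keep], nbins = length(wl_a$entries))
  usage_b <- tabulate(dec$b_index[keep], nbins = length(wl_b$entries))
  pixels <- unique(dec[keep, c("canonical_id", "a_index", "b_index", "barcode")])
  data.table::fwrite(dec[keep, .N, by = .(canonical_id, a_index, b_index, barcode)],
                     paste0(out_prefix, "_pixels.csv"))
  report <- list(
    n_input = n,
    counts = as.list(counts),
    assigned_fraction = if (n > 0L) unname(counts["assigned"]) / n else 0,
    n_distinct_pixels = nrow(pixels),
    usage_a = usage_a, usage_b = usage_b,
    parameters = list(max_linker_mismatch = max_linker_mismatch,
                      bc_radius = bc_radius)
  )
  jsonlite::write_json(report, paste0(out_prefix, "_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
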