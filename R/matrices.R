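#' Build a pixels x genome-tile insertion-count matrix
#'
#' The genome is partitioned into fixed-width tiles (default 5 kb; the
#' last tile of each contig is truncated). Each fragment contributes two
#' insertion counts — its start and its `end - 1` position — each assigned
#' to the containing tile. The mitochondrial contig is excluded. The
#' counting rule is recorded in the matrix attributes.
#'
#' @param frags deduplicated fragment table.
#' @param contig_sizes named integer vector covering every fragment contig.
#' @param tile_bp tile width (default 5000).
#' @param mito_contig excluded contig (default `"chrM"`).
#' @return sparse `dgCMatrix` (pixels x tiles) with barcode rownames and
#'   `"contig:start-end"` colnames; attributes `tile_bp`, `counting`,
#'   `tile_map` (data.table of tile coordinates).
#' @export
build_tile_matrix <- function(frags, contig_sizes, tile_bp = 5000L,
                              mito_contig = "chrM") {
  frags <- as.data.table(frags)
  contig_sizes <- contig_sizes[names(contig_sizes) != mito_contig]
  frags <- frags[contig != mito_contig]
  unknown <- setdiff(unique(frags$contig), names(contig_sizes))
  if (length(unknown))
    stop("fragments on contig(s) absent from contig_sizes: ",
         paste(unknown, collapse = ", "))
  if (nrow(frags) > 0L &&
      any(frags$end > contig_sizes[frags$contig]))
    stop("fragment(s) extend beyond their contig end")

  n_tiles <- as.integer(ceiling(contig_sizes / tile_bp))
  offset <- setNames(cumsum(c(0L, head(n_tiles, -1L))), names(contig_sizes))
  tile_map <- data.table(
    contig = rep(names(contig_sizes), n_tiles),
    start = unlist(lapply(n_tiles, function(k) (seq_len(k) - 1L) * tile_bp),
                   use.names = FALSE))
  tile_map[, end := pmin(start + tile_bp, contig_sizes[contig])]
  tile_ids <- tile_map[, sprintf("%s:%d-%d", contig, start, end)]

  barcodes <- sort(unique(frags$barcode))
  ins <- fragment_insertions(frags)
  j <- offset[ins$contig] + ins$pos %/% tile_bp + 1L
  i <- match(ins$barcode, barcodes)
  mat <- Matrix::sparseMatrix(i = i, j = unname(j), x = 1,
                              dims = c(length(barcodes), sum(n_tiles)),
                              dimnames = list(barcodes, tile_ids))
  mat <- methods::as(mat, "CsparseMatrix")
  attr(mat, "tile_bp") <- tile_bp
  attr(mat, "counting") <- "insertions (2 per fragment)"
  attr(mat, "tile_map") <- tile_map[]
  mat
}

#' Build a pixels x gene accessibility-score matrix
#'
#' Gene scores use an exponential-decay model: the gene body is extended
#' `upstream_bp` on its 5' side; every Tn5 insertion within `max_dist_bp`
#' of the extended body contributes weight 1 inside the body and
#' `exp(-d / decay_bp)` at distance `d` outside it. Scores are summed per
#' pixel. Optional per-pixel depth normalisation rescales each pixel's
#' scores to sum to `10^4` (off by default so count conservation holds
#' exactly for insertions inside gene bodies).
#'
#' @param frags deduplicated fragment table.
#' @param genes stranded GRanges (or 6-column BED path) of gene bodies,
#'   ideally with names or a `gene_id` column.
#' @param decay_bp exponential decay length (default 5000).
#' @param max_dist_bp maximum distance from the extended body (default 1e5).
#' @param upstream_bp upstream extension (default 5000).
#' @param normalize depth-normalise each pixel to 1e4 (default FALSE).
#' @param mito_contig excluded contig.
#' @return sparse matrix (pixels x genes) with attributes recording the
#'   model parameters.
#' @export
build_gene_scores <- function(frags, genes, decay_bp = 5000, max_dist_bp = 1e5,
                              upstream_bp = 5000, normalize = FALSE,
                              mito_contig = "chrM") {
  genes <- as_bed_granges(genes, "genes")
  gene_ids <- names(genes) %||% genes$gene_id %||%
    sprintf("gene%04d", seq_along(genes))
  frags <- as.data.table(frags)[contig != mito_contig]
  known <- as.character(GenomicRanges::seqnames(genes)) %in% unique(frags$contig)
  if (nrow(frags) > 0L && !all(known)) {
    warning(sum(!known), " gene(s) on contigs absent from the fragments; skipped")
  }
  ins <- fragment_insertions(frags)
  barcodes <- sort(unique(frags$barcode))

  ## 5'-extended body, then distance-weighted window
  ext <- GenomicRanges::resize(genes, GenomicRanges::width(genes) + upstream_bp,
                               fix = "end")  # fix=end extends the start side on "+"
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ext),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(ext)),
                     GenomicRanges::end(ext)),
    strand = GenomicRanges::strand(ext))
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ext),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(ext) - max_dist_bp),
                     GenomicRanges::end(ext) + max_dist_bp))
  mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(barcodes), length(genes)),
                              dimnames = list(barcodes, gene_ids))
  if (nrow(ins) > 0L && length(genes) > 0L) {
    ov <- GenomicRanges::findOverlaps(insertion_granges(ins), win)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    pos1 <- ins$pos[qi] + 1L  # 1-based
    s <- GenomicRanges::start(ext)[si]; e <- GenomicRanges::end(ext)[si]
    d <- pmax(0L, pmax(s - pos1, pos1 - e))
    w <- ifelse(d == 0L, 1, exp(-d / decay_bp))
    mat <- Matrix::sparseMatrix(i = match(ins$barcode[qi], barcodes),
                                j = si, x = w,
                                dims = c(length(barcodes), length(genes)),
                                dimnames = list(barcodes, gene_ids))
  }
  mat <- methods::as(mat, "CsparseMatrix")
  if (normalize) {
    tot <- Matrix::rowSums(mat)
    tot[tot == 0] <- 1
    mat <- Matrix::Diagonal(x = 1e4 / tot) %*% mat
    dimnames(mat) <- list(barcodes, gene_ids)
  }
  attr(mat, "model") <- list(decay_bp = decay_bp, max_dist_bp = max_dist_bp,
                             upstream_bp = upstream_bp, normalize = normalize)
  mat
}

#' Restrict a pixel matrix to on-tissue pixels
#'
#' @param mat pixels x features matrix with pixel-barcode rownames.
#' @param mask mask table (with `barcode` and `on_tissue` columns) or a
#'   character vector of on-tissue pixel barcodes.
#' @return the matrix restricted to on-tissue pixels present in the data;
#'   the number of removed rows is reported via a message and attribute
#'   `n_removed`.
#' @export
apply_mask <- function(mat, mask) {
  if (is.character(mask)) {
    ids <- mask
  } else {
    mask <- as.data.table(mask)
    if (!all(c("barcode", "on_tissue") %in% names(mask)))
      stop("mask must have 'barcode' and 'on_tissue' columns (or be a barcode vector)")
    ids <- mask$barcode[mask$on_tissue %in% TRUE]
  }
  keep <- intersect(rownames(mat), ids)
  if (length(keep) == 0L)
    stop("mask does not intersect the matrix pixels: nothing left after masking")
  removed <- nrow(mat) - length(keep)
  message("apply_mask: removed ", removed, " off-tissue/absent pixel(s), kept ",
          length(keep))
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_removed") <- removed
  out
}

#' Export / import a sparse pixel matrix as MatrixMarket triplets
#'
#' Writes `<prefix>.mtx` plus sidecar files `<prefix>.rows.txt` (pixel
#' barcodes) and `<prefix>.cols.txt` (feature ids); import reverses the
#' round trip losslessly and validates that sidecar lengths match the
#' matrix dimensions.
#'
#' @param mat sparse matrix with dimnames.
#' @param prefix file prefix.
#' @export
export_matrix <- function(mat, prefix) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix must carry pixel rownames and feature colnames")
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"), paste0(prefix, ".mtx"))
  writeLines(rownames(mat), paste0(prefix, ".rows.txt"))
  writeLines(colnames(mat), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' @rdname export_matrix
#' @export
import_matrix <- function(prefix) {
  mtx <- paste0(prefix, ".mtx")
  mat <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("cannot parse '", mtx, "': ",
                                           conditionMessage(e), call. = FALSE))
  rows <- readLines(paste0(prefix, ".rows.txt"))
  cols <- readLines(paste0(prefix, ".cols.txt"))
  if (length(rows) != nrow(mat) || length(cols) != ncol(mat))
    stop("sidecar dimensions (", length(rows), " x ", length(cols),
         ") do not match matrix (", nrow(mat), " x ", ncol(mat), ")")
  dimnames(mat) <- list(rows, cols)
  methods::as(mat, "CsparseMatrix")
}
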