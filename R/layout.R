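#' Read-1 layout of the two-round ligation construct
#'
#' A spatial ATAC-seq read 1 is a fixed-length barcode/linker construct
#' followed by the genomic insert:
#' `[barcodeB][linker2][barcodeA][linker1][genomic]` by default. A layout
#' records the ordered segments with their lengths and the two constant
#' linker sequences, from which the fixed offset of every segment follows.
#'
#' @param segments data.frame with columns `role` and `length`. Roles must
#'   include `linker1`, `linker2`, `barcodeA`, `barcodeB` and exactly one
#'   `genomic` segment, which must come last (its length is `NA`: the rest
#'   of the read).
#' @param linker1,linker2 constant linker sequences (ACGTN alphabet); their
#'   lengths must match the declared segment lengths.
#' @return object of class `read_layout` with per-segment offsets
#'   (`offset`: 0-based start of each segment in read 1) and
#'   `fixed_length`, the total length of the non-genomic prefix.
#' @export
read_layout <- function(segments, linker1, linker2) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("role", "length") %in% names(segments)))
  roles <- as.character(segments$role)
  need <- c("barcodeA", "barcodeB", "linker1", "linker2", "genomic")
  missing_roles <- setdiff(need, roles)
  if (length(missing_roles) > 0L)
    stop("layout is missing segment role(s): ", paste(missing_roles, collapse = ", "))
  if (sum(roles == "genomic") != 1L || roles[length(roles)] != "genomic")
    stop("layout must have exactly one genomic segment and it must be last")
  lens <- as.integer(segments$length)
  if (any(is.na(lens[roles != "genomic"])) || any(lens[roles != "genomic"] <= 0L))
    stop("all non-genomic segment lengths must be positive integers")
  for (lk in c("linker1", "linker2")) {
    seqs <- get(lk)
    if (!grepl("^[ACGTN]+$", seqs))
      stop(lk, " contains characters outside ACGTN")
    if (nchar(seqs) != lens[roles == lk])
      stop(lk, " sequence length (", nchar(seqs), ") does not match declared length (",
           lens[roles == lk], ")")
  }
  fixed <- lens
  fixed[is.na(fixed)] <- 0L
  offsets <- cumsum(c(0L, fixed[-length(fixed)]))
  structure(list(
    segments = data.frame(role = roles, length = lens, offset = offsets,
                          stringsAsFactors = FALSE),
    linker1 = linker1, linker2 = linker2,
    fixed_length = sum(fixed)
  ), class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat("read_layout: fixed prefix", x$fixed_length, "bp\n")
  print(x$segments)
  invisible(x)
}

segment_window <- function(layout, role) {
  i <- match(role, layout$segments$role)
  c(start = layout$segments$offset[i] + 1L,
    end = layout$segments$offset[i] + layout$segments$length[i])
}

#' Load / write a read layout as JSON
#'
#' @param path JSON file with fields `segments` (role, length; genomic
#'   length null) and `linker1`/`linker2`.
#' @return a [read_layout()].
#' @export
load_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$segments) || is.null(obj$linker1) || is.null(obj$linker2))
    stop("layout file must contain 'segments', 'linker1' and 'linker2'")
  read_layout(obj$segments, obj$linker1, obj$linker2)
}

#' @rdname load_layout
#' @param layout a `read_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "read_layout"))
  jsonlite::write_json(list(
    segments = layout$segments[, c("role", "length")],
    linker1 = layout$linker1, linker2 = layout$linker2
  ), path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' Default simulator layout and whitelists
#'
#' The default construct is `[barcodeB 8][linker2 30][barcodeA 30][linker1]
#' [genomic]` with two fixed 30-bp linkers and two 50-entry 8-bp barcode
#' whitelists whose minimum pairwise Hamming distance is 3, so radius-1
#' correction is unambiguous by construction. Real datasets require a
#' user-supplied layout file and whitelists.
#'
#' @return `default_layout()`: a [read_layout()];
#'   `default_whitelist()`: a `barcode_whitelist`.
#' @export
default_layout <- function() {
  load_layout(system.file("extdata", "default_layout.json", package = "spatac"))
}

#' Barcode whitelist for one ligation round
#'
#' @param sequences character vector of equal-length unique DNA barcodes,
#'   in channel order (entry i = channel i).
#' @param round `"A"` or `"B"`.
#' @param correction_radius radius the decoder will use; a warning is
#'   emitted when the minimum pairwise Hamming distance is `<= 2 * radius`,
#'   since correction can then be ambiguous.
#' @return object of class `barcode_whitelist`.
#' @export
barcode_whitelist <- function(sequences, round = c("A", "B"), correction_radius = 1L) {
  round <- match.arg(round)
  sequences <- toupper(as.character(sequences))
  if (anyDuplicated(sequences)) stop("whitelist entries must be unique")
  if (length(unique(nchar(sequences))) != 1L)
    stop("whitelist entries must all have the same length")
  if (!all(grepl("^[ACGT]+$", sequences)))
    stop("whitelist entries must be ACGT strings")
  mind <- min_pairwise_hamming(sequences)
  if (is.finite(mind) && mind <= 2L * correction_radius)
    warning("whitelist ", round, ": minimum pairwise Hamming distance ", mind,
            " <= 2 * correction radius ", correction_radius,
            "; some corrections may be ambiguous")
  structure(list(round = round, entries = sequences,
                 width = nchar(sequences[1L]), min_distance = mind),
            class = "barcode_whitelist")
}

min_pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(Inf)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  mind <- ncol(m)
  for (i in seq_len(n - 1L)) {
    d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    mind <- min(mind, d)
  }
  as.integer(mind)
}

#' Load a whitelist from a 2-column CSV (index, sequence)
#' @param path CSV path.
#' @inheritParams barcode_whitelist
#' @export
load_whitelist <- function(path, round = c("A", "B"), correction_radius = 1L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "sequence") %in% names(df)))
    stop("whitelist CSV must have columns 'index' and 'sequence'")
  df <- df[order(df$index), ]
  if (!identical(as.integer(df$index), seq_len(nrow(df))))
    stop("whitelist indices must be 1..n")
  barcode_whitelist(df$sequence, round = round, correction_radius = correction_radius)
}

#' @rdname default_layout
#' @inheritParams barcode_whitelist
#' @export
default_whitelist <- function(round = c("A", "B")) {
  round <- match.arg(round)
  f <- if (round == "A") "whitelist_a.csv" else "whitelist_b.csv"
  load_whitelist(system.file("extdata", f, package = "spatac"), round = round)
}

#' Canonical pixel identity from grid indices
#'
#' A pixel is the intersection of barcode-A channel `a` and barcode-B
#' channel `b`; its canonical id is the zero-padded string `"A05B07"`.
#' The mapping between `(a, b)`, the canonical id and the concatenated
#' barcode sequence is a bijection.
#'
#' @param a,b integer channel indices (1-based).
#' @param n_a,n_b grid dimensions (only used for validation/padding).
#' @export
pixel_id <- function(a, b, n_a = 50L, n_b = 50L) {
  stopifnot(all(a >= 1L & a <= n_a), all(b >= 1L & b <= n_b))
  wa <- max(2L, nchar(as.character(n_a)))
  wb <- max(2L, nchar(as.character(n_b)))
  sprintf("A%0*dB%0*d", wa, a, wb, b)
}

#' Parse canonical pixel ids back to grid indices
#' @param id character vector of ids such as `"A05B07"`.
#' @return data.frame with columns `a_index`, `b_index`.
#' @export
parse_pixel_id <- function(id) {
  m <- regmatches(id, regexec("^A([0-9]+)B([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed pixel id(s): ", paste(head(id[bad]), collapse = ", "))
  data.frame(a_index = as.integer(vapply(m, `[`, "", 2L)),
             b_index = as.integer(vapply(m, `[`, "", 3L)))
}

#' Combined barcode sequence for a pixel
#'
#' The 16-base (by default) concatenation `barcodeA + barcodeB` used as the
#' cell-barcode field in decoded output and fragment files.
#' @param a,b channel indices.
#' @param wl_a,wl_b whitelists.
#' @export
pixel_barcode <- function(a, b, wl_a, wl_b) {
  paste0(wl_a$entries[a], wl_b$entries[b])
}
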