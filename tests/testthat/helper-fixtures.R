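## shared fixtures, built once per test run
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, force(expr), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

small_genome <- function() fixture("genome", make_genome(
  contig_lengths = c(chr1 = 200000L, chr2 = 200000L),
  mito_length = 16000L, n_peaks = 30L, peak_width = 400L,
  n_genes = 12L, seed = 42L))

small_config <- function(...)
  do.call(sim_config, utils::modifyList(list(n_a = 8L, n_b = 8L, depth = 50),
                                        list(...)))

## a complete small simulated run shared across decoder/fragment tests
small_run <- function() fixture("run", {
  dir <- file.path(tempdir(), "spatac-small-run")
  simulate_run(dir, config = small_config(error_rate = 0.01),
               genome = small_genome(), seed = 11L)
})

## adjusted Rand index against ground truth (mclust as independent oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## ---- independent brute-force decoder oracle --------------------------------
## per-read reimplementation from the written contract, used to cross-check
## the vectorised decoder; deliberately naive (character loops)
oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  sum(va != vb | va == "N")
}

oracle_correct <- function(obs, entries, radius) {
  d <- vapply(entries, function(e) oracle_hamming(obs, e), numeric(1))
  dmin <- min(d)
  if (dmin > radius) return("unmatched")
  if (sum(d == dmin) > 1L) return("ambiguous")
  "matched"
}

oracle_decode_status <- function(read1, layout, wl_a, wl_b, max_mm, radius) {
  segs <- layout$segments
  if (nchar(read1) < layout$fixed_length + 1L) return("too_short")
  win <- function(role) {
    i <- match(role, segs$role)
    substr(read1, segs$offset[i] + 1L, segs$offset[i] + segs$length[i])
  }
  if (oracle_hamming(win("linker1"), layout$linker1) > max_mm ||
      oracle_hamming(win("linker2"), layout$linker2) > max_mm)
    return("linker_fail")
  sa <- oracle_correct(win("barcodeA"), wl_a$entries, radius)
  sb <- oracle_correct(win("barcodeB"), wl_b$entries, radius)
  if (sa == "unmatched" || sb == "unmatched") return("barcode_unmatched")
  if (sa == "ambiguous" || sb == "ambiguous") return("barcode_ambiguous")
  "assigned"
}

## build an error-free read-1 string for a pixel
construct_read1 <- function(a, b, layout, wl_a, wl_b, genomic = "ACGTACGTAC") {
  parts <- vapply(seq_len(nrow(layout$segments)), function(i) {
    switch(layout$segments$role[i],
           barcodeA = wl_a$entries[a], barcodeB = wl_b$entries[b],
           linker1 = layout$linker1, linker2 = layout$linker2,
           genomic = genomic)
  }, "")
  paste(parts, collapse = "")
}

## mutate specific positions of a string to a different base
mutate_at <- function(seq, positions) {
  for (p in positions) {
    cur <- substr(seq, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), cur)[1]
    substr(seq, p, p) <- alt
  }
  seq
}
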