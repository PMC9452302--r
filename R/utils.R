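#' Hamming mismatch count against a fixed reference string
#'
#' Vectorised over `x`; every `x[i]` must have `nchar(ref)` characters.
#' Any `N` in the query counts as a mismatch regardless of the reference
#' base, so low-confidence calls can never rescue a match.
#'
#' @param x character vector of equal-length strings.
#' @param ref single reference string.
#' @return integer vector of mismatch counts.
#' @keywords internal
hamming_to_ref <- function(x, ref) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  mm <- integer(length(x))
  for (i in seq_along(rc)) {
    ch <- substr(x, i, i)
    mm <- mm + ((ch != rc[i]) | (ch == "N"))
  }
  mm
}

#' Random DNA strings (A/C/G/T)
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Apply substitution errors to a character vector of sequences
#'
#' Each base independently mutates to one of the three other bases with
#' probability `rate`. Implemented by flattening all sequences into one
#' integer vector, drawing the global error count from the matching
#' binomial, and substituting at uniformly sampled positions — exactly
#' equivalent to per-base Bernoulli draws but vectorised.
#'
#' @keywords internal
add_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  widths <- nchar(seqs)
  total <- sum(widths)
  if (total == 0L) return(seqs)
  flat <- utf8ToInt(paste(seqs, collapse = ""))
  n_err <- rbinom(1L, total, rate)
  if (n_err > 0L) {
    pos <- sample.int(total, n_err)
    bases <- utf8ToInt("ACGT")
    cur <- flat[pos]
    ## draw a base uniformly from the three alternatives
    repl <- bases[(match(cur, bases) - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L + 1L]
    repl[is.na(repl)] <- bases[sample.int(4L, sum(is.na(repl)), replace = TRUE)]
    flat[pos] <- repl
  }
  big <- intToUtf8(flat)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  substring(big, starts, ends)
}

#' Reverse-complement a character vector of DNA sequences
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Rolling mean with shrinking windows at the edges
#' @keywords internal
roll_mean_partial <- function(x, window = 3L) {
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)], na.rm = TRUE)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
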