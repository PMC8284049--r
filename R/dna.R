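#' DNA string helpers
#'
#' Plain-character DNA utilities. Sequences are uppercase strings over
#' {A,C,G,T,N}; coordinates throughout the package are 0-based, half-open,
#' on the top strand, and circular molecules are indexed modulo length.
#' Strand arithmetic is delegated to Biostrings.
#'
#' @name dna-utils
#' @keywords internal
NULL

DNA_ALPHABET_RE <- "^[ACGTN]*$"

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    gb_abort("sequence_error", sprintf("%s must be a single DNA string", what))
  }
  x <- toupper(x)
  if (!grepl(DNA_ALPHABET_RE, x)) {
    gb_abort("sequence_error",
             sprintf("%s contains letters outside A/C/G/T/N", what))
  }
  x
}

#' Reverse complement of a DNA string
#'
#' @param x a DNA string (character scalar).
#' @return the reverse complement, as a character scalar.
#' @export
#' @examples
#' revcomp("GGTCTC")
revcomp <- function(x) {
  x <- check_dna(x)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## All start positions (0-based) of fixed pattern `pat` in `subject`,
## including overlapping occurrences (zero-width lookahead). For circular
## subjects the scan wraps across the origin; matches are reported modulo
## length and deduplicated.
str_find_all <- function(subject, pat, circular = FALSE) {
  n <- nchar(subject)
  k <- nchar(pat)
  if (n < k) return(integer(0))
  scan_in <- if (circular && n >= k) {
    paste0(subject, substr(subject, 1L, k - 1L))
  } else {
    subject
  }
  m <- gregexpr(paste0("(?=", pat, ")"), scan_in, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  starts <- as.integer(m) - 1L   # to 0-based
  starts <- starts[starts < n]
  sort(unique(starts %% n))
}

## substring by 0-based half-open interval, wrapping when circular
seq_slice <- function(seq, start, end, circular = FALSE) {
  n <- nchar(seq)
  if (!circular) {
    stopifnot(start >= 0L, end <= n, start <= end)
    return(substr(seq, start + 1L, end))
  }
  start <- start %% n
  span <- end - start
  if (span < 0L) gb_abort("sequence_error", "negative slice span")
  if (start + span <= n) {
    substr(seq, start + 1L, start + span)
  } else {
    paste0(substr(seq, start + 1L, n), seq_slice(paste0(seq, seq), n, start + span) )
  }
}

## rotate a circular sequence so that 0-based position `at` becomes position 0
seq_rotate <- function(seq, at) {
  n <- nchar(seq)
  at <- at %% n
  if (at == 0L) return(seq)
  paste0(substr(seq, at + 1L, n), substr(seq, 1L, at))
}

## lexicographically minimal rotation; canonical form for comparing circles
canonical_rotation <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(seq)
  rots <- vapply(seq_len(n) - 1L, function(i) seq_rotate(seq, i), character(1))
  sort(rots)[1L]
}
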