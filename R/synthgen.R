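#' Synthetic spacer and target inputs
#'
#' Deterministic generators so that every design pipeline is testable and
#' demonstrable offline: uniform random spacers free of BsaI/BsmBI
#' recognitions (also in the junction context the cloning flanks will
#' create), and toy target loci that embed each protospacer next to its
#' PAM (NGG 3' for Cas9, TTTV 5' for Cas12a).
#'
#' @name synthgen
NULL

#' Construct (and validate) a spacer input
#'
#' Cas9 spacers are exactly 20 nt; Cas12a spacers 20-23 nt. No recognition
#' site of BsaI or BsmBI may occur on either strand: the spacer must
#' survive one BsmBI and one BsaI reaction.
#'
#' @param sequence spacer DNA (5'->3', the protospacer strand).
#' @param nuclease `"Cas9"` or `"Cas12a"`.
#' @param name spacer name.
#' @param grammar a `gb_grammar`.
#' @return a `gb_spacer`.
#' @export
spacer_input <- function(sequence, nuclease = c("Cas9", "Cas12a"),
                         name = "spacer", grammar = default_grammar()) {
  nuclease <- match.arg(nuclease)
  sequence <- check_dna(sequence, "spacer")
  n <- nchar(sequence)
  if (nuclease == "Cas9" && n != 20L) {
    gb_abort("spacer_length_error",
             sprintf("Cas9 spacer '%s' is %d nt; exactly 20 nt required", name, n))
  }
  if (nuclease == "Cas12a" && (n < 20L || n > 23L)) {
    gb_abort("spacer_length_error",
             sprintf("Cas12a spacer '%s' is %d nt; 20-23 nt required", name, n))
  }
  hits <- scan_forbidden_sites(sequence, grammar)
  if (nrow(hits)) {
    gb_abort("forbidden_site_error",
             sprintf("spacer '%s' contains a %s recognition (%s) at offset %d",
                     name, hits$enzyme[1], hits$pattern[1], hits$offset[1]),
             hits = hits)
  }
  structure(list(name = name, nuclease = nuclease, sequence = sequence),
            class = "gb_spacer")
}

as_spacer <- function(x, nuclease, name = NULL, grammar = default_grammar()) {
  if (inherits(x, "gb_spacer")) {
    if (!identical(x$nuclease, nuclease)) {
      gb_abort("spacer_length_error",
               sprintf("spacer '%s' was declared for %s, not %s", x$name, x$nuclease, nuclease))
    }
    return(x)
  }
  spacer_input(x, nuclease, name %||% "spacer", grammar)
}

## Would this spacer create a Type IIS recognition across the junctions the
## cloning flanks generate? Checked in every context the spacer can occupy.
spacer_context_clean <- function(sequence, nuclease, grammar = default_grammar()) {
  s <- grammar$sites
  el <- registry_element_seqs(grammar)
  ctx <- if (nuclease == "Cas9") {
    c(paste0(s[["PROM_GUIDE"]], sequence, s[["GUIDE_SCAFFOLD"]]),
      paste0(s[["TRNA_SPACER"]], sequence, s[["GUIDE_SCAFFOLD"]]))
  } else {
    c(paste0(s[["DR_SPACER"]], sequence, s[["SPACER_HDV"]]),
      paste0(s[["DR_SPACER"]], sequence, substr(el$dr, 1L, 4L)))
  }
  all(vapply(ctx, function(x) nrow(scan_forbidden_sites(x, grammar)) == 0L, logical(1)))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Draw random valid spacers
#'
#' Uniform random sequences, rejected and resampled until free of
#' BsaI/BsmBI recognitions on both strands (including the junction context
#' of the cloning overhangs); reproducible per seed, with no float state.
#'
#' @param n number of spacers.
#' @param nuclease `"Cas9"` or `"Cas12a"`.
#' @param seed integer seed.
#' @param length spacer length; defaults to 20 (Cas9) / 23 (Cas12a).
#' @param prefix name prefix.
#' @param grammar a `gb_grammar`.
#' @return a list of `gb_spacer` (for [random_spacer()], a single one).
#' @export
random_spacers <- function(n, nuclease = c("Cas9", "Cas12a"), seed = 1L,
                           length = NULL, prefix = "sp",
                           grammar = default_grammar()) {
  nuclease <- match.arg(nuclease)
  len <- as.integer(length %||% if (nuclease == "Cas9") 20L else 23L)
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
        ok <- nrow(scan_forbidden_sites(cand, grammar)) == 0L &&
          spacer_context_clean(cand, nuclease, grammar)
        if (ok) break
      }
      out[[i]] <- spacer_input(cand, nuclease, sprintf("%s%d", prefix, i), grammar)
    }
    out
  })
}

#' @rdname random_spacers
#' @export
random_spacer <- function(nuclease = c("Cas9", "Cas12a"), seed = 1L,
                          length = NULL, grammar = default_grammar()) {
  random_spacers(1L, nuclease, seed, length, grammar = grammar)[[1]]
}

#' Raw site-free random DNA of arbitrary length
#'
#' Like [random_spacers()] but without length validation: plain strings,
#' free of BsaI/BsmBI recognitions on both strands and in every junction
#' context the cloning flanks can create. Used to probe validators with
#' off-length inputs.
#'
#' @param length sequence length.
#' @param seed integer seed.
#' @param n how many.
#' @param grammar a `gb_grammar`.
#' @return character vector of length `n`.
#' @export
random_sitefree_dna <- function(length, seed = 1L, n = 1L,
                                grammar = default_grammar()) {
  with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      repeat {
        cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                      collapse = "")
        if (nrow(scan_forbidden_sites(cand, grammar)) == 0L &&
            spacer_context_clean(cand, "Cas9", grammar) &&
            spacer_context_clean(cand, "Cas12a", grammar)) break
      }
      out[i] <- cand
    }
    out
  })
}

#' Build a toy target locus embedding protospacers with PAMs
#'
#' A synthetic "gene" for documentation and demos of the target/spacer
#' orientation: each protospacer is embedded in random sequence, followed
#' by an NGG PAM (Cas9) or preceded by a TTTV PAM (Cas12a); with
#' `reverse = TRUE` the protospacer-PAM unit is placed on the reverse
#' strand (appears as its reverse complement).
#'
#' @param spacers list of `gb_spacer` (one nuclease).
#' @param seed integer seed.
#' @param reverse logical, recycled over spacers.
#' @param flank random flank length between protospacers.
#' @return a linear `gb_part` with `protospacer` and `PAM` features.
#' @export
toy_target_locus <- function(spacers, seed = 1L, reverse = FALSE, flank = 30L) {
  if (inherits(spacers, "gb_spacer")) spacers <- list(spacers)
  if (!length(spacers)) gb_abort("empty_input_error", "need at least one spacer")
  reverse <- rep_len(reverse, length(spacers))
  nuc <- spacers[[1]]$nuclease
  with_seed(seed, {
    seq <- ""
    feats <- empty_features()
    rand <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    for (i in seq_along(spacers)) {
      sp <- spacers[[i]]
      seq <- paste0(seq, rand(flank))
      pam <- if (nuc == "Cas9") paste0(sample(c("A", "C", "G", "T"), 1), "GG")
             else paste0("TTT", sample(c("A", "C", "G"), 1))
      unit <- if (nuc == "Cas9") paste0(sp$sequence, pam) else paste0(pam, sp$sequence)
      sp_off <- if (nuc == "Cas9") 0L else nchar(pam)
      pam_off <- if (nuc == "Cas9") nchar(sp$sequence) else 0L
      if (reverse[i]) {
        u0 <- nchar(seq)
        unit_rc <- revcomp(unit)
        feats <- rbind(feats,
          gb_feature(sp$name, "protospacer",
                     u0 + nchar(unit) - sp_off - nchar(sp$sequence),
                     u0 + nchar(unit) - sp_off, "-"),
          gb_feature(paste0(sp$name, "_PAM"), "PAM",
                     u0 + nchar(unit) - pam_off - nchar(pam),
                     u0 + nchar(unit) - pam_off, "-"))
        seq <- paste0(seq, unit_rc)
      } else {
        u0 <- nchar(seq)
        feats <- rbind(feats,
          gb_feature(sp$name, "protospacer", u0 + sp_off,
                     u0 + sp_off + nchar(sp$sequence), "+"),
          gb_feature(paste0(sp$name, "_PAM"), "PAM", u0 + pam_off,
                     u0 + pam_off + nchar(pam), "+"))
        seq <- paste0(seq, unit)
      }
    }
    seq <- paste0(seq, rand(flank))
    part_record("toy_target_locus", seq, "linear", features = feats)
  })
}

#' Write a FASTA file for a part record
#' @param part a `gb_part`.
#' @param path output path.
#' @export
write_fasta <- function(part, path) {
  n <- nchar(part$sequence)
  starts <- seq(1L, n, by = 70L)
  writeLines(c(paste0(">", part$id),
               substring(part$sequence, starts, pmin(starts + 69L, n))), path)
  invisible(path)
}

#' Read spacers from a CSV (name,sequence) or FASTA file
#' @param path input file.
#' @param nuclease `"Cas9"` or `"Cas12a"`.
#' @param grammar a `gb_grammar`.
#' @return list of `gb_spacer`.
#' @export
read_spacers <- function(path, nuclease = c("Cas9", "Cas12a"),
                         grammar = default_grammar()) {
  nuclease <- match.arg(nuclease)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) gb_abort("empty_input_error", "no spacers in input file")
  if (startsWith(lines[1], ">")) {
    idx <- grep("^>", lines)
    names <- sub("^>\\s*", "", lines[idx])
    seqs <- vapply(seq_along(idx), function(i) {
      to <- if (i < length(idx)) idx[i + 1] - 1L else length(lines)
      paste(lines[(idx[i] + 1L):to], collapse = "")
    }, character(1))
  } else {
    df <- utils::read.csv(textConnection(lines), stringsAsFactors = FALSE,
                          header = grepl("name", lines[1], ignore.case = TRUE))
    if (ncol(df) < 2L) gb_abort("format_error", "spacer CSV needs name,sequence columns")
    names <- as.character(df[[1]]); seqs <- as.character(df[[2]])
  }
  Map(function(nm, sq) spacer_input(sq, nuclease, nm, grammar), names, seqs)
}
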