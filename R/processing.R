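#' In-planta transcript processing and editing-efficiency calls
#'
#' The repository's ground-truth oracle for scarlessness: simulates what
#' the plant cell does to a guide transcript. Pol III transcription starts
#' at the annotated promoter 3' end and stops at the poly-T terminator;
#' endogenous RNase P / RNase Z excise the tRNAs flanking each
#' spacer-scaffold unit of a Cas9 polycistron; Cas12a self-processes its
#' transcript at each direct repeat; and the HDV ribozyme cleaves at its
#' own 5' boundary, trimming everything 3' of the last spacer nucleotide.
#' Cleavage boundaries are annotation-driven (they are known exactly at
#' design time); the RNA chemistry itself is out of scope.
#'
#' Editing-efficiency estimates from sequencing deconvolution are binned
#' into genotype categories at the 20/40/60/80 percent boundaries.
#'
#' @name processing
NULL

#' Simulate transcript processing of a guide TU
#'
#' For every Pol III cassette (promoter ... terminator) in the record,
#' cuts the transcript at the annotated processing boundaries and returns
#' the mature guides:
#' * Cas9 mode (tRNA or scaffold features present): cut at tRNA
#'   boundaries; each mature guide is spacer + scaffold. A single-guide
#'   TU (no tRNA) yields the whole transcript as one guide.
#' * Cas12a mode (DR features present): cut at each DR 5' boundary; each
#'   mature crRNA is DR + spacer; a segment carrying no spacer (the
#'   leader DR of an array) is consumed; HDV removes everything 3' of its
#'   own 5' boundary, exposing the last nucleotide of the spacer.
#'
#' Mature sequences are reported in DNA letters (top strand of the TU).
#'
#' @param guide_TU an annotated `gb_part` (a Level 1 guide TU or any
#'   construct containing such cassettes).
#' @param grammar a `gb_grammar`.
#' @return a `gb_mature_guides` data.frame with columns `cassette`,
#'   `unit`, `spacer`, `sequence`, and attribute `nuclease`.
#' @export
process_transcript <- function(guide_TU, grammar = default_grammar()) {
  f <- guide_TU$features
  proms <- features_of(guide_TU, "promoter")
  terms <- features_of(guide_TU, "terminator")
  if (nrow(proms) == 0L) {
    gb_abort("annotation_error",
             sprintf("%s has no promoter feature; cannot locate a transcript", guide_TU$id))
  }
  within <- function(df, lo, hi) df[df$start >= lo & df$end <= hi, , drop = FALSE]
  out <- NULL
  nuclease <- NA_character_
  for (ci in seq_len(nrow(proms))) {
    tss <- proms$end[ci]
    tend_cands <- terms$start[terms$start >= tss]
    if (!length(tend_cands)) next
    tend <- min(tend_cands)
    trnas <- within(features_of(guide_TU, "tRNA"), tss, tend)
    drs <- within(features_of(guide_TU, "DR"), tss, tend)
    spacers <- within(features_of(guide_TU, "spacer"), tss, tend)
    hdvs <- within(features_of(guide_TU, "HDV"), tss, tend)
    if (nrow(spacers) == 0L) {
      gb_abort("annotation_error",
               sprintf("%s: transcript at %d-%d has no annotated guide units",
                       guide_TU$id, tss, tend))
    }
    segs <- if (nrow(drs)) {
      nuclease <- "Cas12a"
      ## self-processing: cut at each DR 5' boundary
      cuts <- sort(drs$start)
      data.frame(from = cuts, to = c(cuts[-1], if (nrow(hdvs)) min(hdvs$start) else tend))
    } else {
      nuclease <- "Cas9"
      if (nrow(trnas) == 0L) {
        data.frame(from = tss, to = if (nrow(hdvs)) min(hdvs$start) else tend)
      } else {
        ## RNase P / RNase Z excise each tRNA
        bounds <- trnas[order(trnas$start), ]
        data.frame(from = c(tss, bounds$end), to = c(bounds$start, tend))
      }
    }
    unit <- 0L
    for (si in seq_len(nrow(segs))) {
      from <- segs$from[si]; to <- segs$to[si]
      if (to <= from) next
      sp_in <- spacers[spacers$start >= from & spacers$end <= to, , drop = FALSE]
      if (nrow(sp_in) == 0L) next   # spacer-less leader segment: consumed
      unit <- unit + 1L
      out <- rbind(out, data.frame(
        cassette = ci, unit = unit, spacer = sp_in$label[1],
        sequence = substr(guide_TU$sequence, from + 1L, to),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    gb_abort("annotation_error",
             sprintf("%s contains no processable guide cassette", guide_TU$id))
  }
  structure(out, class = c("gb_mature_guides", "data.frame"), nuclease = nuclease)
}

#' Describe the guides an array is planned to encode
#'
#' @param spacers list of `gb_spacer`.
#' @param nuclease `"Cas9"` or `"Cas12a"`.
#' @param scaffold_kind Cas9 scaffold variant.
#' @param grammar a `gb_grammar`.
#' @return a `gb_array_plan` with the expected mature sequence per unit.
#' @export
array_plan <- function(spacers, nuclease = c("Cas9", "Cas12a"),
                       scaffold_kind = c("standard", "aptamer"),
                       grammar = default_grammar()) {
  nuclease <- match.arg(nuclease); scaffold_kind <- match.arg(scaffold_kind)
  if (inherits(spacers, "gb_spacer")) spacers <- list(spacers)
  el <- registry_element_seqs(grammar)
  expected <- vapply(spacers, function(sp) {
    if (nuclease == "Cas9") {
      paste0(sp$sequence, if (scaffold_kind == "aptamer") el$aptamer_scaffold else el$scaffold)
    } else {
      paste0(el$dr, sp$sequence)
    }
  }, character(1))
  structure(list(nuclease = nuclease, scaffold_kind = scaffold_kind,
                 spacers = spacers,
                 expected = data.frame(unit = seq_along(spacers),
                                       spacer = vapply(spacers, `[[`, character(1), "name"),
                                       sequence = expected, stringsAsFactors = FALSE)),
            class = "gb_array_plan")
}

#' Verify scarless maturation against the design plan
#'
#' Passes iff the processed guide count, order, and sequences (exact
#' spacer + scaffold for Cas9, DR + spacer for Cas12a) all match the plan.
#'
#' @param plan a `gb_array_plan` (e.g. `attr(tu, "plan")` from
#'   [design_cas9_array()]).
#' @param guides a `gb_mature_guides` from [process_transcript()].
#' @return a `gb_scarless_report`: list with `pass` (logical) and
#'   `failures` (data.frame naming unit index and failure kind).
#' @export
verify_scarless <- function(plan, guides) {
  failures <- data.frame(unit = integer(0), kind = character(0),
                         detail = character(0), stringsAsFactors = FALSE)
  exp <- plan$expected
  if (nrow(guides) != nrow(exp)) {
    failures <- rbind(failures, data.frame(
      unit = NA_integer_, kind = "count",
      detail = sprintf("expected %d mature guides, got %d", nrow(exp), nrow(guides))))
  } else {
    for (i in seq_len(nrow(exp))) {
      if (!identical(guides$spacer[i], exp$spacer[i])) {
        failures <- rbind(failures, data.frame(
          unit = i, kind = "order",
          detail = sprintf("unit %d carries spacer '%s', planned '%s'",
                           i, guides$spacer[i], exp$spacer[i])))
      } else if (!identical(guides$sequence[i], exp$sequence[i])) {
        failures <- rbind(failures, data.frame(
          unit = i, kind = "sequence",
          detail = sprintf("unit %d mature sequence differs from plan (scar?)", i)))
      }
    }
  }
  structure(list(pass = nrow(failures) == 0L, failures = failures),
            class = "gb_scarless_report")
}

#' @export
print.gb_scarless_report <- function(x, ...) {
  cat(if (x$pass) "scarless: PASS\n" else "scarless: FAIL\n")
  if (nrow(x$failures)) print(x$failures)
  invisible(x)
}

EDIT_CATEGORIES <- c("negative", "chimeric_one_allele", "heterozygous",
                     "chimeric_both_alleles", "biallelic")

#' Classify editing-efficiency estimates into genotype categories
#'
#' Estimates (percent edited reads from chromatogram deconvolution of a
#' diploid T0 plant) are binned: at or below 20 percent negative; above 20
#' up to 40 chimeric affecting one allele; above 40 up to 60 presumed
#' heterozygous; above 60 up to 80 chimeric affecting both alleles; above
#' 80 regarded as biallelic. Boundary values fall in the lower bin
#' (right-closed intervals).
#'
#' @param estimate numeric vector of percentages in `[0, 100]`.
#' @return a `gb_edit_call` data.frame with columns `estimate`,
#'   `category`.
#' @export
#' @examples
#' classify_edit_estimate(c(15, 35, 50, 70, 85))
classify_edit_estimate <- function(estimate) {
  if (!is.numeric(estimate) || any(is.na(estimate)) ||
      any(estimate < 0 | estimate > 100)) {
    gb_abort("value_range_error", "estimates must be percentages in [0, 100]")
  }
  idx <- findInterval(estimate, c(20, 40, 60, 80), left.open = FALSE) + 1L
  ## findInterval with these breaks puts a boundary value in the upper bin;
  ## shift exact boundaries down to keep intervals right-closed
  at_boundary <- estimate %in% c(20, 40, 60, 80)
  idx[at_boundary] <- idx[at_boundary] - 1L
  structure(data.frame(estimate = estimate, category = EDIT_CATEGORIES[idx],
                       stringsAsFactors = FALSE),
            class = c("gb_edit_call", "data.frame"))
}

#' Aggregate per-guide estimates into one gene-level call
#'
#' When several guides target the same gene, the gene call is taken from
#' the maximum estimate. With `conservative = TRUE`, the rule used when
#' two or more guides each show about 50 percent editing (it cannot be
#' resolved whether one or both alleles are hit) applies: the gene is
#' assumed heterozygous rather than biallelic.
#'
#' @param estimates numeric vector of per-guide estimates for one gene.
#' @param conservative apply the conservative heterozygous assumption.
#' @return one-row `gb_edit_call`.
#' @export
classify_gene_edits <- function(estimates, conservative = FALSE) {
  call <- classify_edit_estimate(max(estimates))
  if (conservative && sum(estimates > 40 & estimates <= 60) >= 2L &&
      call$category %in% c("chimeric_both_alleles", "biallelic")) {
    call$category <- "heterozygous"
  }
  call
}
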