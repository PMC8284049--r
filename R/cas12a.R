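#' Cas12a crRNA design tools
#'
#' Cas12a guides put the constant element (the direct repeat, DR) at the
#' 5' end and the spacer at the 3' end, and Cas12a self-processes
#' polycistronic transcripts at its DRs, so no tRNA spacers are needed.
#' The single-crRNA tools mirror the Cas9 pair: a 20-23-nt spacer becomes
#' an annealed oligo duplex, assembled with the upstream constant element
#' (Pol III promoter + first DR) and the HDV ribozyme that trims the 3'
#' end to expose the last nucleotide of the spacer. The multiplex tool
#' designs a synthesis-ready DNA fragment -- a tandem of DR-spacer units
#' terminated by the HDV ribozyme, flanked by BsmBI cassettes -- which is
#' cloned as a Level 0 part and then combined with the same upstream
#' element into the Level 1 polycistronic crRNA TU.
#'
#' @name cas12a_design
NULL

#' Design oligos for a single Cas12a crRNA (domesticator)
#'
#' @param spacer a 20-23-nt DNA string or `gb_spacer` (Cas12a).
#' @param name spacer name.
#' @param grammar a `gb_grammar`.
#' @return a `gb_oligo_pair` whose double-stranded core is exactly the
#'   spacer, with the DR-spacer and spacer-HDV fusion sites as
#'   protrusions.
#' @export
design_single_cas12a_oligos <- function(spacer, name = "crRNA1",
                                        grammar = default_grammar()) {
  sp <- as_spacer(spacer, "Cas12a", name, grammar)
  design_guide_oligos(sp, "DR_SPACER", "SPACER_HDV", "_cr", grammar)
}

#' Assemble a single Cas12a crRNA transcriptional unit (assembler)
#'
#' BsaI restriction-ligation of the annealed oligos with the upstream
#' constant element (Pol III promoter + first crRNA DR) and the HDV
#' ribozyme into an alpha-class destination: a Level 1 TU ordered
#' promoter+DR, spacer, HDV (5'->3').
#'
#' @param oligos `gb_oligo_pair` from [design_single_cas12a_oligos()].
#' @param upstream_id registry id of the promoter+DR element.
#' @param hdv_id registry id of the HDV ribozyme part.
#' @param destination alpha-class vector id or `gb_part`.
#' @param product_id id for the resulting TU.
#' @param grammar a `gb_grammar`.
#' @return a Level 1 `gb_part`; reaction attached as attribute
#'   `"reactions"`.
#' @export
assemble_single_cas12a <- function(oligos, upstream_id = "cas12a_upstream",
                                   hdv_id = "hdv_ribozyme",
                                   destination = "alpha1",
                                   product_id = paste0(oligos$name, "_TU"),
                                   grammar = default_grammar()) {
  dest <- resolve_destination(destination, c("alpha1", "alpha2"), grammar)
  rx <- simulate_reaction(list(registry_lookup(upstream_id), oligos,
                               registry_lookup(hdv_id)),
                          "BsaI", dest, grammar, product_id = product_id, level = "L1")
  prod <- add_tu_feature(rx$products[[1]], paste0(oligos$name, "_crRNA_TU"), grammar)
  attr(prod, "reactions") <- list(rx)
  prod
}

#' Design the synthesis fragment for a multiplex Cas12a crRNA array
#' (multiplex domesticator)
#'
#' Takes two to six 20-23-nt spacers and designs the tandem of DR-spacer
#' units, terminated (by default) with the HDV ribozyme and the Pol III
#' terminator, flanked by outward-cutting BsmBI cassettes that release the
#' grammar-compatible overhangs for pUPD2 cloning; the cargo carries its
#' own BsaI flanks for the later Level 1 assembly. The fragment is
#' synthesis-ready DNA (the upstream element's DR acts as a spacer-less
#' leader during self-processing, so the fragment carries one DR per
#' spacer).
#'
#' @param spacers 2-6 Cas12a spacers (character vector or `gb_spacer`
#'   list).
#' @param name fragment name.
#' @param include_hdv terminate the array with the HDV ribozyme
#'   (`FALSE` leaves terminator run-off only).
#' @param flank_stuffer nt of stuffer outside each BsmBI recognition
#'   (synthesis/binding margin).
#' @param grammar a `gb_grammar`.
#' @return a `gb_synth_fragment`: fields `name`, `part` (linear annotated
#'   `gb_part`), `unit_count`, `units` (per-unit table), `include_hdv`.
#' @export
design_cas12a_array_fragment <- function(spacers, name = "cas12a_array",
                                         include_hdv = TRUE,
                                         flank_stuffer = 4L,
                                         grammar = default_grammar()) {
  sps <- as_spacer_list(spacers, "Cas12a", name, grammar)
  n <- length(sps)
  if (n == 1L) {
    gb_abort("use_single_tool_error",
             "one spacer: use the single-crRNA tools (design_single_cas12a_oligos / assemble_single_cas12a)")
  }
  if (n < 1L) gb_abort("empty_input_error", "no spacers supplied")
  if (n > grammar$max_array_size) {
    gb_abort("capacity_error",
             sprintf("%d spacers exceed the array capacity of %d", n, grammar$max_array_size))
  }
  s <- grammar$sites
  el <- registry_element_seqs(grammar)
  stuff <- function(k) paste0("AA", strrep("C", max(0L, k - 2L)))   # inert, site-safe
  b <- new_build()
  b <- add_seg(b, stuff(flank_stuffer))
  b <- add_seg(b, paste0(grammar$enzymes$BsmBI$recognition, "A"))
  b <- add_seg(b, s[["UPD5"]], site_feat("UPD5", grammar))
  b <- add_seg(b, "GGTCTCA")
  b <- add_seg(b, s[["DR_SPACER"]], site_feat("DR_SPACER", grammar))
  for (k in seq_len(n)) {
    b <- add_seg(b, el$dr, gb_feature(sprintf("crRNA_DR_%d", k), "DR", 0L, nchar(el$dr), "+"))
    b <- add_seg(b, sps[[k]]$sequence,
                 gb_feature(sps[[k]]$name, "spacer", 0L, nchar(sps[[k]]$sequence), "+"))
  }
  if (include_hdv) {
    b <- add_seg(b, el$hdv, gb_feature("HDV_ribozyme", "HDV", 0L, nchar(el$hdv), "+"))
  }
  b <- add_seg(b, el$terminator,
               gb_feature("PolIII_terminator", "terminator", 0L, nchar(el$terminator), "+"))
  b <- add_seg(b, s[["VEC3"]], site_feat("VEC3", grammar))
  b <- add_seg(b, "TGAGACC")
  b <- add_seg(b, s[["UPD3"]], site_feat("UPD3", grammar))
  b <- add_seg(b, paste0("T", revcomp(grammar$enzymes$BsmBI$recognition)))
  b <- add_seg(b, stuff(flank_stuffer))
  part <- part_record(name, b$seq, "linear", level = NA_character_,
                      features = b$feats)
  ## the designed flanks are the only Type IIS sites in the fragment
  n_bsmbi <- nrow(find_sites(part, "BsmBI", grammar))
  n_bsai <- nrow(find_sites(part, "BsaI", grammar))
  if (n_bsmbi != 2L || n_bsai != 2L) {
    gb_abort("forbidden_site_error",
             sprintf("fragment '%s' carries unexpected internal Type IIS sites (%d BsaI, %d BsmBI)",
                     name, n_bsai, n_bsmbi))
  }
  structure(list(name = name, part = part, unit_count = n,
                 units = data.frame(unit = seq_len(n),
                                    spacer = vapply(sps, `[[`, character(1), "name"),
                                    spacer_length = vapply(sps, function(x) nchar(x$sequence),
                                                           integer(1)),
                                    stringsAsFactors = FALSE),
                 spacers = sps, include_hdv = include_hdv),
            class = "gb_synth_fragment")
}

#' @export
print.gb_synth_fragment <- function(x, ...) {
  cat(sprintf("<gb_synth_fragment> %s: %d bp, %d DR-spacer units%s\n",
              x$name, nchar(x$part$sequence), x$unit_count,
              if (x$include_hdv) " + HDV" else ""))
  invisible(x)
}

#' Clone a synthesized array fragment as a Level 0 part
#'
#' BsmBI restriction-ligation of the linear fragment into pUPD2.
#'
#' @param fragment a `gb_synth_fragment`.
#' @param product_id id for the Level 0 part.
#' @param grammar a `gb_grammar`.
#' @return a Level 0 `gb_part`; reaction attached as attribute
#'   `"reactions"`.
#' @export
clone_cas12a_fragment_L0 <- function(fragment,
                                     product_id = paste0(fragment$name, "_L0"),
                                     grammar = default_grammar()) {
  rx <- simulate_reaction(list(fragment$part), "BsmBI", registry_lookup("pUPD2"),
                          grammar, product_id = product_id, level = "L0")
  prod <- rx$products[[1]]
  attr(prod, "reactions") <- list(rx)
  prod
}

#' Assemble a polycistronic Cas12a crRNA TU (multiplex assembler)
#'
#' BsaI restriction-ligation of the Level 0 array fragment with the same
#' upstream element used by the single-crRNA assembler, into an
#' alpha-class destination.
#'
#' @param fragment_L0 a Level 0 `gb_part` from
#'   [clone_cas12a_fragment_L0()], or a `gb_synth_fragment` (cloned
#'   automatically).
#' @param upstream_id registry id of the promoter+DR element.
#' @param destination alpha-class vector id or `gb_part`.
#' @param product_id id for the array TU.
#' @param grammar a `gb_grammar`.
#' @return a Level 1 polycistronic `gb_part`; reactions attached as
#'   attribute `"reactions"`.
#' @export
assemble_cas12a_array <- function(fragment_L0, upstream_id = "cas12a_upstream",
                                  destination = "alpha1",
                                  product_id = "cas12a_crRNA_array_TU",
                                  grammar = default_grammar()) {
  pre_rx <- list()
  if (inherits(fragment_L0, "gb_synth_fragment")) {
    fragment_L0 <- clone_cas12a_fragment_L0(fragment_L0, grammar = grammar)
    pre_rx <- attr(fragment_L0, "reactions")
  }
  dest <- resolve_destination(destination, c("alpha1", "alpha2"), grammar)
  rx <- simulate_reaction(list(registry_lookup(upstream_id), fragment_L0),
                          "BsaI", dest, grammar, product_id = product_id, level = "L1")
  prod <- add_tu_feature(rx$products[[1]], product_id, grammar)
  attr(prod, "reactions") <- c(pre_rx, list(rx))
  prod
}
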