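#' Cas9 guide-RNA design tools
#'
#' The single-guide pair of tools (domesticator + assembler) and the
#' three-step multiplex pipeline: spacer domestication into
#' position-independent oligos, construction of Level 0 guide units
#' (tRNA + spacer + scaffold, assembled with BsmBI from pUPD2 and the
#' position's level -1 tRNA-scaffold plasmid), and multipartite BsaI
#' assembly of up to six guides plus a Pol III promoter into a Level 1
#' polycistronic transcriptional unit. The aptamer variant swaps in an
#' MS2-aptamer scaffold for dCas-based regulation arrays (at most three
#' units).
#'
#' The 4-nt junctions are part of the biological elements (tRNA head/tail,
#' scaffold head), so every assembly is scarless: in-planta processing
#' releases exactly spacer + scaffold for each unit (see
#' [process_transcript()]).
#'
#' @name cas9_design
NULL

## warn once per design if the spacer lacks the 5' G many Pol III promoters
## prefer; the spacer itself is never modified (scarlessness is contractual).
check_5prime_g <- function(sp) {
  if (substr(sp$sequence, 1L, 1L) != "G") {
    gb_warn("five_prime_g_warning",
            sprintf("spacer '%s' does not start with G; many Pol III promoters prefer a 5' G (spacer left unmodified)",
                    sp$name))
  }
  sp
}

design_guide_oligos <- function(sp, ovh5_role, ovh3_role, suffix, grammar) {
  s <- grammar$sites
  ovh5 <- s[[ovh5_role]]; ovh3 <- s[[ovh3_role]]
  virtual <- paste0(ovh5, sp$sequence, ovh3)
  hits <- scan_forbidden_sites(virtual, grammar)
  if (nrow(hits)) {
    gb_abort("forbidden_site_error",
             sprintf("spacer '%s' creates a %s recognition (%s) at duplex offset %d",
                     sp$name, hits$enzyme[1], hits$pattern[1], hits$offset[1]),
             hits = hits)
  }
  oligo_pair(name = paste0(sp$name, suffix),
             forward = paste0(ovh5, sp$sequence),
             reverse = revcomp(paste0(sp$sequence, ovh3)),
             overhang_5p = ovh5, overhang_3p = ovh3,
             core_role = "spacer", core_label = sp$name)
}

#' Design oligos for a single Cas9 guide (domesticator)
#'
#' Produces the pair of overlapping oligonucleotides whose annealed duplex
#' carries exactly the 20-nt spacer as double-stranded core, with the
#' single-guide promoter-spacer and spacer-scaffold fusion sites as 5'
#' protrusions.
#'
#' @param spacer a 20-nt DNA string or `gb_spacer` (Cas9).
#' @param name spacer name (when `spacer` is a plain string).
#' @param grammar a `gb_grammar`.
#' @return a `gb_oligo_pair`.
#' @export
design_single_cas9_oligos <- function(spacer, name = "gRNA1",
                                      grammar = default_grammar()) {
  sp <- check_5prime_g(as_spacer(spacer, "Cas9", name, grammar))
  design_guide_oligos(sp, "PROM_GUIDE", "GUIDE_SCAFFOLD", "_sg", grammar)
}

#' Assemble a single Cas9 gRNA transcriptional unit (assembler)
#'
#' BsaI restriction-ligation of the annealed oligos with a Pol III
#' promoter and the Cas9 scaffold into an alpha-class destination vector,
#' yielding a Level 1 gRNA TU annotated with promoter, spacer, scaffold
#' and terminator features.
#'
#' @param oligos `gb_oligo_pair` from [design_single_cas9_oligos()].
#' @param promoter_id,scaffold_id registry ids of the constant parts.
#' @param destination an alpha-class vector id or `gb_part`.
#' @param product_id id for the resulting TU.
#' @param grammar a `gb_grammar`.
#' @return a Level 1 `gb_part`; the underlying `gb_reaction` is attached
#'   as attribute `"reactions"`.
#' @export
assemble_single_cas9 <- function(oligos, promoter_id = "pol3_promoter_single",
                                 scaffold_id = "cas9_scaffold",
                                 destination = "alpha1",
                                 product_id = paste0(oligos$name, "_TU"),
                                 grammar = default_grammar()) {
  dest <- resolve_destination(destination, c("alpha1", "alpha2"), grammar)
  rx <- simulate_reaction(list(registry_lookup(promoter_id), oligos,
                               registry_lookup(scaffold_id)),
                          "BsaI", dest, grammar, product_id = product_id, level = "L1")
  prod <- add_tu_feature(rx$products[[1]], paste0(oligos$name, "_gRNA_TU"), grammar)
  attr(prod, "reactions") <- list(rx)
  prod
}

#' Design position-independent oligos for a multiplex Cas9 spacer
#' (multiplex domesticator, step 1)
#'
#' The duplex carries the tRNA-spacer and spacer-scaffold junctions, which
#' are shared by all array positions: the same pair is reusable at any
#' position, the position being chosen later when the Level 0 guide is
#' built.
#'
#' @inheritParams design_single_cas9_oligos
#' @return a `gb_oligo_pair`.
#' @export
design_multi_cas9_oligos <- function(spacer, name = "gRNA1",
                                     grammar = default_grammar()) {
  sp <- check_5prime_g(as_spacer(spacer, "Cas9", name, grammar))
  design_guide_oligos(sp, "TRNA_SPACER", "GUIDE_SCAFFOLD", "_mg", grammar)
}

#' Build a Level 0 guide unit for one array position
#' (multiplex domesticator, step 2)
#'
#' BsmBI restriction-ligation of the domesticated oligos with pUPD2 and
#' the level -1 tRNA-scaffold plasmid of the requested position: the
#' released cassettes contribute the position's tRNA (whose head is the
#' position's fusion site) and the scaffold (standard or MS2-aptamer),
#' flanked by the BsaI sites the Level 1 assembly will use. The last unit
#' of an array is built with `terminal = TRUE`: its cassette ends with the
#' Pol III terminator and the vector-side fusion site instead of the next
#' position's tRNA head.
#'
#' @param oligos `gb_oligo_pair` from [design_multi_cas9_oligos()].
#' @param position array position, 1-based.
#' @param scaffold_kind `"standard"` or `"aptamer"` (aptamer arrays are
#'   capped at `grammar$max_aptamer_array_size` units).
#' @param terminal is this the last unit of its array?
#' @param product_id id for the Level 0 part.
#' @param grammar a `gb_grammar`.
#' @return a Level 0 `gb_part` with tRNA, spacer and scaffold features;
#'   reaction attached as attribute `"reactions"`.
#' @export
build_guide_L0 <- function(oligos, position, scaffold_kind = c("standard", "aptamer"),
                           terminal = FALSE,
                           product_id = sprintf("%s_L0_pos%d", oligos$name, position),
                           grammar = default_grammar()) {
  scaffold_kind <- match.arg(scaffold_kind)
  maxn <- if (scaffold_kind == "aptamer") grammar$max_aptamer_array_size else grammar$max_array_size
  if (!is.numeric(position) || position < 1 || position > maxn) {
    gb_abort("position_error",
             sprintf("position %s out of range 1..%d for %s scaffold",
                     format(position), maxn, scaffold_kind))
  }
  position <- as.integer(position)
  if (position == maxn && !terminal) {
    gb_abort("position_error",
             sprintf("position %d is the array maximum and must be terminal", position))
  }
  lm1 <- registry_lookup(level_minus1_id(position, terminal, scaffold_kind))
  rx <- simulate_reaction(list(oligos, lm1), "BsmBI", registry_lookup("pUPD2"),
                          grammar, product_id = product_id, level = "L0")
  prod <- rx$products[[1]]
  attr(prod, "reactions") <- list(rx)
  prod
}

## read a guide L0's array position / terminal flag back from its junctions
guide_l0_slot <- function(guide) {
  fs <- features_of(guide, "fusion_site")
  pos_labels <- fs$label[grepl("^POS[0-9]$", fs$label)]
  if (!length(pos_labels)) {
    gb_abort("position_error", sprintf("%s has no position junction annotation", guide$id))
  }
  pos <- min(as.integer(sub("POS", "", pos_labels))) + 1L
  list(position = pos, terminal = "VEC3" %in% fs$label)
}

#' Assemble a polycistronic Cas9 gRNA TU (multiplex assembler)
#'
#' Multipartite BsaI restriction-ligation of a Pol III promoter and 1-6
#' consecutive Level 0 guide units into an alpha-class destination. The
#' guides' array positions are read back from their fusion-site
#' annotations; they must be consecutive from 1 and the last must be a
#' terminal unit.
#'
#' @param guides list of Level 0 guide `gb_part`s (order irrelevant;
#'   positions are encoded in the parts).
#' @param promoter_id registry id of the array promoter.
#' @param destination alpha-class vector id or `gb_part`.
#' @param product_id id for the array TU.
#' @param grammar a `gb_grammar`.
#' @return a Level 1 polycistronic `gb_part`; reaction attached as
#'   attribute `"reactions"`.
#' @export
assemble_cas9_array <- function(guides, promoter_id = "pol3_promoter_multi",
                                destination = "alpha1",
                                product_id = "cas9_gRNA_array_TU",
                                grammar = default_grammar()) {
  if (inherits(guides, "gb_part")) guides <- list(guides)
  n <- length(guides)
  if (n < 1L) gb_abort("empty_input_error", "no guide units supplied")
  if (n > grammar$max_array_size) {
    gb_abort("capacity_error",
             sprintf("%d guide units exceed the array capacity of %d",
                     n, grammar$max_array_size))
  }
  slots <- lapply(guides, guide_l0_slot)
  pos <- vapply(slots, `[[`, integer(1), "position")
  ord <- order(pos)
  if (!identical(sort(pos), seq_len(n))) {
    gb_abort("position_gap_error",
             sprintf("guide positions (%s) must be consecutive 1..%d",
                     paste(sort(pos), collapse = ","), n))
  }
  if (!slots[[ord[n]]]$terminal) {
    gb_abort("position_gap_error",
             sprintf("the last unit (position %d) must be a terminal unit", n))
  }
  if (any(vapply(slots[ord[-n]], `[[`, logical(1), "terminal"))) {
    gb_abort("position_gap_error", "a terminal unit may only occupy the last position")
  }
  dest <- resolve_destination(destination, c("alpha1", "alpha2"), grammar)
  rx <- simulate_reaction(c(list(registry_lookup(promoter_id)), guides[ord]),
                          "BsaI", dest, grammar, product_id = product_id, level = "L1")
  prod <- add_tu_feature(rx$products[[1]], product_id, grammar)
  attr(prod, "reactions") <- list(rx)
  prod
}

#' One-call Cas9 array pipeline: spacers in, Level 1 array TU out
#'
#' Runs multiplex domestication, Level 0 construction (position k for the
#' k-th spacer, terminal for the last) and the multipartite array
#' assembly. Returns the array TU with the full bundle (oligos, Level 0
#' intermediates, reactions, plan) in attributes.
#'
#' @param spacers character vector or list of `gb_spacer` (Cas9).
#' @param scaffold_kind `"standard"` or `"aptamer"`.
#' @param destination alpha-class vector id or `gb_part`.
#' @param id_prefix prefix for generated ids.
#' @param grammar a `gb_grammar`.
#' @return Level 1 array TU (`gb_part`) with attributes `oligos`,
#'   `intermediates`, `reactions`, `plan`.
#' @export
design_cas9_array <- function(spacers, scaffold_kind = c("standard", "aptamer"),
                              destination = "alpha1", id_prefix = "array",
                              grammar = default_grammar()) {
  scaffold_kind <- match.arg(scaffold_kind)
  sps <- as_spacer_list(spacers, "Cas9", id_prefix, grammar)
  n <- length(sps)
  if (n < 1L) gb_abort("empty_input_error", "no spacers supplied")
  maxn <- if (scaffold_kind == "aptamer") grammar$max_aptamer_array_size else grammar$max_array_size
  if (n > maxn) {
    gb_abort("capacity_error", sprintf("%d spacers exceed the capacity of %d", n, maxn))
  }
  oligos <- lapply(sps, design_multi_cas9_oligos, grammar = grammar)
  l0s <- lapply(seq_len(n), function(k) {
    build_guide_L0(oligos[[k]], position = k, scaffold_kind = scaffold_kind,
                   terminal = (k == n), grammar = grammar)
  })
  tu <- assemble_cas9_array(l0s, destination = destination,
                            product_id = paste0(id_prefix, "_gRNA_TU"),
                            grammar = grammar)
  attr(tu, "oligos") <- oligos
  attr(tu, "intermediates") <- l0s
  attr(tu, "reactions") <- c(unlist(lapply(l0s, attr, "reactions"), recursive = FALSE),
                             attr(tu, "reactions"))
  attr(tu, "plan") <- array_plan(sps, nuclease = "Cas9", scaffold_kind = scaffold_kind)
  tu
}

as_spacer_list <- function(spacers, nuclease, prefix, grammar) {
  if (inherits(spacers, "gb_spacer")) spacers <- list(spacers)
  if (is.character(spacers)) {
    nms <- names(spacers) %||% sprintf("%s_g%d", prefix, seq_along(spacers))
    nms[nms == ""] <- sprintf("%s_g%d", prefix, which(nms == ""))
    spacers <- Map(function(sq, nm) spacer_input(sq, nuclease, nm, grammar), spacers, nms)
  }
  lapply(spacers, as_spacer, nuclease = nuclease, grammar = grammar)
}

resolve_destination <- function(destination, allowed, grammar) {
  dest <- if (is.character(destination)) registry_lookup(destination) else destination
  if (!dest$backbone %in% allowed) {
    gb_abort("destination_mismatch_error",
             sprintf("destination %s is %s-class; expected one of %s",
                     dest$id, dest$backbone, paste(allowed, collapse = "/")))
  }
  dest
}

## annotate the assembled cargo (between the VEC5 and VEC3 junctions) as a TU
add_tu_feature <- function(prod, label, grammar) {
  fs <- features_of(prod, "fusion_site")
  v5 <- fs[fs$label == "VEC5", , drop = FALSE]
  v3 <- fs[fs$label == "VEC3", , drop = FALSE]
  if (nrow(v5) == 1L && nrow(v3) == 1L) {
    prod$features <- rbind(prod$features,
                           gb_feature(label, "TU", v5$start[1], v3$end[1], "+"))
  }
  prod
}
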