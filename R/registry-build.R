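#' Registry construction (internal)
#'
#' Builds every bundled part as a `gb_part` from the grammar's fusion-site
#' table plus fixed element bodies (sgRNA scaffold, pre-tRNA, Cas12a direct
#' repeat, HDV ribozyme, MS2 aptamer). Backbone chassis, promoters, stuffers
#' and TU bodies are synthetic stand-ins: deterministic pseudo-random
#' sequences free of BsaI/BsmBI recognitions, generated once with a fixed
#' authoring seed and shipped as GenBank fixtures under
#' `inst/extdata/registry/`. The committed files are the registry;
#' [build_registry()] exists to regenerate and to validate them.
#'
#' Sequence conventions (all coordinates 0-based, top strand):
#' * every pseudo-random segment starts and ends with `AA`, so no Type IIS
#'   recognition (none contains `AA`, none starts with or ends in `A`) can
#'   arise across a junction with a random segment;
#' * the tRNA of array position k starts with the POS(k-1) fusion site and
#'   ends with the TRNA_SPACER site; the scaffold starts with the
#'   GUIDE_SCAFFOLD site; the direct repeat ends with DR_SPACER; the HDV
#'   ribozyme starts with SPACER_HDV. Junction tetramers are thus part of
#'   the biological element, which is what makes assemblies scarless.
#'
#' @name registry-build
#' @keywords internal
NULL

## Fixed element bodies (heads/tails come from the grammar's site table).
SCAFFOLD_REST <- "TAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC"
MS2_APTAMER   <- "ACATGAGGATCACCCATGT"
TRNA_MID      <- "AAAGCACCAGTGGTCTAGTGGTAGAATAGTACCCTGCCACGGTACAGACCCGGGTTCGATTCCCGGCTG"
DR_BODY       <- "TAATTTCTACTAAGTGT"
HDV_REST      <- "GGCATGGTCCCAGCCTCCTCGCTGGCGCCGGCTGGGCAACATGCTTCGGCATGGCGAATGGGAC"
POLIII_TERM   <- "TTTTTTT"

registry_element_seqs <- function(grammar = default_grammar()) {
  s <- grammar$sites
  list(
    scaffold = paste0(s[["GUIDE_SCAFFOLD"]], SCAFFOLD_REST),
    aptamer_scaffold = paste0(s[["GUIDE_SCAFFOLD"]], substr(SCAFFOLD_REST, 1, 44),
                              MS2_APTAMER, substr(SCAFFOLD_REST, 45, nchar(SCAFFOLD_REST))),
    trna = function(pos_site) paste0(pos_site, TRNA_MID, s[["TRNA_SPACER"]]),
    dr = paste0(DR_BODY, s[["DR_SPACER"]]),
    hdv = paste0(s[["SPACER_HDV"]], HDV_REST),
    terminator = POLIII_TERM
  )
}

## deterministic site-free random DNA, AA-capped at both ends
rand_dna_safe <- function(n, grammar = default_grammar()) {
  stopifnot(n >= 6)
  core <- paste(sample(c("A", "C", "G", "T"), n - 4L, replace = TRUE), collapse = "")
  x <- paste0("AA", core, "AA")
  pats <- forbidden_site_patterns(grammar)
  repeat {
    hits <- unlist(lapply(pats, function(p) str_find_all(x, p)))
    if (!length(hits)) break
    for (h in hits) {       # mutate one letter inside each recognition
      pos <- h + 3L
      old <- substr(x, pos + 1L, pos + 1L)
      substr(x, pos + 1L, pos + 1L) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  x
}

## --- tiny segment assembler: tracks offsets, places features ---------------
new_build <- function() list(seq = "", feats = empty_features())
add_seg <- function(b, seq, feats = NULL) {
  off <- nchar(b$seq)
  b$seq <- paste0(b$seq, seq)
  if (!is.null(feats) && nrow(feats)) {
    feats$start <- feats$start + off
    feats$end <- feats$end + off
    b$feats <- rbind(b$feats, feats)
  }
  b
}
site_feat <- function(label, grammar, at = 0L) {
  gb_feature(label, "fusion_site", at, at + 4L, "+")
}

finish_part <- function(b, id, grammar, level, backbone, marker,
                        expected_bsai, expected_bsmbi) {
  p <- part_record(id, b$seq, "circular", level = level, backbone = backbone,
                   marker = marker, features = b$feats)
  got_a <- nrow(find_sites(p, "BsaI", grammar))
  got_b <- nrow(find_sites(p, "BsmBI", grammar))
  if (got_a != expected_bsai || got_b != expected_bsmbi) {
    gb_abort("registry_build_error",
             sprintf("%s: expected %d BsaI / %d BsmBI sites, found %d / %d",
                     id, expected_bsai, expected_bsmbi, got_a, got_b))
  }
  p
}

chassis_seg <- function(b, n, marker_label, class_label, grammar) {
  seq <- rand_dna_safe(n, grammar)
  m_from <- 60L; m_to <- min(n - 60L, m_from + 600L)
  add_seg(b, seq, rbind(
    gb_feature(class_label, "backbone", 0L, n, "+"),
    gb_feature(marker_label, "marker", m_from, m_to, "+")))
}

## ---------------------------------------------------------------------------
## Individual plasmid builders
## ---------------------------------------------------------------------------

build_pupd2 <- function(grammar) {
  s <- grammar$sites
  b <- new_build()
  b <- chassis_seg(b, 820L, "CmR", "pUPD2_backbone", grammar)
  b <- add_seg(b, s[["UPD5"]], site_feat("UPD5", grammar))
  b <- add_seg(b, "TGAGACG")
  b <- add_seg(b, rand_dna_safe(260L, grammar),
               gb_feature("lacZ_stuffer", "stuffer", 0L, 260L, "+"))
  b <- add_seg(b, "CGTCTCA")
  b <- add_seg(b, s[["UPD3"]], site_feat("UPD3", grammar))
  finish_part(b, "pUPD2", grammar, NA_character_, "pUPD2", "chloramphenicol", 0L, 2L)
}

## alpha/omega destination vectors: entry cassette (stuffer) + exit flanks
build_destination <- function(id, grammar) {
  s <- grammar$sites
  spec <- switch(id,
    alpha1 = list(marker = "kanamycin", mlab = "KanR",
                  exit5 = "OMEGA5", entry5 = "VEC5", entry3 = "VEC3", exit3 = "ALPHA_MID",
                  exit_enz = "BsmBI", entry_enz = "BsaI"),
    alpha2 = list(marker = "kanamycin", mlab = "KanR",
                  exit5 = "ALPHA_MID", entry5 = "VEC5", entry3 = "VEC3", exit3 = "OMEGA3",
                  exit_enz = "BsmBI", entry_enz = "BsaI"),
    omega1 = list(marker = "spectinomycin", mlab = "SpecR",
                  exit5 = "VEC5", entry5 = "OMEGA5", entry3 = "OMEGA3", exit3 = "OMEGA_MID",
                  exit_enz = "BsaI", entry_enz = "BsmBI"),
    omega2 = list(marker = "spectinomycin", mlab = "SpecR",
                  exit5 = "OMEGA_MID", entry5 = "OMEGA5", entry3 = "OMEGA3", exit3 = "VEC3",
                  exit_enz = "BsaI", entry_enz = "BsmBI"))
  rec <- function(enz) grammar$enzymes[[enz]]$recognition
  b <- new_build()
  b <- chassis_seg(b, 980L, spec$mlab, paste0(id, "_backbone"), grammar)
  b <- add_seg(b, paste0(rec(spec$exit_enz), "A"))                  # exit cut, 5' side
  b <- add_seg(b, s[[spec$exit5]], site_feat(spec$exit5, grammar))
  b <- add_seg(b, s[[spec$entry5]], site_feat(spec$entry5, grammar))
  b <- add_seg(b, paste0("T", revcomp(rec(spec$entry_enz))))        # entry cut, 5' side
  b <- add_seg(b, rand_dna_safe(300L, grammar),
               gb_feature("lacZ_stuffer", "stuffer", 0L, 300L, "+"))
  b <- add_seg(b, paste0(rec(spec$entry_enz), "A"))                 # entry cut, 3' side
  b <- add_seg(b, s[[spec$entry3]], site_feat(spec$entry3, grammar))
  b <- add_seg(b, s[[spec$exit3]], site_feat(spec$exit3, grammar))
  b <- add_seg(b, paste0("T", revcomp(rec(spec$exit_enz))))         # exit cut, 3' side
  finish_part(b, id, grammar, NA_character_, id, spec$marker, 2L, 2L)
}

## Level 0 parts hosted in pUPD2: cargo carries its own BsaI release flanks.
## cargo_fun(b) must append GGTCTCA + [5'site ... 3'site] + TGAGACC.
build_l0_host <- function(id, grammar, cargo_fun) {
  s <- grammar$sites
  b <- new_build()
  b <- chassis_seg(b, 820L, "CmR", "pUPD2_backbone", grammar)
  b <- add_seg(b, s[["UPD5"]], site_feat("UPD5", grammar))
  b <- cargo_fun(b)
  b <- add_seg(b, s[["UPD3"]], site_feat("UPD3", grammar))
  finish_part(b, id, grammar, "L0", "pUPD2", "chloramphenicol", 2L, 0L)
}

build_promoter_single <- function(grammar, prom_body) {
  s <- grammar$sites
  build_l0_host("pol3_promoter_single", grammar, function(b) {
    b <- add_seg(b, "GGTCTCA")
    p0 <- nchar(b$seq)
    b <- add_seg(b, s[["VEC5"]], site_feat("VEC5", grammar))
    b <- add_seg(b, prom_body)
    b <- add_seg(b, s[["PROM_GUIDE"]], site_feat("PROM_GUIDE", grammar))
    plen <- nchar(b$seq) - p0
    b$feats <- rbind(b$feats, gb_feature("U6_PolIII_promoter", "promoter", p0, p0 + plen, "+"))
    add_seg(b, "TGAGACC")
  })
}

build_promoter_multi <- function(grammar, prom_body) {
  s <- grammar$sites
  build_l0_host("pol3_promoter_multi", grammar, function(b) {
    b <- add_seg(b, "GGTCTCA")
    p0 <- nchar(b$seq)
    b <- add_seg(b, s[["VEC5"]], site_feat("VEC5", grammar))
    b <- add_seg(b, prom_body)
    plen <- nchar(b$seq) - p0
    b$feats <- rbind(b$feats, gb_feature("U6_PolIII_promoter", "promoter", p0, p0 + plen, "+"))
    ## POS0: head of the first tRNA, shared junction letters
    b <- add_seg(b, s[["POS0"]], site_feat("POS0", grammar))
    add_seg(b, "TGAGACC")
  })
}

build_cas9_scaffold_l0 <- function(grammar) {
  el <- registry_element_seqs(grammar)
  build_l0_host("cas9_scaffold", grammar, function(b) {
    b <- add_seg(b, "GGTCTCA")
    b <- add_seg(b, el$scaffold,
                 rbind(gb_feature("sgRNA_scaffold", "scaffold", 0L, nchar(el$scaffold), "+"),
                       site_feat("GUIDE_SCAFFOLD", grammar)))
    b <- add_seg(b, el$terminator,
                 gb_feature("PolIII_terminator", "terminator", 0L, nchar(el$terminator), "+"))
    b <- add_seg(b, grammar$sites[["VEC3"]], site_feat("VEC3", grammar))
    add_seg(b, "TGAGACC")
  })
}

build_cas12a_upstream <- function(grammar, prom_body) {
  s <- grammar$sites
  el <- registry_element_seqs(grammar)
  build_l0_host("cas12a_upstream", grammar, function(b) {
    b <- add_seg(b, "GGTCTCA")
    p0 <- nchar(b$seq)
    b <- add_seg(b, s[["VEC5"]], site_feat("VEC5", grammar))
    b <- add_seg(b, prom_body)
    plen <- nchar(b$seq) - p0
    b$feats <- rbind(b$feats, gb_feature("U6_PolIII_promoter", "promoter", p0, p0 + plen, "+"))
    b <- add_seg(b, el$dr,
                 rbind(gb_feature("crRNA_DR", "DR", 0L, nchar(el$dr), "+"),
                       site_feat("DR_SPACER", grammar, at = nchar(el$dr) - 4L)))
    add_seg(b, "TGAGACC")
  })
}

build_hdv_l0 <- function(grammar) {
  el <- registry_element_seqs(grammar)
  build_l0_host("hdv_ribozyme", grammar, function(b) {
    b <- add_seg(b, "GGTCTCA")
    b <- add_seg(b, el$hdv,
                 rbind(gb_feature("HDV_ribozyme", "HDV", 0L, nchar(el$hdv), "+"),
                       site_feat("SPACER_HDV", grammar)))
    b <- add_seg(b, el$terminator,
                 gb_feature("PolIII_terminator", "terminator", 0L, nchar(el$terminator), "+"))
    b <- add_seg(b, grammar$sites[["VEC3"]], site_feat("VEC3", grammar))
    add_seg(b, "TGAGACC")
  })
}

## Level -1 tRNA-scaffold plasmid for one array position. The BsmBI-released
## tRNA cassette carries the position's 5' junction (the tRNA head) and the
## left BsaI flank of the future Level 0 guide; the scaffold cassette carries
## the 3' junction (next position's tRNA head, or VEC3 + terminator when the
## unit is the last of its array) and the right BsaI flank.
build_level_minus1 <- function(position, terminal, aptamer, grammar) {
  s <- grammar$sites
  el <- registry_element_seqs(grammar)
  trna_seq <- el$trna(s[[paste0("POS", position - 1L)]])
  scaf_seq <- if (aptamer) el$aptamer_scaffold else el$scaffold
  id <- sprintf("trna_scaffold%s_pos%d%s", if (aptamer) "_aptamer" else "",
                position, if (terminal) "_term" else "")
  b <- new_build()
  b <- chassis_seg(b, 760L, "AmpR", "level_minus1_backbone", grammar)
  ## tRNA cassette
  b <- add_seg(b, "CGTCTCA")
  b <- add_seg(b, s[["UPD5"]], site_feat("UPD5", grammar))
  b <- add_seg(b, "GGTCTCA")
  b <- add_seg(b, trna_seq,
               rbind(gb_feature(sprintf("pre_tRNA_pos%d", position), "tRNA",
                                0L, nchar(trna_seq), "+"),
                     site_feat(paste0("POS", position - 1L), grammar),
                     site_feat("TRNA_SPACER", grammar, at = nchar(trna_seq) - 4L)))
  b <- add_seg(b, "TGAGACG")
  ## spacer DNA between the two cassettes
  b <- add_seg(b, rand_dna_safe(60L, grammar))
  ## scaffold cassette
  b <- add_seg(b, "CGTCTCA")
  scaf_feats <- rbind(
    gb_feature(if (aptamer) "sgRNA_scaffold_MS2" else "sgRNA_scaffold", "scaffold",
               0L, nchar(scaf_seq), "+"),
    site_feat("GUIDE_SCAFFOLD", grammar))
  if (aptamer) {
    ap_at <- 4L + 44L
    scaf_feats <- rbind(scaf_feats,
                        gb_feature("MS2_aptamer", "misc", ap_at, ap_at + nchar(MS2_APTAMER), "+"))
  }
  b <- add_seg(b, scaf_seq, scaf_feats)
  if (terminal) {
    b <- add_seg(b, el$terminator,
                 gb_feature("PolIII_terminator", "terminator", 0L, nchar(el$terminator), "+"))
    b <- add_seg(b, s[["VEC3"]], site_feat("VEC3", grammar))
  } else {
    b <- add_seg(b, s[[paste0("POS", position)]],
                 site_feat(paste0("POS", position), grammar))
  }
  b <- add_seg(b, "TGAGACC")
  b <- add_seg(b, s[["UPD3"]], site_feat("UPD3", grammar))
  b <- add_seg(b, "TGAGACG")
  finish_part(b, id, grammar, "minus1", "level_minus1", "ampicillin", 2L, 4L)
}

## Pre-made transcriptional units hosted in any of the four destination
## classes ("pre-made TUs and multigene modules" of the collection).
build_tu_fixture <- function(tu, host, tu_body, grammar) {
  s <- grammar$sites
  lab <- c(cas9_tu = "Cas9_TU", cas12a_tu = "Cas12a_TU",
           nptii_tu = "nptII_TU", dsred_tu = "DsRed_TU")[[tu]]
  id <- paste0(tu, "_", host)
  alpha <- host %in% c("alpha1", "alpha2")
  flank5 <- switch(host, alpha1 = "OMEGA5", alpha2 = "ALPHA_MID",
                   omega1 = "VEC5", omega2 = "OMEGA_MID")
  flank3 <- switch(host, alpha1 = "ALPHA_MID", alpha2 = "OMEGA3",
                   omega1 = "OMEGA_MID", omega2 = "VEC3")
  in5 <- if (alpha) "VEC5" else "OMEGA5"
  in3 <- if (alpha) "VEC3" else "OMEGA3"
  exit_rec <- grammar$enzymes[[if (alpha) "BsmBI" else "BsaI"]]$recognition
  marker <- if (alpha) "kanamycin" else "spectinomycin"
  mlab <- if (alpha) "KanR" else "SpecR"
  b <- new_build()
  b <- chassis_seg(b, 980L, mlab, paste0(host, "_backbone"), grammar)
  b <- add_seg(b, paste0(exit_rec, "A"))
  b <- add_seg(b, s[[flank5]], site_feat(flank5, grammar))
  b <- add_seg(b, s[[in5]], site_feat(in5, grammar))
  b <- add_seg(b, tu_body, gb_feature(lab, "TU", 0L, nchar(tu_body), "+"))
  b <- add_seg(b, s[[in3]], site_feat(in3, grammar))
  b <- add_seg(b, s[[flank3]], site_feat(flank3, grammar))
  b <- add_seg(b, paste0("T", revcomp(exit_rec)))
  finish_part(b, id, grammar, "L1", host, marker,
              expected_bsai = if (alpha) 0L else 2L,
              expected_bsmbi = if (alpha) 2L else 0L)
}

## ---------------------------------------------------------------------------
## Whole-registry build
## ---------------------------------------------------------------------------

#' Build the bundled part registry in memory
#'
#' Deterministic: uses a fixed authoring seed for the synthetic chassis /
#' promoter / stuffer / TU-body segments, independent of the caller's RNG
#' state.
#'
#' @param grammar a `gb_grammar`.
#' @return named list of `gb_part`.
#' @keywords internal
build_registry <- function(grammar = default_grammar()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(20260925L)

  parts <- list()
  parts$pUPD2 <- build_pupd2(grammar)
  for (id in c("alpha1", "alpha2", "omega1", "omega2")) {
    parts[[id]] <- build_destination(id, grammar)
  }
  prom_body <- rand_dna_safe(180L, grammar)
  parts$pol3_promoter_single <- build_promoter_single(grammar, prom_body)
  parts$pol3_promoter_multi <- build_promoter_multi(grammar, prom_body)
  parts$cas9_scaffold <- build_cas9_scaffold_l0(grammar)
  parts$cas12a_upstream <- build_cas12a_upstream(grammar, prom_body)
  parts$hdv_ribozyme <- build_hdv_l0(grammar)
  for (k in 1:5) {
    p <- build_level_minus1(k, terminal = FALSE, aptamer = FALSE, grammar)
    parts[[p$id]] <- p
  }
  for (k in 1:6) {
    p <- build_level_minus1(k, terminal = TRUE, aptamer = FALSE, grammar)
    parts[[p$id]] <- p
  }
  for (k in 1:2) {
    p <- build_level_minus1(k, terminal = FALSE, aptamer = TRUE, grammar)
    parts[[p$id]] <- p
  }
  for (k in 1:3) {
    p <- build_level_minus1(k, terminal = TRUE, aptamer = TRUE, grammar)
    parts[[p$id]] <- p
  }
  tu_sizes <- c(cas9_tu = 720L, cas12a_tu = 640L, nptii_tu = 560L, dsred_tu = 500L)
  for (tu in names(tu_sizes)) {
    body <- rand_dna_safe(tu_sizes[[tu]], grammar)
    for (host in c("alpha1", "alpha2", "omega1", "omega2")) {
      p <- build_tu_fixture(tu, host, body, grammar)
      parts[[p$id]] <- p
    }
  }
  parts
}

#' Write the registry as GenBank fixtures
#' @param dir output directory.
#' @param grammar a `gb_grammar`.
#' @return the directory, invisibly.
#' @keywords internal
write_registry_fixtures <- function(dir, grammar = default_grammar()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parts <- build_registry(grammar)
  for (p in parts) write_genbank(p, file.path(dir, paste0(p$id, ".gb")))
  invisible(dir)
}
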