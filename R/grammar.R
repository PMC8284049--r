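#' The GoldenBraid cloning grammar as data
#'
#' A grammar bundles everything the assembly engine needs to know about the
#' cloning standard: the two Type IIS enzymes, the table of 4-nt fusion
#' sites keyed by junction role, the destination-backbone classes with
#' their entry/exit enzymes and selection markers, and the array capacity.
#'
#' The bundled default models the GoldenBraid standard: multipartite
#' Level-1 assemblies with BsaI into alpha-class vectors, binary assemblies
#' with BsmBI into omega-class vectors (and back again, closing the loop),
#' part domestication with BsmBI into pUPD2, and polycistronic guide arrays
#' of up to six units. Fusion-site letters are package defaults; all
#' correctness guarantees are internal-consistency properties (ligation
#' fidelity, scarless maturation), never tests of particular letters, so
#' the table is swappable via [load_grammar()].
#'
#' @name grammar
NULL

#' Construct a Type IIS enzyme specification
#'
#' @param name enzyme name token.
#' @param recognition recognition sequence, written 5'->3' on the strand
#'   that places the cut downstream (Type IIS recognitions are
#'   non-palindromic, hence directional).
#' @param cut_offset nucleotides between the recognition 3' end and the
#'   top-strand cut.
#' @param overhang_len length of the 5' protrusion left by the cut.
#' @return an `enzyme_spec` list.
#' @export
#' @examples
#' enzyme_spec("BsaI", "GGTCTC", 1, 4)
enzyme_spec <- function(name, recognition, cut_offset = 1L, overhang_len = 4L) {
  recognition <- check_dna(recognition, "recognition")
  if (cut_offset < 0) gb_abort("grammar_error", "cut_offset must be >= 0")
  if (identical(recognition, revcomp(recognition))) {
    gb_abort("grammar_error",
             sprintf("recognition %s is palindromic; Type IIS recognitions must be directional",
                     recognition))
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset),
                 overhang_len = as.integer(overhang_len)),
            class = "enzyme_spec")
}

## Junction roles every bundled template uses; validation requires them.
REQUIRED_SITE_ROLES <- c(
  "VEC5", "VEC3",            # cargo boundaries in alpha entry / omega release
  "OMEGA5", "OMEGA3",        # cargo boundaries in omega entry / alpha release
  "ALPHA_MID", "OMEGA_MID",  # handover site between the two complementary vectors
  "UPD5", "UPD3",            # pUPD2 cloning boundaries
  "PROM_GUIDE",              # single-guide promoter-spacer junction
  "GUIDE_SCAFFOLD",          # spacer-scaffold junction (= scaffold head)
  "TRNA_SPACER",             # tRNA-spacer junction (= tRNA tail)
  "DR_SPACER",               # upstream DR-spacer junction (= direct-repeat tail)
  "SPACER_HDV",              # spacer-HDV junction (= HDV head)
  paste0("POS", 0:5)         # array-position junctions (promoter-unit1 .. unit5-unit6)
)

default_sites <- function() {
  c(VEC5 = "GGAG", VEC3 = "CGCT",
    OMEGA5 = "CAGG", OMEGA3 = "CTCA",
    ALPHA_MID = "TACA", OMEGA_MID = "CCAT",
    UPD5 = "CTCG", UPD3 = "GGTA",
    PROM_GUIDE = "ATTG", GUIDE_SCAFFOLD = "GTTT",
    TRNA_SPACER = "CGCA", DR_SPACER = "AGAT", SPACER_HDV = "GTCC",
    POS0 = "CACC", POS1 = "GCAA", POS2 = "ACTA",
    POS3 = "TTAC", POS4 = "CAGC", POS5 = "TGGA")
}

#' Construct a backbone-class descriptor
#'
#' @param class one of `"pUPD2"`, `"alpha1"`, `"alpha2"`, `"omega1"`,
#'   `"omega2"`, `"level_minus1"`, `"custom"`.
#' @param marker resistance-marker token used for selection filtering.
#' @param entry_enzyme enzyme that opens the backbone to accept cargo
#'   (`NA` for level -1 donors, which are never destinations).
#' @param exit_enzyme enzyme that releases the hosted cargo.
#' @return a `backbone_spec` list.
#' @export
backbone_spec <- function(class, marker, entry_enzyme, exit_enzyme) {
  structure(list(class = class, marker = marker,
                 entry_enzyme = entry_enzyme, exit_enzyme = exit_enzyme),
            class = "backbone_spec")
}

default_backbones <- function() {
  list(
    pUPD2  = backbone_spec("pUPD2", "chloramphenicol", "BsmBI", "BsaI"),
    alpha1 = backbone_spec("alpha1", "kanamycin", "BsaI", "BsmBI"),
    alpha2 = backbone_spec("alpha2", "kanamycin", "BsaI", "BsmBI"),
    omega1 = backbone_spec("omega1", "spectinomycin", "BsmBI", "BsaI"),
    omega2 = backbone_spec("omega2", "spectinomycin", "BsmBI", "BsaI"),
    level_minus1 = backbone_spec("level_minus1", "ampicillin", NA_character_, "BsmBI")
  )
}

#' The bundled default grammar
#'
#' @return a validated `gb_grammar` object.
#' @export
#' @examples
#' g <- default_grammar()
#' g$max_array_size
default_grammar <- function() {
  g <- structure(
    list(
      enzymes = list(BsaI = enzyme_spec("BsaI", "GGTCTC", 1L, 4L),
                     BsmBI = enzyme_spec("BsmBI", "CGTCTC", 1L, 4L)),
      sites = default_sites(),
      backbones = default_backbones(),
      max_array_size = 6L,
      max_aptamer_array_size = 3L
    ),
    class = "gb_grammar"
  )
  validate_grammar(g)
}

#' Validate a grammar
#'
#' Checks the structural invariants of the cloning standard: 4-nt fusion
#' sites that are pairwise distinct and never their own reverse complement
#' (a self-complementary overhang would self-ligate ambiguously),
#' directional enzyme recognitions, the alpha/omega enzyme alternation, and
#' coverage of every junction role the bundled templates use.
#'
#' @param g a `gb_grammar`.
#' @return `g`, invisibly valid; otherwise raises a `grammar_error` naming
#'   the violated rule.
#' @export
validate_grammar <- function(g) {
  if (!inherits(g, "gb_grammar")) gb_abort("grammar_error", "not a gb_grammar object")
  for (e in g$enzymes) {
    if (!inherits(e, "enzyme_spec")) gb_abort("grammar_error", "malformed enzyme spec")
  }
  sites <- g$sites
  if (any(nchar(sites) != 4L)) {
    gb_abort("grammar_error", "all fusion sites must be 4 nt")
  }
  if (anyDuplicated(sites)) {
    dup <- sites[duplicated(sites)][1L]
    gb_abort("grammar_error",
             sprintf("fusion-site sequence %s appears under more than one label", dup))
  }
  self_rc <- vapply(sites, function(s) identical(s, revcomp(s)), logical(1))
  if (any(self_rc)) {
    gb_abort("grammar_error",
             sprintf("fusion site %s equals its own reverse complement and would self-ligate",
                     sites[self_rc][1L]))
  }
  missing <- setdiff(REQUIRED_SITE_ROLES, names(sites))
  if (length(missing)) {
    gb_abort("grammar_error",
             sprintf("fusion-site table lacks junction role(s): %s",
                     paste(missing, collapse = ", ")))
  }
  bks <- g$backbones
  for (cls in c("alpha1", "alpha2")) {
    b <- bks[[cls]]
    if (is.null(b) || !identical(b$entry_enzyme, "BsaI") || !identical(b$exit_enzyme, "BsmBI"))
      gb_abort("grammar_error", "alpha backbones must open with BsaI and release with BsmBI")
  }
  for (cls in c("omega1", "omega2")) {
    b <- bks[[cls]]
    if (is.null(b) || !identical(b$entry_enzyme, "BsmBI") || !identical(b$exit_enzyme, "BsaI"))
      gb_abort("grammar_error", "omega backbones must open with BsmBI and release with BsaI")
  }
  if (is.null(bks$pUPD2) || !identical(bks$pUPD2$entry_enzyme, "BsmBI"))
    gb_abort("grammar_error", "pUPD2 must open with BsmBI")
  if (!is.numeric(g$max_array_size) || g$max_array_size < 1)
    gb_abort("grammar_error", "max_array_size must be >= 1")
  invisible(g)
}

#' Load a grammar from a JSON config (or an override list)
#'
#' Missing keys fall back to the bundled defaults, so `load_grammar()` with
#' no argument (or an empty document) is the zero-configuration path.
#' The config may override `sites` (named map label -> 4-nt sequence),
#' `max_array_size`, enzyme definitions under `enzymes`
#' (`name`/`recognition`/`cut_offset`/`overhang_len`), and backbone markers
#' under `backbones` (`class`/`marker`/`entry_enzyme`/`exit_enzyme`).
#'
#' @param config `NULL`, a path to a JSON document, or a named list of
#'   overrides.
#' @return a validated `gb_grammar`.
#' @export
#' @examples
#' g <- load_grammar()            # bundled default
#' g2 <- load_grammar(list(max_array_size = 4))
load_grammar <- function(config = NULL) {
  g <- structure(
    list(enzymes = list(BsaI = enzyme_spec("BsaI", "GGTCTC", 1L, 4L),
                        BsmBI = enzyme_spec("BsmBI", "CGTCTC", 1L, 4L)),
         sites = default_sites(),
         backbones = default_backbones(),
         max_array_size = 6L,
         max_aptamer_array_size = 3L),
    class = "gb_grammar")
  if (is.null(config)) return(validate_grammar(g))
  ov <- config
  if (is.character(config)) {
    if (!file.exists(config)) gb_abort("config_error", sprintf("no such config file: %s", config))
    ov <- tryCatch(jsonlite::fromJSON(config, simplifyVector = TRUE),
                   error = function(e) gb_abort("config_error",
                                                sprintf("malformed grammar config: %s",
                                                        conditionMessage(e))))
  }
  if (!is.list(ov)) gb_abort("config_error", "grammar config must be a JSON object / named list")
  if (!is.null(ov$sites)) {
    s <- unlist(ov$sites)
    if (is.null(names(s)) || any(names(s) == ""))
      gb_abort("config_error", "sites override must be a named map")
    g$sites[names(s)] <- toupper(as.character(s))
  }
  if (!is.null(ov$max_array_size)) g$max_array_size <- as.integer(ov$max_array_size)
  if (!is.null(ov$max_aptamer_array_size)) g$max_aptamer_array_size <- as.integer(ov$max_aptamer_array_size)
  if (!is.null(ov$enzymes)) {
    for (nm in names(ov$enzymes)) {
      e <- ov$enzymes[[nm]]
      g$enzymes[[nm]] <- enzyme_spec(nm, e$recognition,
                                     e$cut_offset %||% 1L, e$overhang_len %||% 4L)
    }
  }
  if (!is.null(ov$backbones)) {
    for (nm in names(ov$backbones)) {
      b <- ov$backbones[[nm]]
      cur <- g$backbones[[nm]] %||% backbone_spec("custom", "unknown", NA, NA)
      g$backbones[[nm]] <- backbone_spec(b$class %||% cur$class, b$marker %||% cur$marker,
                                         b$entry_enzyme %||% cur$entry_enzyme,
                                         b$exit_enzyme %||% cur$exit_enzyme)
    }
  }
  validate_grammar(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gb_grammar <- function(x, ...) {
  cat("<gb_grammar>\n")
  cat("  enzymes:", paste(vapply(x$enzymes, function(e)
    sprintf("%s (%s, offset %d, %d-nt overhang)", e$name, e$recognition,
            e$cut_offset, e$overhang_len), character(1)), collapse = "; "), "\n")
  cat("  fusion sites:", length(x$sites), "junction roles\n")
  cat("  backbone classes:", paste(names(x$backbones), collapse = ", "), "\n")
  cat("  max array size:", x$max_array_size, "\n")
  invisible(x)
}

## The four recognition strings (both strands, both enzymes) that a
## domesticated sequence must avoid.
forbidden_site_patterns <- function(grammar = default_grammar()) {
  pats <- unlist(lapply(grammar$enzymes, function(e) c(e$recognition, revcomp(e$recognition))))
  stats::setNames(pats, rep(names(grammar$enzymes), each = 2L))
}

## Scan `seq` for Type IIS recognitions on either strand.
## Returns a data.frame(enzyme, pattern, offset) of hits (0-based offsets).
scan_forbidden_sites <- function(seq, grammar = default_grammar(), circular = FALSE) {
  pats <- forbidden_site_patterns(grammar)
  hits <- lapply(seq_along(pats), function(i) {
    off <- str_find_all(seq, pats[[i]], circular = circular)
    if (!length(off)) return(NULL)
    data.frame(enzyme = names(pats)[i], pattern = pats[[i]], offset = off,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) data.frame(enzyme = character(0), pattern = character(0),
                                offset = integer(0), stringsAsFactors = FALSE)
  else hits[order(hits$offset), , drop = FALSE]
}
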