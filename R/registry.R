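#' The bundled part registry
#'
#' The collection of pre-made DNA parts shipped with the package as
#' annotated GenBank fixtures: the pUPD2 entry vector, the four
#' destination vectors (alpha1/alpha2/omega1/omega2), Level 0 elements for
#' guide cloning (Pol III promoters, Cas9 scaffold, the Cas12a upstream
#' element carrying promoter plus first direct repeat, the HDV ribozyme),
#' the level -1 tRNA-scaffold plasmids for every array position (internal
#' and terminal cassettes, plus MS2-aptamer scaffold variants for
#' regulation arrays), and pre-made transcriptional units (Cas9, Cas12a,
#' nptII, DsRed) hosted in each destination class.
#'
#' Chassis, promoter and TU letter sequences are synthetic stand-ins;
#' every downstream guarantee is an internal-consistency property of the
#' grammar, not of particular letters.
#'
#' @name registry
NULL

.registry_env <- new.env(parent = emptyenv())

registry_dir <- function() {
  d <- system.file("extdata", "registry", package = "braidr")
  if (!nzchar(d) || !dir.exists(d)) {
    gb_abort("registry_error", "bundled registry directory not found")
  }
  d
}

## ids that resolve to a default host
REGISTRY_ALIASES <- c(
  cas9_tu = "cas9_tu_alpha1", cas12a_tu = "cas12a_tu_alpha1",
  nptii_tu = "nptii_tu_alpha1", dsred_tu = "dsred_tu_alpha1"
)

#' List all bundled part ids
#' @return character vector of ids (aliases included).
#' @export
registry_ids <- function() {
  files <- list.files(registry_dir(), pattern = "\\.gb$")
  sort(c(sub("\\.gb$", "", files), names(REGISTRY_ALIASES)))
}

#' Look up a part in the bundled registry
#'
#' Returns an independent copy of the fixture record with its features
#' intact (R's copy-on-modify semantics make every returned record a deep
#' copy as far as mutation is concerned).
#'
#' @param part_id a bundled id, e.g. `"pUPD2"`, `"cas9_scaffold"`,
#'   `"trna_scaffold_pos2"`, `"nptii_tu_alpha1"` (see [registry_ids()]).
#' @return a `gb_part`.
#' @export
#' @examples
#' p <- registry_lookup("pUPD2")
#' p$backbone
registry_lookup <- function(part_id) {
  id <- if (part_id %in% names(REGISTRY_ALIASES)) REGISTRY_ALIASES[[part_id]] else part_id
  cached <- .registry_env[[id]]
  if (!is.null(cached)) return(cached)
  path <- file.path(registry_dir(), paste0(id, ".gb"))
  if (!file.exists(path)) {
    gb_abort("unknown_part_error", sprintf("no part '%s' in the bundled registry", part_id))
  }
  rec <- read_genbank(path)
  .registry_env[[id]] <- rec
  rec
}

## level -1 plasmid id for a guide slot
level_minus1_id <- function(position, terminal, scaffold_kind) {
  sprintf("trna_scaffold%s_pos%d%s",
          if (scaffold_kind == "aptamer") "_aptamer" else "",
          position, if (terminal) "_term" else "")
}
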