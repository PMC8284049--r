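#' Multigene composition: the alpha/omega binary loop
#'
#' GoldenBraid composes Level >=1 modules pairwise: two modules hosted in
#' complementary alpha vectors (alpha1 + alpha2) are joined by a BsmBI
#' binary assembly into an omega vector; two omega-hosted modules are
#' joined by BsaI into an alpha vector, closing the loop and allowing
#' indefinite growth while alternating the two enzymes. Because strict
#' pairing alone cannot reach every module count, the bundled collection
#' ships its pre-made TUs hosted in all four destination classes; the
#' composition planner draws each fixture from whichever class the plan
#' requires, while guide-array TUs (which the user builds) are always
#' assembled into an alpha vector first.
#'
#' @name multigene
NULL

vector_class <- function(backbone) {
  if (backbone %in% c("alpha1", "alpha2")) "alpha"
  else if (backbone %in% c("omega1", "omega2")) "omega"
  else NA_character_
}

fixture_in_host <- function(id, host) {
  base <- sub("_(alpha|omega)[12]$", "", id)
  registry_lookup(paste0(base, "_", host))
}

#' Binary GoldenBraid assembly of two hosted modules
#'
#' @param a,b Level >=1 modules (`gb_part`) hosted in complementary
#'   vectors of the same class (alpha1 + alpha2, or omega1 + omega2). The
#'   product carries the alpha1 (resp. omega1) cargo first, per the
#'   grammar, regardless of argument order.
#' @param destination vector id or `gb_part` of the opposite class.
#' @param product_id id for the product.
#' @param grammar a `gb_grammar`.
#' @return a Level >1 `gb_part`; reaction attached as attribute
#'   `"reactions"`.
#' @export
binary_assemble <- function(a, b, destination = NULL,
                            product_id = paste(a$id, b$id, sep = "+"),
                            grammar = default_grammar()) {
  cls_a <- vector_class(a$backbone); cls_b <- vector_class(b$backbone)
  if (is.na(cls_a) || is.na(cls_b) || cls_a != cls_b ||
      identical(a$backbone, b$backbone)) {
    gb_abort("incompatible_vectors_error",
             sprintf("binary assembly needs complementary vectors of one class; got %s + %s",
                     a$backbone, b$backbone))
  }
  dest_class <- if (cls_a == "alpha") "omega" else "alpha"
  if (is.null(destination)) destination <- paste0(dest_class, "1")
  dest <- if (is.character(destination)) registry_lookup(destination) else destination
  if (!identical(vector_class(dest$backbone), dest_class)) {
    gb_abort("destination_mismatch_error",
             sprintf("%s-hosted modules must be composed into an %s-class vector, not %s",
                     cls_a, dest_class, dest$backbone))
  }
  enzyme <- grammar$backbones[[dest$backbone]]$entry_enzyme
  ## grammar order: the "1"-subclass cargo precedes the "2"-subclass cargo
  if (grepl("2$", a$backbone)) { tmp <- a; a <- b; b <- tmp }
  rx <- simulate_reaction(list(a, b), enzyme, dest, grammar,
                          product_id = product_id, level = "Lgt1")
  prod <- rx$products[[1]]
  attr(prod, "reactions") <- list(rx)
  prod
}

## ---------------------------------------------------------------------------
## Composition planner: modules in a fixed left-to-right order are packed
## into a binary tree whose node classes alternate alpha/omega with depth.
## Leaves: "fixture" (pre-made TU, available in any destination class) or
## "array" (built by the user, assemblable into any *alpha* vector).
## ---------------------------------------------------------------------------

compose_modules <- function(leaves, final_host = "alpha1",
                            product_id = "multigene_construct",
                            grammar = default_grammar()) {
  K <- length(leaves)
  if (K < 1L) gb_abort("empty_input_error", "no modules to compose")
  kind <- vapply(leaves, `[[`, character(1), "kind")
  alpha_memo <- new.env(); omega_memo <- new.env()
  alpha_ok <- function(lo, hi) {
    key <- paste(lo, hi)
    if (!is.null(alpha_memo[[key]])) return(alpha_memo[[key]])
    res <- if (lo == hi) TRUE else {
      any(vapply(lo:(hi - 1L), function(m) omega_ok(lo, m) && omega_ok(m + 1L, hi),
                 logical(1)))
    }
    alpha_memo[[key]] <- res
    res
  }
  omega_ok <- function(lo, hi) {
    key <- paste(lo, hi)
    if (!is.null(omega_memo[[key]])) return(omega_memo[[key]])
    res <- if (lo == hi) kind[lo] == "fixture" else {
      any(vapply(lo:(hi - 1L), function(m) alpha_ok(lo, m) && alpha_ok(m + 1L, hi),
                 logical(1)))
    }
    omega_memo[[key]] <- res
    res
  }
  if (!alpha_ok(1L, K)) {
    gb_abort("composition_error",
             "no alpha/omega composition plan exists for this module order")
  }
  reactions <- list(); intermediates <- list()
  note <- function(p) {
    rx <- attr(p, "reactions")
    if (!is.null(rx)) reactions <<- c(reactions, rx)
    intermediates[[p$id]] <<- p
    p
  }
  leaf_part <- function(i, host) {
    lf <- leaves[[i]]
    if (lf$kind == "fixture") registry_lookup(paste0(lf$base, "_", host))
    else note(lf$build(host))
  }
  exec_alpha <- function(lo, hi, host) {
    if (lo == hi) return(leaf_part(lo, host))
    m <- which(vapply(lo:(hi - 1L), function(m) omega_ok(lo, m) && omega_ok(m + 1L, hi),
                      logical(1)))[1L] + lo - 1L
    a <- exec_omega(lo, m, "omega1")
    b <- exec_omega(m + 1L, hi, "omega2")
    note(binary_assemble(a, b, destination = host,
                         product_id = sprintf("mod_%d_%d_%s", lo, hi, host),
                         grammar = grammar))
  }
  exec_omega <- function(lo, hi, host) {
    if (lo == hi) return(leaf_part(lo, host))
    m <- which(vapply(lo:(hi - 1L), function(m) alpha_ok(lo, m) && alpha_ok(m + 1L, hi),
                      logical(1)))[1L] + lo - 1L
    a <- exec_alpha(lo, m, "alpha1")
    b <- exec_alpha(m + 1L, hi, "alpha2")
    note(binary_assemble(a, b, destination = host,
                         product_id = sprintf("mod_%d_%d_%s", lo, hi, host),
                         grammar = grammar))
  }
  final <- exec_alpha(1L, K, final_host)
  final$id <- product_id
  if (length(intermediates)) {
    intermediates[[length(intermediates)]] <- NULL   # drop duplicate of final
  }
  attr(final, "reactions") <- reactions
  attr(final, "intermediates") <- intermediates
  final
}

#' Build the minimal three-TU editing construct
#'
#' A basic CRISPR/Cas genome-editing construct comprises at least three
#' Level 1 TUs: the guide TU, a Cas nuclease TU, and a plant selection
#' marker TU. The guide TU (alpha-hosted) is paired with the Cas TU drawn
#' from the complementary alpha class, composed into omega1, and then
#' joined with the marker TU (drawn omega2-hosted) into the final
#' alpha-class T-DNA.
#'
#' @param guide_TU an alpha-hosted Level 1 guide `gb_part`.
#' @param cas_TU_id registry TU id (default Cas9).
#' @param marker_TU_id registry TU id (default nptII).
#' @param product_id id for the T-DNA.
#' @param grammar a `gb_grammar`.
#' @return `gb_part` with exactly three TU features; reactions attached.
#' @export
build_minimal_editing_construct <- function(guide_TU, cas_TU_id = "cas9_tu",
                                            marker_TU_id = "nptii_tu",
                                            product_id = "editing_construct",
                                            grammar = default_grammar()) {
  if (!identical(vector_class(guide_TU$backbone), "alpha")) {
    gb_abort("incompatible_vectors_error",
             sprintf("guide TU must be alpha-hosted, found %s", guide_TU$backbone))
  }
  other_alpha <- if (identical(guide_TU$backbone, "alpha1")) "alpha2" else "alpha1"
  cas <- fixture_in_host(cas_TU_id, other_alpha)
  marker <- fixture_in_host(marker_TU_id, "omega2")
  m1 <- binary_assemble(cas, guide_TU, destination = "omega1",
                        product_id = "cas_guide_module", grammar = grammar)
  final <- binary_assemble(m1, marker, destination = "alpha1",
                           product_id = product_id, grammar = grammar)
  attr(final, "reactions") <- c(attr(m1, "reactions"), attr(final, "reactions"))
  final
}

#' One-shot Cas9 multiplex pipeline ("fast-track" assembly)
#'
#' From 1-6 Cas9 spacers straight to a ready-to-transform T-DNA: designs
#' the 2N oligos, builds the Level 0 guide units and the polycistronic
#' array TU, and composes it with the constitutive Cas9 TU, the nptII
#' positive-selection TU and the DsRed TU (positive selection in T0,
#' negative in T1) in the default order nptII, Cas9, DsRed, gRNA array.
#'
#' @param spacers 1-6 Cas9 spacers (character vector or `gb_spacer`
#'   list).
#' @param product_id id for the final construct.
#' @param grammar a `gb_grammar`.
#' @return a `gb_bundle`: list with `final` (the T-DNA `gb_part`),
#'   `oligos`, `oligo_sheet` (2N-row data.frame), `intermediates` (every
#'   Level 0/1/>1 record), `reactions`, `protocol`.
#' @export
crispr_for_dummies <- function(spacers, product_id = "crispr_dummies_construct",
                               grammar = default_grammar()) {
  sps <- as_spacer_list(spacers, "Cas9", "dummies", grammar)
  n <- length(sps)
  if (n < 1L) gb_abort("empty_input_error", "at least one spacer is required")
  if (n > grammar$max_array_size) {
    gb_abort("capacity_error",
             sprintf("%d spacers exceed the array capacity of %d", n, grammar$max_array_size))
  }
  leaves <- list(
    list(kind = "fixture", base = "nptii_tu"),
    list(kind = "fixture", base = "cas9_tu"),
    list(kind = "fixture", base = "dsred_tu"),
    list(kind = "array",
         build = function(host) design_cas9_array(sps, destination = host,
                                                  id_prefix = "dummies",
                                                  grammar = grammar)))
  final <- compose_modules(leaves, final_host = "alpha1",
                           product_id = product_id, grammar = grammar)
  ints <- attr(final, "intermediates")
  array_tu <- ints[[grep("_gRNA_TU$", names(ints))[1]]]
  oligos <- attr(array_tu, "oligos")
  ints <- c(lapply(attr(array_tu, "intermediates"), identity), ints)
  reactions <- attr(final, "reactions")
  structure(list(final = final, oligos = oligos,
                 oligo_sheet = do.call(rbind, lapply(oligos, function(p) {
                   data.frame(name = c(paste0(p$name, "_F"), paste0(p$name, "_R")),
                              sequence = c(p$forward, p$reverse),
                              length = c(nchar(p$forward), nchar(p$reverse)),
                              stringsAsFactors = FALSE)
                 })),
                 intermediates = ints, reactions = reactions,
                 protocol = render_protocol(reactions,
                                            title = "Fast-track Cas9 multiplex assembly")),
            class = "gb_bundle")
}

#' @export
print.gb_bundle <- function(x, ...) {
  cat(sprintf("<gb_bundle> final construct %s (%d bp), %d oligos, %d intermediates, %d reactions\n",
              x$final$id, nchar(x$final$sequence), nrow(x$oligo_sheet),
              length(x$intermediates), length(x$reactions)))
  invisible(x)
}

#' Write a design bundle to disk
#'
#' `oligos.csv`, `protocol.md`, one GenBank file per intermediate, and the
#' final construct.
#'
#' @param bundle a `gb_bundle`.
#' @param dir output directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_oligo_sheet(bundle$oligos, file.path(dir, "oligos.csv"))
  write_protocol(bundle$protocol, file.path(dir, "protocol.md"))
  for (p in bundle$intermediates) {
    if (inherits(p, "gb_part")) write_genbank(p, file.path(dir, paste0(p$id, ".gb")))
  }
  write_genbank(bundle$final, file.path(dir, paste0(bundle$final$id, ".gb")))
  invisible(dir)
}

#' Compose a multi-array stress-test T-DNA
#'
#' Builds one polycistronic Cas9 array per spacer batch and composes them
#' with the nptII, Cas9 and DsRed TUs (order: nptII, Cas9, DsRed, then the
#' arrays) through iterated binary assembly. With batches of 6, 5 and 6
#' spacers this reproduces the 17-guide editing construct layout used to
#' stress-test the cloning system.
#'
#' @param batches list of Cas9 spacer vectors (each 1-6 spacers).
#' @param product_id id for the final T-DNA.
#' @param grammar a `gb_grammar`.
#' @return the final `gb_part` with reactions and intermediates attached.
#' @export
compose_stress_test <- function(batches, product_id = "stress_test_construct",
                                grammar = default_grammar()) {
  if (!length(batches)) gb_abort("empty_input_error", "no spacer batches")
  batches <- lapply(batches, function(b) as_spacer_list(b, "Cas9", "stress", grammar))
  for (b in batches) {
    if (length(b) > grammar$max_array_size) {
      gb_abort("capacity_error",
               sprintf("a batch of %d spacers exceeds the array capacity of %d",
                       length(b), grammar$max_array_size))
    }
  }
  leaves <- c(
    list(list(kind = "fixture", base = "nptii_tu"),
         list(kind = "fixture", base = "cas9_tu"),
         list(kind = "fixture", base = "dsred_tu")),
    lapply(seq_along(batches), function(i) {
      list(kind = "array",
           build = function(host) design_cas9_array(batches[[i]], destination = host,
                                                    id_prefix = sprintf("array%d", i),
                                                    grammar = grammar))
      }))
  compose_modules(leaves, final_host = "alpha1", product_id = product_id,
                  grammar = grammar)
}
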