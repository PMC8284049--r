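#' In-silico Type IIS digestion-ligation
#'
#' Every GoldenBraid step -- part domestication, multipartite Level-1
#' assembly, binary alpha/omega composition -- runs through the same
#' mechanism: digest the inputs with one Type IIS enzyme, enumerate the
#' circular ligation products compatible with the 4-nt overhangs, and keep
#' the unique product that carries the destination's selection marker and
#' no remaining site of the reaction enzyme (Golden Gate irreversibility).
#'
#' Sticky fragments are represented by their *virtual top strand*: the
#' top-strand letters spanning from the top cut of the upstream site to the
#' bottom cut of the downstream site, so both 4-nt overhang regions are
#' included once. Two fragments join when the upstream fragment's 3'-side
#' overhang letters equal the downstream fragment's 5'-side letters
#' (exact Watson-Crick annealing of the protrusions); concatenation then
#' drops the shared tetramer, so a circular product of k fragments has
#' length sum(len_i) - 4k.
#'
#' @name goldengate
NULL

## ---------------------------------------------------------------------------
## Site finding
## ---------------------------------------------------------------------------

#' Locate Type IIS sites and their cut coordinates
#'
#' Finds all occurrences of the enzyme's recognition on both strands
#' (scanning across the origin for circular records) and computes the
#' double-strand cut from `cut_offset` and `overhang_len`. `cut_top` /
#' `cut_bottom` are 0-based top-strand coordinates; the 4-nt overhang
#' spans `[cut_top, cut_bottom)`.
#'
#' @param record a `gb_part`.
#' @param enzyme enzyme name (in `grammar$enzymes`) or an `enzyme_spec`.
#' @param grammar a `gb_grammar`.
#' @return data.frame with columns `pos`, `strand`, `cut_top`,
#'   `cut_bottom` (possibly empty).
#' @export
find_sites <- function(record, enzyme, grammar = default_grammar()) {
  e <- resolve_enzyme(enzyme, grammar)
  seq <- record$sequence
  n <- nchar(seq)
  circular <- record$topology == "circular"
  L <- nchar(e$recognition)
  rows <- list()
  for (p in str_find_all(seq, e$recognition, circular = circular)) {
    ct <- p + L + e$cut_offset
    cb <- ct + e$overhang_len
    if (!circular && cb > n) next            # cut falls off a linear molecule
    rows[[length(rows) + 1L]] <- data.frame(
      pos = p, strand = "+",
      cut_top = if (circular) ct %% n else ct,
      cut_bottom = if (circular) cb %% n else cb)
  }
  for (q in str_find_all(seq, revcomp(e$recognition), circular = circular)) {
    ct <- q - e$cut_offset - e$overhang_len
    cb <- q - e$cut_offset
    if (!circular && ct < 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      pos = q, strand = "-",
      cut_top = if (circular) ct %% n else ct,
      cut_bottom = if (circular) cb %% n else cb)
  }
  if (!length(rows)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      cut_top = integer(0), cut_bottom = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cut_top), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_enzyme <- function(enzyme, grammar) {
  if (inherits(enzyme, "enzyme_spec")) return(enzyme)
  e <- grammar$enzymes[[enzyme]]
  if (is.null(e)) gb_abort("grammar_error", sprintf("unknown enzyme: %s", enzyme))
  e
}

## ---------------------------------------------------------------------------
## Sticky fragments
## ---------------------------------------------------------------------------

sticky_fragment <- function(seq, source, features = empty_features(),
                            carries_backbone = FALSE, marker = NA_character_,
                            ovh_len = 4L) {
  structure(list(seq = seq,
                 ovh5 = substr(seq, 1L, ovh_len),
                 ovh3 = substr(seq, nchar(seq) - ovh_len + 1L, nchar(seq)),
                 source = source, features = features,
                 carries_backbone = carries_backbone, marker = marker),
            class = "gb_fragment")
}

flip_fragment <- function(f) {
  n <- nchar(f$seq)
  feats <- f$features
  if (nrow(feats)) {
    s <- n - feats$end; e <- n - feats$start
    feats$start <- s; feats$end <- e
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
  }
  sticky_fragment(revcomp(f$seq), f$source, feats, f$carries_backbone, f$marker)
}

#' @export
print.gb_fragment <- function(x, ...) {
  cat(sprintf("<gb_fragment> %d bp from %s [%s ... %s]%s\n", nchar(x$seq),
              x$source, x$ovh5, x$ovh3,
              if (x$carries_backbone) sprintf(" backbone(%s)", x$marker) else ""))
  invisible(x)
}

#' Digest a record into sticky fragments
#'
#' Fragments partition the molecule: concatenating them in order while
#' overlapping the shared overhang tetramers reconstructs the input.
#' A record with zero sites raises an `inert_part_error` (flagged, not
#' fatal, for bystander parts in a pooled reaction).
#'
#' @inheritParams find_sites
#' @return list of `gb_fragment`.
#' @export
digest <- function(record, enzyme, grammar = default_grammar()) {
  e <- resolve_enzyme(enzyme, grammar)
  sites <- find_sites(record, e, grammar)
  if (nrow(sites) == 0L) {
    gb_abort("inert_part_error",
             sprintf("%s has no %s site", record$id, e$name))
  }
  seq <- record$sequence
  n <- nchar(seq)
  circular <- record$topology == "circular"
  k <- nrow(sites)
  frags <- list()
  has_marker_feature <- function(feats) any(feats$role == "marker")

  grab <- function(ct_i, flen_total) {
    ## virtual top strand starting at cut i, spanning flen_total letters
    fseq <- if (circular) seq_slice(seq, ct_i, ct_i + flen_total, circular = TRUE)
            else substr(seq, ct_i + 1L, ct_i + flen_total)
    ## collect parent features fully inside the window (vectorized)
    feats <- record$features
    kept <- empty_features()
    if (nrow(feats)) {
      fs <- feats$start; fe <- feats$end
      flen <- ifelse(fe >= fs, fe - fs, fe - fs + n)
      ls <- if (circular) (fs - ct_i) %% n else fs - ct_i
      keep <- ls >= 0L & (ls + flen) <= nchar(fseq)
      if (any(keep)) {
        kept <- data.frame(label = feats$label[keep], role = feats$role[keep],
                           start = as.integer(ls[keep]),
                           end = as.integer(ls[keep] + flen[keep]),
                           strand = feats$strand[keep], stringsAsFactors = FALSE)
      }
    }
    sticky_fragment(fseq, record$id, kept,
                    carries_backbone = has_marker_feature(kept),
                    marker = if (has_marker_feature(kept)) record$marker else NA_character_)
  }

  if (circular) {
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      span <- (sites$cut_top[j] - sites$cut_top[i]) %% n
      if (span == 0L) span <- n             # single cut: linearized full circle
      frags[[i]] <- grab(sites$cut_top[i], span + e$overhang_len)
    }
  } else {
    bounds <- c(0L, sites$cut_top, n)
    ## linear: terminal fragments have blunt/truncated ends and never religate
    for (i in seq_len(k + 1L)) {
      from <- bounds[i]
      to <- if (i <= k) sites$cut_bottom[i] else n
      frags[[i]] <- grab(from, to - from)
    }
  }
  frags
}

## Registry fixtures are digested over and over (pUPD2, destination vectors,
## level -1 plasmids); memoize their fragment lists per enzyme. The cache is
## validated against the full sequence, so a same-id record with different
## letters never hits it; features of registry parts are immutable per id.
.digest_cache <- new.env(parent = emptyenv())

digest_memo <- function(record, enzyme, grammar) {
  key <- paste(record$id, enzyme$name, sep = "\r")
  hit <- .digest_cache[[key]]
  if (!is.null(hit) && identical(hit$sequence, record$sequence) &&
      identical(hit$features, record$features)) {
    return(hit$frags)
  }
  frags <- digest(record, enzyme, grammar)
  .digest_cache[[key]] <- list(sequence = record$sequence,
                               features = record$features, frags = frags)
  frags
}

## OligoPair enters a reaction as a pre-cut fragment (never digested)
fragment_from_oligos <- function(pair) {
  v <- duplex_virtual_seq(pair)
  feats <- gb_feature(pair$core_label, pair$core_role, 4L, 4L + nchar(pair$core), "+")
  sticky_fragment(v, pair$name, feats)
}

## ---------------------------------------------------------------------------
## Ligation: cycle enumeration over the overhang-matching graph
## ---------------------------------------------------------------------------

#' Enumerate circular ligation products
#'
#' Joins fragments wherever a 3'-side overhang matches a 5'-side overhang
#' exactly (Watson-Crick, no mismatch tolerance), each fragment used at
#' most once per cycle in either orientation, and returns the circular
#' products that contain exactly one backbone-carrying fragment whose
#' marker matches `selection`. Products are canonicalized starting at the
#' backbone fragment, and rotationally duplicate cycles are merged.
#'
#' @param fragments list of `gb_fragment`.
#' @param selection marker token the product backbone must carry
#'   (`NULL` accepts any single-backbone cycle).
#' @return list of cycles; each cycle is a list of oriented
#'   `gb_fragment`s starting with the backbone. Empty list if no viable
#'   product.
#' @export
ligate <- function(fragments, selection = NULL) {
  if (!length(fragments)) return(list())
  is_bb <- vapply(fragments, function(f) isTRUE(f$carries_backbone), logical(1))
  sel_ok <- vapply(fragments, function(f) {
    isTRUE(f$carries_backbone) && (is.null(selection) || identical(f$marker, selection))
  }, logical(1))
  starts <- which(sel_ok)
  if (!length(starts)) return(list())
  cycles <- list()
  seen <- character(0)
  n <- length(fragments)
  flipped <- lapply(fragments, flip_fragment)   # orientation computed once
  for (s in starts) {
    root <- fragments[[s]]
    path <- list(root)
    used <- rep(FALSE, n); used[s] <- TRUE
    recurse <- function(path, used) {
      tail_ovh <- path[[length(path)]]$ovh3
      ## close the circle? (a single fragment may self-circularize)
      if (identical(tail_ovh, root$ovh5)) {
        key <- paste(vapply(path, function(f) f$seq, character(1)), collapse = "|")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- path
        }
      }
      for (i in seq_len(n)) {
        if (used[i]) next
        for (cand in list(fragments[[i]], flipped[[i]])) {
          if (cand$carries_backbone) next   # exactly one backbone: the root
          if (identical(cand$ovh5, tail_ovh)) {
            used2 <- used; used2[i] <- TRUE
            recurse(c(path, list(cand)), used2)
          }
        }
      }
    }
    recurse(path, used)
  }
  cycles
}

## Build the product sequence + remapped features for one cycle.
## Returns list(sequence, features, provenance).
assemble_cycle <- function(cycle, grammar = default_grammar()) {
  lens <- vapply(cycle, function(f) nchar(f$seq), integer(1))
  N <- sum(lens - 4L)
  pieces <- vapply(cycle, function(f) substr(f$seq, 5L, nchar(f$seq)), character(1))
  sequence <- paste(pieces, collapse = "")
  stopifnot(nchar(sequence) == N)
  rows <- vector("list", 2L * length(cycle))
  offset <- -4L
  for (idx in seq_along(cycle)) {
    f <- cycle[[idx]]
    if (nrow(f$features)) {
      s <- (offset + f$features$start) %% N
      e <- s + (f$features$end - f$features$start)
      e[e > N] <- e[e > N] - N          # wraps the origin
      rows[[2L * idx - 1L]] <- data.frame(label = f$features$label,
                                          role = f$features$role,
                                          start = as.integer(s), end = as.integer(e),
                                          strand = f$features$strand,
                                          stringsAsFactors = FALSE)
    }
    ## junction between this fragment and the next
    jpos <- (offset + nchar(f$seq) - 4L) %% N
    lab <- names(grammar$sites)[match(f$ovh3, grammar$sites)]
    if (is.na(lab)) lab <- "junction"
    jend <- jpos + 4L; if (jend > N) jend <- jend - N
    rows[[2L * idx]] <- gb_feature(lab, "fusion_site", jpos, jend, "+")
    offset <- offset + nchar(f$seq) - 4L
  }
  feats <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  feats <- unique(feats)   # junction sites may duplicate inherited annotations
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  rownames(feats) <- NULL
  list(sequence = sequence, features = feats,
       provenance = unique(vapply(cycle, function(f) f$source, character(1))))
}

## ---------------------------------------------------------------------------
## Full reaction
## ---------------------------------------------------------------------------

#' Simulate a Type IIS restriction-ligation reaction
#'
#' Digests the input parts (annealed oligo pairs pass through uncut as
#' pre-cut fragments), ligates, applies the destination's antibiotic
#' selection, discards any cycle still carrying a site of the reaction
#' enzyme (it would be re-cut), and demands exactly one surviving product.
#' Bystander parts with no site are reported in the diagnostics, never
#' silently dropped.
#'
#' @param parts list of `gb_part` and/or `gb_oligo_pair` inserts.
#' @param enzyme reaction enzyme name.
#' @param destination destination vector (`gb_part`) whose entry enzyme
#'   must equal `enzyme`.
#' @param grammar a `gb_grammar`.
#' @param product_id id for the predicted product.
#' @param level GoldenBraid level to stamp on the product.
#' @return a `gb_reaction` with fields `enzyme`, `inputs`, `destination`,
#'   `selection`, `products` (length 1), `diagnostics`.
#' @export
simulate_reaction <- function(parts, enzyme, destination,
                              grammar = default_grammar(),
                              product_id = paste0(destination$id, "_product"),
                              level = NA_character_) {
  e <- resolve_enzyme(enzyme, grammar)
  bb <- grammar$backbones[[destination$backbone]]
  if (is.null(bb) || !identical(bb$entry_enzyme, e$name)) {
    gb_abort("destination_mismatch_error",
             sprintf("destination %s (class %s) does not open with %s",
                     destination$id, destination$backbone, e$name))
  }
  if (inherits(parts, "gb_part") || inherits(parts, "gb_oligo_pair")) parts <- list(parts)
  fragments <- list(); bystanders <- character(0)
  for (p in c(parts, list(destination))) {
    if (inherits(p, "gb_oligo_pair")) {
      fragments <- c(fragments, list(fragment_from_oligos(p)))
    } else {
      fr <- tryCatch(digest_memo(p, e, grammar),
                     braidr_error = function(cond) {
                       if (inherits(cond, "inert_part_error")) {
                         bystanders <<- c(bystanders, p$id); NULL
                       } else stop(cond)
                     })
      fragments <- c(fragments, fr)
    }
  }
  selection <- destination$marker
  cycles <- ligate(fragments, selection = selection)

  recuttable <- list(); clean <- list(); clean_cycles <- list()
  for (cy in cycles) {
    asm <- assemble_cycle(cy, grammar)
    tmp <- part_record("candidate", asm$sequence, "circular")
    if (nrow(find_sites(tmp, e, grammar)) > 0L) {
      ## a re-cut cycle only matters if it actually joined different inputs;
      ## self-religation of one digested input is not a product candidate
      if (length(unique(vapply(cy, function(f) f$source, character(1)))) > 1L) {
        recuttable <- c(recuttable, list(asm))
      }
    } else {
      clean <- c(clean, list(asm))
      clean_cycles <- c(clean_cycles, list(cy))
    }
  }

  overhang_graph <- data.frame(
    fragment = vapply(fragments, function(f) f$source, character(1)),
    length = vapply(fragments, function(f) nchar(f$seq), integer(1)),
    ovh5 = vapply(fragments, function(f) f$ovh5, character(1)),
    ovh3 = vapply(fragments, function(f) f$ovh3, character(1)),
    backbone = vapply(fragments, function(f) isTRUE(f$carries_backbone), logical(1)),
    marker = vapply(fragments, function(f) f$marker %||% NA_character_, character(1)),
    stringsAsFactors = FALSE)

  if (length(clean) == 0L) {
    if (length(recuttable)) {
      gb_abort("recuttable_product_error",
               sprintf("every candidate product of %s retains a %s site and would be re-cut",
                       product_id, e$name),
               overhang_graph = overhang_graph)
    }
    gb_abort("no_product_error",
             sprintf("no circular product closes with selection '%s'", selection),
             overhang_graph = overhang_graph)
  }
  if (length(clean) > 1L) {
    ## deduplicate rotationally identical sequences before declaring ambiguity
    canon <- vapply(clean, function(a) canonical_rotation(a$sequence), character(1))
    clean <- clean[!duplicated(canon)]
    clean_cycles <- clean_cycles[!duplicated(canon)]
  }
  if (length(clean) > 1L) {
    gb_abort("ambiguous_assembly_error",
             sprintf("%d distinct products are selectable (interchangeable overhangs?)",
                     length(clean)),
             overhang_graph = overhang_graph)
  }
  asm <- clean[[1]]
  prod <- part_record(product_id, asm$sequence, "circular", level = level,
                      backbone = destination$backbone, marker = selection,
                      features = asm$features,
                      provenance = unique(c(vapply(parts, function(p) {
                        if (inherits(p, "gb_oligo_pair")) p$name else p$id
                      }, character(1)), destination$id)))

  ## downstream-risk flags: the partner enzyme's recognition inside a spacer
  flags <- character(0)
  for (other in grammar$enzymes) {
    if (identical(other$name, e$name)) next
    hits <- find_sites(prod, other, grammar)
    sp <- features_of(prod, "spacer")
    if (nrow(hits) && nrow(sp)) {
      for (i in seq_len(nrow(hits))) {
        inside <- sp$start <= hits$pos[i] & hits$pos[i] < sp$end
        if (any(inside)) {
          flags <- c(flags, sprintf(
            "%s recognition at %d lies inside spacer '%s'; the downstream %s reaction will fail",
            other$name, hits$pos[i], sp$label[inside][1L], other$name))
        }
      }
    }
  }
  cyc <- clean_cycles[[1]]
  product_cycle <- data.frame(
    source = vapply(cyc, function(f) f$source, character(1)),
    length = vapply(cyc, function(f) nchar(f$seq), integer(1)),
    ovh5 = vapply(cyc, function(f) f$ovh5, character(1)),
    ovh3 = vapply(cyc, function(f) f$ovh3, character(1)),
    stringsAsFactors = FALSE)
  structure(list(enzyme = e$name, inputs = parts, destination = destination,
                 selection = selection, products = list(prod),
                 diagnostics = list(overhang_graph = overhang_graph,
                                    product_cycle = product_cycle,
                                    bystanders = bystanders,
                                    n_candidate_cycles = length(cycles),
                                    n_recuttable_rejected = length(recuttable),
                                    flags = flags)),
            class = "gb_reaction")
}

#' @export
print.gb_reaction <- function(x, ...) {
  cat(sprintf("<gb_reaction> %s into %s (select %s): product %s, %d bp\n",
              x$enzyme, x$destination$id, x$selection,
              x$products[[1]]$id, nchar(x$products[[1]]$sequence)))
  if (length(x$diagnostics$flags)) cat("  flags:", paste(x$diagnostics$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize reaction diagnostics as JSON
#' @param reaction a `gb_reaction`.
#' @return JSON string.
#' @export
reaction_diagnostics_json <- function(reaction) {
  jsonlite::toJSON(reaction$diagnostics, auto_unbox = TRUE, dataframe = "rows")
}
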