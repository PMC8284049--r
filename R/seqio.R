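#' Part records: annotated DNA molecules
#'
#' A `gb_part` is an annotated circular or linear DNA molecule carrying its
#' GoldenBraid level, backbone class, selection marker, features, and
#' provenance (ids of the parts it was assembled from). Coordinates are
#' 0-based half-open on the top strand; a circular feature may wrap the
#' origin, in which case `end < start` and the interval is read modulo
#' length.
#'
#' Feature roles are a fixed vocabulary so that downstream counting
#' operations (how many transcriptional units? how many spacers?) are
#' unambiguous: `promoter`, `spacer`, `scaffold`, `tRNA`, `DR`, `HDV`,
#' `terminator`, `TU`, `fusion_site`, `marker`, `backbone`, `stuffer`,
#' `misc`.
#'
#' @param id part identifier.
#' @param sequence DNA string (A/C/G/T/N).
#' @param topology `"circular"` or `"linear"`.
#' @param level `"minus1"`, `"L0"`, `"L1"`, `"Lgt1"`, or `NA`.
#' @param backbone backbone class token (or `NA`).
#' @param marker selection-marker token (or `NA`).
#' @param features data.frame with columns `label`, `role`, `start`, `end`,
#'   `strand` (see [gb_feature()]).
#' @param provenance character vector of parent part ids.
#' @return a validated `gb_part`.
#' @export
part_record <- function(id, sequence, topology = c("circular", "linear"),
                        level = NA_character_, backbone = NA_character_,
                        marker = NA_character_, features = empty_features(),
                        provenance = character(0)) {
  topology <- match.arg(topology)
  sequence <- check_dna(sequence)
  n <- nchar(sequence)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    bad <- features$start < 0 | features$start >= n | features$end < 0 | features$end > n
    if (any(bad)) {
      gb_abort("format_error",
               sprintf("feature '%s' outside [0, %d)", features$label[bad][1L], n))
    }
    if (topology == "linear" && any(features$end < features$start)) {
      gb_abort("format_error", "wrap-around feature on a linear record")
    }
  }
  structure(list(id = id, level = level, backbone = backbone, marker = marker,
                 topology = topology, sequence = sequence,
                 features = features, provenance = provenance),
            class = "gb_part")
}

#' @export
print.gb_part <- function(x, ...) {
  cat(sprintf("<gb_part> %s: %d bp %s", x$id, nchar(x$sequence), x$topology))
  if (!is.na(x$level)) cat(sprintf(", level %s", x$level))
  if (!is.na(x$backbone)) cat(sprintf(", backbone %s", x$backbone))
  cat(sprintf("\n  %d feature(s)", nrow(x$features)))
  if (nrow(x$features)) {
    tab <- table(x$features$role)
    cat(": ", paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Build one feature row
#' @param label feature label.
#' @param role role token (see [part_record()]).
#' @param start,end 0-based half-open interval on the top strand.
#' @param strand `"+"` or `"-"`.
#' @export
gb_feature <- function(label, role, start, end, strand = "+") {
  data.frame(label = label, role = role, start = as.integer(start),
             end = as.integer(end), strand = strand, stringsAsFactors = FALSE)
}

empty_features <- function() {
  data.frame(label = character(0), role = character(0), start = integer(0),
             end = integer(0), strand = character(0), stringsAsFactors = FALSE)
}

## features of a given role, in top-strand order
features_of <- function(part, role) {
  f <- part$features[part$features$role %in% role, , drop = FALSE]
  f[order(f$start), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## GenBank flat-file dialect: single record, uppercase sequence, features as
## simple ranges. A circular wrap-around feature is split at the origin into
## two ranges tagged /gb_wrap="a" / "b" on write and re-merged on read.
## ---------------------------------------------------------------------------

#' Write a part record as a GenBank flat file
#'
#' @param record a `gb_part`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  if (!inherits(record, "gb_part")) gb_abort("format_error", "not a gb_part")
  n <- nchar(record$sequence)
  name <- gsub("[^A-Za-z0-9_.-]", "_", record$id)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %-8s UNA       01-JAN-2026",
            substr(name, 1, 16), n,
            if (record$topology == "circular") "circular" else "linear"),
    sprintf("DEFINITION  %s.", record$id),
    sprintf("ACCESSION   %s", name),
    sprintf("COMMENT     gb_level: %s", record$level),
    sprintf("COMMENT     gb_backbone: %s", record$backbone),
    sprintf("COMMENT     gb_marker: %s", record$marker),
    sprintf("COMMENT     gb_provenance: %s",
            if (length(record$provenance)) paste(record$provenance, collapse = ",") else "NA"),
    "FEATURES             Location/Qualifiers"
  )
  feats <- record$features
  if (nrow(feats)) {
    for (i in seq_len(nrow(feats))) {
      f <- feats[i, ]
      pieces <- if (f$end >= f$start) {
        list(c(f$start, f$end, NA))
      } else {
        list(c(f$start, n, "a"), c(0L, f$end, "b"))  # split wrap at origin
      }
      for (p in pieces) {
        s1 <- as.integer(p[[1]]) + 1L; e1 <- as.integer(p[[2]])  # 1-based inclusive
        loc <- sprintf("%d..%d", s1, e1)
        if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
        lines <- c(lines,
                   sprintf("     misc_feature    %s", loc),
                   sprintf("                     /label=\"%s\"", f$label),
                   sprintf("                     /gb_role=\"%s\"", f$role))
        if (!is.na(p[[3]])) {
          lines <- c(lines, sprintf("                     /gb_wrap=\"%s\"", p[[3]]))
        }
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  if (n > 0L) {
    seq <- tolower(record$sequence)
    block_start <- seq(1L, n, by = 10L)                     # 10-nt blocks
    blocks <- substring(seq, block_start, pmin(block_start + 9L, n))
    grp <- (block_start - 1L) %/% 60L                       # 6 blocks per row
    rows <- split(blocks, factor(grp, levels = unique(grp)))
    row_start <- seq(1L, n, by = 60L)
    lines <- c(lines, sprintf("%9d %s", row_start,
                              vapply(rows, paste, character(1), collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank flat file into a part record
#'
#' Accepts standard single-record flat files with a LOCUS topology field.
#' Raises a `format_error` with line context on unparseable input, and on
#' features extending beyond the sequence of a linear record.
#'
#' @param path path to a GenBank file.
#' @return a `gb_part`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) gb_abort("format_error", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  fail <- function(i, why) {
    gb_abort("format_error",
             sprintf("%s at line %d: %s", why, i,
                     if (i <= length(lines)) lines[i] else "<eof>"))
  }
  locus_i <- grep("^LOCUS", lines)[1]
  if (is.na(locus_i)) fail(1L, "missing LOCUS line")
  locus <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  if (length(locus) < 3L) fail(locus_i, "malformed LOCUS line")
  name <- locus[2]
  len <- suppressWarnings(as.integer(locus[3]))
  if (is.na(len)) fail(locus_i, "malformed LOCUS length")
  topology <- if (any(grepl("circular", locus, ignore.case = TRUE))) "circular" else "linear"

  meta <- c(level = NA_character_, backbone = NA_character_, marker = NA_character_)
  provenance <- character(0)
  for (ln in grep("^COMMENT", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("gb_(level|backbone|marker|provenance):\\s*(\\S.*)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- trimws(m[3])
      if (m[2] == "provenance") {
        if (val != "NA") provenance <- strsplit(val, ",")[[1]]
      } else if (val != "NA") meta[[m[2]]] <- val
    }
  }

  feat_i <- grep("^FEATURES", lines)[1]
  orig_i <- grep("^ORIGIN", lines)[1]
  if (is.na(orig_i)) fail(length(lines), "missing ORIGIN section")

  ## --- features ---
  feats <- empty_features(); wrap_tag <- character(0)
  if (!is.na(feat_i)) {
    i <- feat_i + 1L
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return()
      feats <<- rbind(feats, gb_feature(cur$label %||% "feature", cur$role %||% "misc",
                                        cur$start, cur$end, cur$strand))
      wrap_tag <<- c(wrap_tag, cur$wrap %||% NA_character_)
    }
    while (i < orig_i) {
      ln <- lines[i]
      if (grepl("^\\s{1,10}\\S", ln) && !grepl("^\\s+/", ln)) {
        flush(cur)
        loc <- trimws(sub("^\\s*\\S+\\s+", "", ln))
        strand <- "+"
        if (grepl("^complement\\(", loc)) {
          strand <- "-"
          loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
        if (length(m) != 3L) {
          m1 <- regmatches(loc, regexec("^(\\d+)$", loc))[[1]]
          if (length(m1) == 2L) m <- c(m1[1], m1[2], m1[2]) else fail(i, "unparseable feature location")
        }
        cur <- list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]), strand = strand)
        if (cur$end > len || cur$start < 0L) fail(i, "feature range beyond sequence length")
      } else if (grepl("^\\s+/", ln)) {
        q <- regmatches(ln, regexec("/([A-Za-z_]+)=\"?([^\"]*)\"?", ln))[[1]]
        if (length(q) == 3L && !is.null(cur)) {
          if (q[2] == "label") cur$label <- q[3]
          if (q[2] == "gb_role") cur$role <- q[3]
          if (q[2] == "gb_wrap") cur$wrap <- q[3]
        }
      } else if (!nzchar(trimws(ln))) {
        # blank line, skip
      } else fail(i, "unexpected line in FEATURES block")
      i <- i + 1L
    }
    flush(cur)
  }

  ## --- sequence ---
  term_i <- grep("^//", lines)
  term_i <- if (length(term_i)) term_i[term_i > orig_i][1] else NA_integer_
  last_i <- if (is.na(term_i)) length(lines) else term_i - 1L
  seq_lines <- if (last_i > orig_i) lines[(orig_i + 1L):last_i] else character(0)
  sequence <- toupper(paste(gsub("[^A-Za-z]", "", seq_lines), collapse = ""))
  if (nchar(sequence) != len) {
    fail(orig_i, sprintf("sequence length %d disagrees with LOCUS length %d",
                         nchar(sequence), len))
  }

  ## --- re-merge origin-split wrap features ---
  if (nrow(feats) && any(!is.na(wrap_tag))) {
    keep <- rep(TRUE, nrow(feats))
    for (i1 in which(wrap_tag == "a")) {
      j <- which(wrap_tag == "b" & feats$label == feats$label[i1] &
                   feats$role == feats$role[i1] & keep)
      if (length(j)) {
        j <- j[1]
        feats$end[i1] <- feats$end[j]
        keep[j] <- FALSE
      }
    }
    feats <- feats[keep, , drop = FALSE]
    rownames(feats) <- NULL
  }

  part_record(id = name, sequence = sequence, topology = topology,
              level = meta[["level"]], backbone = meta[["backbone"]],
              marker = meta[["marker"]], features = feats, provenance = provenance)
}

## ---------------------------------------------------------------------------
## Oligo pairs
## ---------------------------------------------------------------------------

#' Construct an annealed oligonucleotide pair
#'
#' Two partially complementary oligos that anneal into a duplex with 4-nt
#' 5' protrusions on both ends, ready to enter a Type IIS
#' restriction-ligation reaction uncut. `forward` is the top strand
#' (5' protrusion + core), `reverse` the bottom strand (reverse complement
#' of core + 3'-side protrusion). The double-stranded core carries the
#' spacer.
#'
#' @param name pair name.
#' @param forward,reverse oligo sequences 5'->3'.
#' @param overhang_5p,overhang_3p the two protrusions, in top-strand
#'   letters.
#' @param core_role feature role annotated on the duplex core.
#' @param core_label feature label for the core.
#' @return a `gb_oligo_pair`.
#' @export
oligo_pair <- function(name, forward, reverse, overhang_5p, overhang_3p,
                       core_role = "spacer", core_label = name) {
  forward <- check_dna(forward, "forward oligo")
  reverse <- check_dna(reverse, "reverse oligo")
  overhang_5p <- check_dna(overhang_5p); overhang_3p <- check_dna(overhang_3p)
  if (nchar(overhang_5p) != 4L || nchar(overhang_3p) != 4L) {
    gb_abort("oligo_error", "both protrusions must be exactly 4 nt (5' overhangs)")
  }
  if (substr(forward, 1L, 4L) != overhang_5p) {
    gb_abort("oligo_error", "forward oligo must start with the 5' protrusion")
  }
  core <- substr(forward, 5L, nchar(forward))
  if (!identical(revcomp(reverse), paste0(core, overhang_3p))) {
    gb_abort("oligo_error",
             "reverse oligo must be the reverse complement of core + 3' protrusion")
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 duplex_overhang_5p = overhang_5p, duplex_overhang_3p = overhang_3p,
                 core = core, core_role = core_role, core_label = core_label),
            class = "gb_oligo_pair")
}

## duplex as virtual top strand including both overhang regions
duplex_virtual_seq <- function(pair) paste0(pair$forward, pair$duplex_overhang_3p)

#' @export
print.gb_oligo_pair <- function(x, ...) {
  cat(sprintf("<gb_oligo_pair> %s\n  fwd 5'-%s-3' (%d nt)\n  rev 5'-%s-3' (%d nt)\n",
              x$name, x$forward, nchar(x$forward), x$reverse, nchar(x$reverse)))
  cat(sprintf("  protrusions %s / %s, core %d nt\n",
              x$duplex_overhang_5p, x$duplex_overhang_3p, nchar(x$core)))
  invisible(x)
}

#' Write an oligo order sheet
#'
#' One CSV row per oligo (two per pair), with columns `name`, `sequence`,
#' `length` -- the 2xN synthesis order of a multiplex design.
#'
#' @param pairs non-empty list of `gb_oligo_pair`.
#' @param path output CSV path.
#' @return the sheet as a data.frame, invisibly.
#' @export
write_oligo_sheet <- function(pairs, path) {
  if (inherits(pairs, "gb_oligo_pair")) pairs <- list(pairs)
  if (length(pairs) == 0L) gb_abort("empty_input_error", "no oligo pairs to write")
  rows <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(name = c(paste0(p$name, "_F"), paste0(p$name, "_R")),
               sequence = c(p$forward, p$reverse),
               length = c(nchar(p$forward), nchar(p$reverse)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}

## ---------------------------------------------------------------------------
## Protocol rendering
## ---------------------------------------------------------------------------

#' Render a laboratory protocol from a chain of simulated reactions
#'
#' One numbered step per reaction, naming the enzyme, the input parts, the
#' destination backbone and its selection marker. The reagent table maps
#' every part id to its role and backbone marker.
#'
#' @param reactions a `gb_reaction` or list of them, in execution
#'   (provenance/topological) order.
#' @param title protocol title.
#' @return a `gb_protocol` with fields `title`, `steps`, `enzymes`,
#'   `reagents`.
#' @export
render_protocol <- function(reactions, title = "GoldenBraid assembly protocol") {
  if (inherits(reactions, "gb_reaction")) reactions <- list(reactions)
  if (length(reactions) == 0L) gb_abort("empty_input_error", "empty reaction chain")
  steps <- character(0); enzymes <- character(0); reagents <- NULL
  for (k in seq_along(reactions)) {
    rx <- reactions[[k]]
    prod <- rx$products[[1]]
    inputs <- vapply(rx$inputs, function(p) {
      if (inherits(p, "gb_oligo_pair")) sprintf("annealed oligos %s", p$name) else p$id
    }, character(1))
    steps <- c(steps, sprintf(
      "Step %d: %s restriction-ligation of %s into %s (%s); select on %s. Product: %s (%d bp).",
      k, rx$enzyme, paste(inputs, collapse = " + "),
      rx$destination$id, rx$destination$backbone, rx$selection, prod$id,
      nchar(prod$sequence)))
    enzymes <- c(enzymes, rx$enzyme)
    reagents <- rbind(reagents, do.call(rbind, lapply(rx$inputs, function(p) {
      if (inherits(p, "gb_oligo_pair")) {
        data.frame(part_id = p$name, role = "annealed oligo duplex",
                   marker = NA_character_, stringsAsFactors = FALSE)
      } else {
        data.frame(part_id = p$id,
                   role = sprintf("%s part", p$level %||% "DNA"),
                   marker = p$marker, stringsAsFactors = FALSE)
      }
    })), data.frame(part_id = rx$destination$id, role = "destination vector",
                    marker = rx$destination$marker, stringsAsFactors = FALSE))
  }
  reagents <- unique(reagents)
  rownames(reagents) <- NULL
  structure(list(title = title, steps = steps, enzymes = enzymes,
                 reagents = reagents),
            class = "gb_protocol")
}

#' @export
print.gb_protocol <- function(x, ...) {
  cat("#", x$title, "\n\n")
  for (s in x$steps) cat(s, "\n")
  invisible(x)
}

#' Write a protocol as a markdown document
#' @param doc a `gb_protocol`.
#' @param path output path.
#' @export
write_protocol <- function(doc, path) {
  lines <- c(paste("#", doc$title), "", "## Steps", "",
             paste0(seq_along(doc$steps), ". ", doc$steps), "",
             "## Reagents", "",
             "| part | role | marker |", "|---|---|---|",
             sprintf("| %s | %s | %s |", doc$reagents$part_id, doc$reagents$role,
                     ifelse(is.na(doc$reagents$marker), "-", doc$reagents$marker)))
  writeLines(lines, path)
  invisible(path)
}
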