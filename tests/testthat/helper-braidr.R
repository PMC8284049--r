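## Shared test helpers: independent oracles and random-record generators.

GRAMMAR <- default_grammar()

## design helpers with the 5'-G advisory silenced (spacers are random)
quiet <- function(expr) suppressWarnings(expr)

## ---------------------------------------------------------------------------
## Brute-force ligation oracle, independent of ligate():
## enumerate every subset containing exactly one backbone fragment, every
## ordering of the remaining fragments, and every orientation assignment;
## keep closed circles. Returns a character set of product sequences
## (canonical: starting at the backbone fragment, first overhang dropped).
## ---------------------------------------------------------------------------
bf_flip <- function(f) {
  n <- nchar(f$seq)
  rc <- revcomp(f$seq)
  list(seq = rc, ovh5 = substr(rc, 1, 4), ovh3 = substr(rc, n - 3, n),
       carries_backbone = f$carries_backbone, marker = f$marker)
}

bf_products <- function(fragments, selection = NULL) {
  is_bb <- vapply(fragments, function(f) isTRUE(f$carries_backbone), logical(1))
  roots <- which(is_bb & vapply(fragments, function(f)
    is.null(selection) || identical(f$marker, selection), logical(1)))
  inserts <- which(!is_bb)
  out <- character(0)
  perms <- function(v) {
    if (!length(v)) return(list(integer(0)))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (root in roots) {
    rf <- fragments[[root]]
    for (sub in subsets(inserts)) {
      for (ord in perms(sub)) {
        k <- length(ord)
        for (mask in seq_len(max(1L, 2L^k)) - 1L) {
          chain <- list(rf)
          for (j in seq_len(k)) {
            f <- fragments[[ord[j]]]
            if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) f <- bf_flip(f)
            chain <- c(chain, list(f))
          }
          ok <- TRUE
          for (j in seq_len(length(chain) - 1L)) {
            if (!identical(chain[[j]]$ovh3, chain[[j + 1L]]$ovh5)) { ok <- FALSE; break }
          }
          if (ok && identical(chain[[length(chain)]]$ovh3, chain[[1]]$ovh5)) {
            segs <- vapply(chain, function(f) substr(f$seq, 5, nchar(f$seq)), character(1))
            out <- c(out, paste(segs, collapse = ""))
          }
        }
      }
    }
  }
  unique(out)
}

## make a bare sticky fragment for toy ligation tests
toy_frag <- function(core, ovh5, ovh3, backbone = FALSE, marker = NA_character_,
                     source = "toy") {
  seq <- paste0(ovh5, core, ovh3)
  f <- list(seq = seq, ovh5 = ovh5, ovh3 = ovh3, source = source,
            features = if (backbone) gb_feature("M", "marker", 6L, 10L, "+")
                       else gb_feature(source, "misc", 4L, nchar(seq) - 4L, "+"),
            carries_backbone = backbone, marker = marker)
  class(f) <- "gb_fragment"
  f
}

## random DNA (test-local; no site avoidance unless asked)
rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

## random annotated part record for GenBank round-trip properties
random_record <- function(len = sample(100:20000, 1), topology = sample(c("circular", "linear"), 1)) {
  seq <- rnd_dna(len)
  nfeat <- sample(0:6, 1)
  feats <- empty_features()
  if (nfeat > 0) {
    for (i in seq_len(nfeat)) {
      s <- sample(0:(len - 1L), 1)
      w <- sample(1:min(len, 500L), 1)
      e <- s + w
      if (topology == "linear") e <- min(e, len)
      else if (e > len) e <- e - len          # wrap-around feature
      if (e == s) e <- min(s + 1L, len)
      feats <- rbind(feats, gb_feature(sprintf("f%d", i),
                                       sample(c("promoter", "spacer", "TU", "misc"), 1),
                                       s, e, sample(c("+", "-"), 1)))
    }
  }
  part_record(sprintf("rnd_%d", sample(1e6, 1)), seq, topology, features = feats)
}

expect_braidr_error <- function(expr, class) {
  expect_error(expr, class = class)
}

## length conservation + irreversibility checks applied to a reaction
check_reaction_invariants <- function(rx, grammar = GRAMMAR) {
  prod <- rx$products[[1]]
  og <- rx$diagnostics$overhang_graph
  ## the product is one cycle: its length is the sum of the used fragment
  ## lengths minus 4 nt per junction; verify via re-digestion instead of
  ## trusting internals: re-digest must find no site of the reaction enzyme
  expect_error(digest(prod, rx$enzyme, grammar), class = "inert_part_error")
  invisible(rx)
}
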