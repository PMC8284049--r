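test_that("find_sites computes cut coordinates from offset and overhang", {
  ## no recognition on either strand -> no sites
  blank <- part_record("blank", strrep("AC", 25), "linear")
  expect_identical(nrow(find_sites(blank, "BsaI")), 0L)

  ## 30-nt linear toy, GGTCTC at index 2: hand-computed index arithmetic
  ## recognition [2,8), spacer N at 8, top cut at 9, bottom cut at 13
  toy <- part_record("toy", paste0("AT", "GGTCTC", "A", rnd_dna(21)), "linear")
  s <- find_sites(toy, "BsaI")
  expect_identical(nrow(s), 1L)
  expect_identical(s$pos, 2L)
  expect_identical(s$strand, "+")
  expect_identical(s$cut_top, 9L)
  expect_identical(s$cut_bottom, 13L)

  ## bottom-strand site: GAGACC at index 10 cuts upstream of the recognition
  toyb <- part_record("toyb", paste0(rnd_dna(10), "GAGACC", rnd_dna(10)), "linear")
  sb <- find_sites(toyb, "BsaI")
  expect_identical(nrow(sb), 1L)
  expect_identical(sb$strand, "-")
  expect_identical(sb$cut_top, 5L)     # 10 - 1 - 4
  expect_identical(sb$cut_bottom, 9L)  # 10 - 1

  ## recognition split across the origin of a circular record is still found
  circ <- part_record("circ", paste0("TC", strrep("CA", 20), "GGTC"), "circular")
  expect_identical(nrow(find_sites(circ, "BsaI")), 1L)
  ## the same letters on a linear record: no site
  expect_identical(nrow(find_sites(part_record("lin", circ$sequence, "linear"),
                                   "BsaI")), 0L)
})

test_that("digest partitions the molecule and re-concatenation reconstructs it", {
  g <- GRAMMAR
  ## circular plasmid with 2 same-orientation sites -> 2 fragments
  core1 <- rnd_dna(60); core2 <- rnd_dna(90)
  seq <- paste0("GGTCTCA", core1, "GGTCTCA", core2)
  p <- part_record("twosite", seq, "circular")
  fr <- digest(p, "BsaI", g)
  expect_length(fr, 2L)
  ## each overhang counted once: sum of (len - overhang) equals plasmid length
  expect_identical(sum(vapply(fr, function(f) nchar(f$seq) - 4L, integer(1))),
                   nchar(seq))
  ## re-concatenation oracle: joining on the shared tetramers rebuilds a
  ## rotation of the input
  joined <- paste0(substr(fr[[1]]$seq, 5, nchar(fr[[1]]$seq)),
                   substr(fr[[2]]$seq, 5, nchar(fr[[2]]$seq)))
  expect_true(grepl(joined, strrep(seq, 2), fixed = TRUE))
  expect_identical(fr[[1]]$ovh3, fr[[2]]$ovh5)
  expect_identical(fr[[2]]$ovh3, fr[[1]]$ovh5)

  ## single site on a circular molecule -> one linearized fragment
  p1 <- part_record("onesite", paste0("GGTCTCA", rnd_dna(50)), "circular")
  fr1 <- digest(p1, "BsaI", g)
  expect_length(fr1, 1L)
  expect_identical(nchar(fr1[[1]]$seq), nchar(p1$sequence) + 4L)
  expect_identical(fr1[[1]]$ovh5, fr1[[1]]$ovh3)

  ## zero sites -> inert part
  expect_braidr_error(digest(part_record("inert", strrep("AC", 40), "circular"), "BsaI", g),
                      "inert_part_error")
})

test_that("ligate agrees with brute-force enumeration and flags ambiguity", {
  bb <- toy_frag(rnd_dna(40), "CGCT", "GGAG", backbone = TRUE, marker = "kan", source = "bb")
  i1 <- toy_frag(rnd_dna(20), "GGAG", "ATTG", source = "i1")
  i2 <- toy_frag(rnd_dna(25), "ATTG", "CGCT", source = "i2")

  ## backbone(A..B) + insert chain (B..A): exactly one product
  frs <- list(bb, i1, i2)
  cycles <- ligate(frs, selection = "kan")
  expect_length(cycles, 1L)
  got <- paste(vapply(cycles[[1]], function(f) substr(f$seq, 5, nchar(f$seq)),
                      character(1)), collapse = "")
  expect_identical(sort(got), sort(bf_products(frs, "kan")))
  expect_identical(nchar(got), sum(vapply(frs, function(f) nchar(f$seq) - 4L, integer(1))))

  ## no complementary overhangs -> no product
  expect_length(ligate(list(bb, toy_frag(rnd_dna(20), "TACA", "CCAT")), "kan"), 0L)

  ## two interchangeable inserts with identical flanks -> >= 2 products
  j1 <- toy_frag(rnd_dna(20), "GGAG", "CGCT", source = "j1")
  j2 <- toy_frag(rnd_dna(22), "GGAG", "CGCT", source = "j2")
  amb <- ligate(list(bb, j1, j2), "kan")
  expect_gte(length(amb), 2L)
  expect_setequal(
    vapply(amb, function(cy) paste(vapply(cy, function(f)
      substr(f$seq, 5, nchar(f$seq)), character(1)), collapse = ""), character(1)),
    bf_products(list(bb, j1, j2), "kan"))
})

test_that("ligate equals the brute-force oracle on randomized <=6-fragment pools", {
  set.seed(99)
  sites <- unname(GRAMMAR$sites)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    ovh <- sample(sites, k + 1, replace = FALSE)
    frs <- list(toy_frag(rnd_dna(30), ovh[k + 1], ovh[1], backbone = TRUE,
                         marker = "kan", source = "bb"))
    for (j in seq_len(k)) {
      ## mostly chainable fragments, sometimes scrambled ends
      o5 <- if (stats::runif(1) < 0.8) ovh[j] else sample(sites, 1)
      o3 <- if (stats::runif(1) < 0.8) ovh[j + 1] else sample(sites, 1)
      frs <- c(frs, list(toy_frag(rnd_dna(sample(15:40, 1)), o5, o3,
                                  source = paste0("f", j))))
    }
    got <- vapply(ligate(frs, "kan"), function(cy)
      paste(vapply(cy, function(f) substr(f$seq, 5, nchar(f$seq)), character(1)),
            collapse = ""), character(1))
    expect_setequal(got, bf_products(frs, "kan"))
  }
})

test_that("simulate_reaction demands a unique selectable uncuttable product", {
  g <- GRAMMAR
  ## the Level 0 guide build: oligo duplex + level -1 plasmid into pUPD2
  ol <- quiet(design_multi_cas9_oligos(random_spacer("Cas9", seed = 21), "g1"))
  rx <- simulate_reaction(list(ol, registry_lookup("trna_scaffold_pos1")),
                          "BsmBI", registry_lookup("pUPD2"), g,
                          product_id = "g1_L0", level = "L0")
  prod <- rx$products[[1]]
  expect_identical(prod$topology, "circular")
  expect_identical(prod$marker, "chloramphenicol")
  expect_identical(sum(prod$features$role == "marker"), 1L)   # exactly one backbone
  ## irreversibility: the product has no remaining site of the reaction enzyme
  check_reaction_invariants(rx)
  ## bystanders are reported, never silently dropped
  rx2 <- simulate_reaction(list(ol, registry_lookup("trna_scaffold_pos1"),
                                part_record("bystander", strrep("AG", 30), "circular")),
                           "BsmBI", registry_lookup("pUPD2"), g)
  expect_identical(rx2$diagnostics$bystanders, "bystander")

  ## overhangs that cannot close a circle
  expect_braidr_error(
    simulate_reaction(list(registry_lookup("pol3_promoter_single")),
                      "BsaI", registry_lookup("alpha1"), g),
    "no_product_error")

  ## wrong destination enzyme
  expect_braidr_error(
    simulate_reaction(list(ol), "BsaI", registry_lookup("pUPD2"), g),
    "destination_mismatch_error")
})

test_that("a partner-enzyme site inside a spacer is reported, flagged for downstream failure", {
  ## hand-built duplex whose 20-nt core contains a BsaI recognition
  s <- GRAMMAR$sites
  core <- paste0("GGTCTC", "ATATATATATATAT")   # 20 nt
  ol <- oligo_pair("bad", paste0(s[["TRNA_SPACER"]], core),
                   revcomp(paste0(core, s[["GUIDE_SCAFFOLD"]])),
                   s[["TRNA_SPACER"]], s[["GUIDE_SCAFFOLD"]], core_label = "bad_sp")
  rx <- simulate_reaction(list(ol, registry_lookup("trna_scaffold_pos1_term")),
                          "BsmBI", registry_lookup("pUPD2"), GRAMMAR)
  expect_length(rx$products, 1L)               # the BsmBI step itself succeeds
  expect_true(any(grepl("BsaI", rx$diagnostics$flags)))
  expect_true(any(grepl("bad_sp", rx$diagnostics$flags)))
  ## and the downstream BsaI array assembly indeed fails on this guide:
  ## religating the internal cut restores the site, so every candidate is
  ## re-cuttable
  expect_braidr_error(
    assemble_cas9_array(list(rx$products[[1]])),
    "recuttable_product_error")
})

test_that("length conservation and irreversibility hold across randomized assemblies", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(1:4, 1)
    tu <- quiet(design_cas9_array(random_spacers(n, "Cas9", seed = 700 + i),
                                  destination = "alpha2"))
    rxs <- attr(tu, "reactions")
    for (rx in rxs) {
      prod <- rx$products[[1]]
      cyc <- rx$diagnostics$product_cycle
      ## len(product) = sum(fragment lengths) - junctions x overhang_len
      expect_identical(nchar(prod$sequence),
                       sum(cyc$length) - 4L * nrow(cyc))
      ## every junction anneals exactly
      expect_identical(cyc$ovh3, c(cyc$ovh5[-1], cyc$ovh5[1]))
      check_reaction_invariants(rx)
    }
  }
})
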