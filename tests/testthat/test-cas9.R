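test_that("the single-Cas9 domesticator accepts exactly 20-nt spacers", {
  accepted <- integer(0)
  for (len in 15:30) {
    sp <- random_sitefree_dna(len, seed = 1000 + len)
    ok <- tryCatch({ quiet(design_single_cas9_oligos(sp)); TRUE },
                   spacer_length_error = function(e) FALSE)
    if (ok) accepted <- c(accepted, len)
  }
  expect_identical(accepted, 20L)
  expect_braidr_error(quiet(design_single_cas9_oligos(strrep("G", 19))),
                      "spacer_length_error")
})

test_that("domestication rejects internal Type IIS sites, naming enzyme and offset", {
  bad <- paste0("GATT", "GAGACG", strrep("AT", 5))    # BsmBI bottom strand, 20 nt
  err <- tryCatch(quiet(design_multi_cas9_oligos(bad)), braidr_error = identity)
  expect_s3_class(err, "forbidden_site_error")
  expect_match(conditionMessage(err), "BsmBI")
  expect_match(conditionMessage(err), "4")            # offset of the hit
  bad2 <- paste0("GATT", "GGTCTC", strrep("AT", 5))   # BsaI top strand
  expect_braidr_error(quiet(design_single_cas9_oligos(bad2)), "forbidden_site_error")
})

test_that("a spacer without a leading G triggers the advisory, unmodified", {
  sp <- random_spacer("Cas9", seed = 31)
  sp$sequence <- paste0("A", substr(sp$sequence, 2, 20))
  expect_warning(ol <- design_single_cas9_oligos(sp), class = "five_prime_g_warning")
  expect_identical(substr(ol$forward, 5, 24), sp$sequence)   # never edited
})

test_that("single-guide assembly places the spacer scarlessly between promoter and scaffold", {
  sp <- random_spacer("Cas9", seed = 17)
  ol <- quiet(design_single_cas9_oligos(sp, "gX"))
  expect_identical(ol$core, sp$sequence)
  tu <- assemble_single_cas9(ol, destination = "alpha2")
  expect_identical(tu$level, "L1")
  expect_identical(sum(tu$features$role == "spacer"), 1L)
  ## substring oracle: spacer occurs exactly once, directly followed by the
  ## scaffold (no scar)
  expect_identical(length(gregexpr(sp$sequence, tu$sequence, fixed = TRUE)[[1]]), 1L)
  scaffold <- registry_lookup("cas9_scaffold")
  scaf_feat <- scaffold$features[scaffold$features$role == "scaffold", ]
  scaf_seq <- substr(scaffold$sequence, scaf_feat$start + 1, scaf_feat$end)
  expect_true(grepl(paste0(sp$sequence, scaf_seq), tu$sequence, fixed = TRUE))
  ## omega destinations are rejected
  expect_braidr_error(assemble_single_cas9(ol, destination = "omega1"),
                      "destination_mismatch_error")
})

test_that("multiplex oligos are position-independent and core == spacer", {
  sps <- random_spacers(30, "Cas9", seed = 55)
  for (sp in sps) {
    ol <- quiet(design_multi_cas9_oligos(sp))
    expect_identical(ol$core, sp$sequence)               # string-equality oracle
  }
  ## the same oligo pair assembled at two positions yields identical mature
  ## guides after processing (reusability)
  ol <- quiet(design_multi_cas9_oligos(sps[[1]]))
  others <- lapply(2:3, function(k) quiet(design_multi_cas9_oligos(sps[[k]])))
  arr_a <- assemble_cas9_array(list(
    build_guide_L0(ol, 1), build_guide_L0(others[[1]], 2),
    build_guide_L0(others[[2]], 3, terminal = TRUE)), destination = "alpha1")
  arr_b <- assemble_cas9_array(list(
    build_guide_L0(others[[1]], 1), build_guide_L0(ol, 2),
    build_guide_L0(others[[2]], 3, terminal = TRUE)), destination = "alpha1")
  ga <- process_transcript(arr_a); gb <- process_transcript(arr_b)
  expect_identical(ga$sequence[ga$spacer == sps[[1]]$name],
                   gb$sequence[gb$spacer == sps[[1]]$name])
})

test_that("Level 0 guides encode their position in the fusion sites", {
  ol <- quiet(design_multi_cas9_oligos(random_spacer("Cas9", seed = 61), "gP"))
  p1 <- build_guide_L0(ol, 1)
  p2 <- build_guide_L0(ol, 2)
  expect_false(identical(p1$sequence, p2$sequence))
  ## the two parts differ only in their position fusion sites: masking the
  ## annotated POS tetramers leaves identical sequences
  mask_pos <- function(p) {
    f <- p$features[p$features$role == "fusion_site" & grepl("^POS", p$features$label), ]
    s <- p$sequence
    for (i in seq_len(nrow(f))) substr(s, f$start[i] + 1L, f$end[i]) <- "NNNN"
    s
  }
  expect_identical(mask_pos(p1), mask_pos(p2))
  expect_braidr_error(build_guide_L0(ol, 7), "position_error")
  expect_braidr_error(build_guide_L0(ol, 0), "position_error")
})

test_that("aptamer guides carry the MS2-extended scaffold", {
  ol <- quiet(design_multi_cas9_oligos(random_spacer("Cas9", seed = 62), "gA"))
  p <- build_guide_L0(ol, 1, scaffold_kind = "aptamer", terminal = TRUE)
  scafs <- p$features[p$features$role == "scaffold", ]
  expect_match(scafs$label, "MS2")
  expect_true("MS2_aptamer" %in% p$features$label)
  ## aptamer arrays are capped at 3 units
  expect_braidr_error(build_guide_L0(ol, 4, scaffold_kind = "aptamer"),
                      "position_error")
})

test_that("array assembly enforces capacity, consecutiveness and a terminal unit", {
  sps <- random_spacers(3, "Cas9", seed = 63)
  ols <- lapply(sps, function(s) quiet(design_multi_cas9_oligos(s)))
  g1 <- build_guide_L0(ols[[1]], 1)
  g2 <- build_guide_L0(ols[[2]], 2)
  g3t <- build_guide_L0(ols[[3]], 3, terminal = TRUE)
  arr <- assemble_cas9_array(list(g1, g2, g3t), destination = "alpha2")
  sp_feats <- arr$features[arr$features$role == "spacer", ]
  sp_feats <- sp_feats[order(sp_feats$start), ]
  expect_identical(sp_feats$label, vapply(sps, `[[`, character(1), "name"))
  ## 7 units exceed capacity
  expect_braidr_error(assemble_cas9_array(rep(list(g1), 7)), "capacity_error")
  ## positions 1,3 leave a gap
  g3 <- build_guide_L0(ols[[3]], 3, terminal = TRUE)
  expect_braidr_error(assemble_cas9_array(list(g1, g3)), "position_gap_error")
  ## a non-terminal last unit is rejected
  expect_braidr_error(assemble_cas9_array(list(g1, g2)), "position_gap_error")
  ## 7 spacers through the one-call pipeline
  expect_braidr_error(quiet(design_cas9_array(random_spacers(7, "Cas9", seed = 64))),
                      "capacity_error")
})
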