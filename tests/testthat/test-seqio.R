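test_that("GenBank write/read round-trips sequence, topology and features", {
  set.seed(41)
  for (i in 1:60) {
    rec <- random_record(len = sample(100:5000, 1))
    path <- tempfile(fileext = ".gb")
    write_genbank(rec, path)
    back <- read_genbank(path)
    expect_identical(back$sequence, rec$sequence)
    expect_identical(back$topology, rec$topology)
    f1 <- rec$features[order(rec$features$start, rec$features$end, rec$features$label), ]
    f2 <- back$features[order(back$features$start, back$features$end, back$features$label), ]
    rownames(f1) <- rownames(f2) <- NULL
    expect_identical(f2, f1)
  }
})

test_that("a linear zero-feature record writes a LOCUS with its length", {
  rec <- part_record("tiny", "ACGTACGTAC", "linear")
  path <- tempfile(fileext = ".gb")
  write_genbank(rec, path)
  locus <- readLines(path)[1]
  expect_match(locus, "^LOCUS\\s+tiny\\s+10 bp")
  expect_match(locus, "linear")
  expect_identical(read_genbank(path)$sequence, "ACGTACGTAC")
})

test_that("malformed GenBank input raises format errors with line context", {
  path <- tempfile(fileext = ".gb")
  ## feature beyond sequence length on a linear record
  writeLines(c(
    "LOCUS       bad 10 bp    DNA     linear UNA 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     misc_feature    5..40",
    "                     /label=\"x\"",
    "ORIGIN",
    "        1 acgtacgtac",
    "//"), path)
  expect_braidr_error(read_genbank(path), "format_error")
  ## LOCUS length disagreeing with the sequence
  writeLines(c(
    "LOCUS       bad 12 bp    DNA     linear UNA 01-JAN-2026",
    "ORIGIN",
    "        1 acgtacgtac",
    "//"), path)
  expect_braidr_error(read_genbank(path), "format_error")
  expect_braidr_error(read_genbank(tempfile()), "format_error")
  ## wrap-around features are forbidden on linear molecules at construction
  expect_braidr_error(part_record("x", "ACGTACGT", "linear",
                                  features = gb_feature("w", "misc", 6, 2)),
                      "format_error")
})

test_that("circular wrap-around features split at the origin and re-merge", {
  rec <- part_record("wrap", rnd_dna(300), "circular",
                     features = rbind(gb_feature("ori_span", "misc", 280, 20),
                                      gb_feature("plain", "promoter", 10, 60)))
  path <- tempfile(fileext = ".gb")
  write_genbank(rec, path)
  txt <- readLines(path)
  expect_length(grep("gb_wrap", txt), 2L)      # split into two tagged ranges
  back <- read_genbank(path)
  w <- back$features[back$features$label == "ori_span", ]
  expect_identical(c(w$start, w$end), c(280L, 20L))
})

test_that("oligo sheets have two rows per pair, reverse-complementary over the core", {
  sps <- random_spacers(4, "Cas9", seed = 2)
  pairs <- lapply(sps, function(s) quiet(design_multi_cas9_oligos(s)))
  path <- tempfile(fileext = ".csv")
  sheet <- write_oligo_sheet(pairs, path)
  expect_identical(nrow(sheet), 8L)                      # 2 x N oligos
  expect_identical(nrow(utils::read.csv(path)), 8L)
  p <- pairs[[1]]
  core_f <- substr(p$forward, 5, nchar(p$forward))       # drop 5' protrusion
  core_r <- substr(p$reverse, 5, nchar(p$reverse))
  expect_identical(revcomp(core_r), core_f)              # duplex core anneals
  expect_braidr_error(write_oligo_sheet(list(), tempfile()), "empty_input_error")
})

test_that("protocols list one step per reaction, in provenance order, with selection", {
  bundle <- quiet(crispr_for_dummies(random_spacers(2, "Cas9", seed = 8)))
  doc <- bundle$protocol
  expect_identical(length(doc$steps), length(bundle$reactions))
  expect_true(all(grepl("BsaI|BsmBI", doc$steps)))
  ## provenance DAG oracle: by the time a product is used as input, its own
  ## assembly step must already have been listed (topological order)
  made <- character(0)
  for (rx in bundle$reactions) {
    for (p in rx$inputs) {
      if (inherits(p, "gb_part") && length(p$provenance) > 0 &&
          !is.na(p$level) && p$level %in% c("L0", "L1", "Lgt1")) {
        expect_true(p$id %in% made, label = sprintf("%s made before use", p$id))
      }
    }
    made <- c(made, rx$products[[1]]$id)
  }
  ## a step using pUPD2 lists chloramphenicol selection
  upd_steps <- grep("pUPD2", doc$steps, value = TRUE)
  expect_true(all(grepl("chloramphenicol", upd_steps)))
  expect_gt(length(upd_steps), 0)
  ## single-reaction chain renders a one-step protocol
  one <- render_protocol(bundle$reactions[[1]])
  expect_length(one$steps, 1L)
  expect_braidr_error(render_protocol(list()), "empty_input_error")
})
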