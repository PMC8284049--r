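test_that("binary assembly joins complementary vectors and conserves cargo", {
  a1 <- registry_lookup("nptii_tu_alpha1")
  a2 <- registry_lookup("cas9_tu_alpha2")
  om <- binary_assemble(a1, a2, destination = "omega1")
  expect_identical(om$backbone, "omega1")
  expect_identical(om$level, "Lgt1")
  ## cargo conservation: TU multiset of the product equals the parents' union
  expect_setequal(om$features$label[om$features$role == "TU"],
                  c("nptII_TU", "Cas9_TU"))
  expect_setequal(om$provenance, c("nptii_tu_alpha1", "cas9_tu_alpha2", "omega1"))

  ## omega modules close the loop back into alpha
  o1 <- registry_lookup("dsred_tu_omega1")
  o2 <- registry_lookup("nptii_tu_omega2")
  al <- binary_assemble(o1, o2, destination = "alpha2")
  expect_identical(al$backbone, "alpha2")
  expect_setequal(al$features$label[al$features$role == "TU"],
                  c("DsRed_TU", "nptII_TU"))

  ## same-vector inputs are incompatible
  expect_braidr_error(binary_assemble(a1, registry_lookup("dsred_tu_alpha1")),
                      "incompatible_vectors_error")
  ## wrong destination class
  expect_braidr_error(binary_assemble(a1, a2, destination = "alpha1"),
                      "destination_mismatch_error")
})

test_that("the minimal editing construct carries exactly three TUs", {
  guide <- assemble_single_cas9(
    quiet(design_single_cas9_oligos(random_spacer("Cas9", seed = 81), "gM")),
    destination = "alpha2")
  med <- build_minimal_editing_construct(guide)
  expect_identical(sum(med$features$role == "TU"), 3L)
  expect_identical(sum(med$features$role == "spacer"), 1L)

  ## a six-guide array TU still counts as one TU, now with six spacers
  arr <- quiet(design_cas9_array(random_spacers(6, "Cas9", seed = 82),
                                 destination = "alpha2"))
  med6 <- build_minimal_editing_construct(arr)
  expect_identical(sum(med6$features$role == "TU"), 3L)
  expect_identical(sum(med6$features$role == "spacer"), 6L)

  expect_braidr_error(
    build_minimal_editing_construct(guide, marker_TU_id = "no_such_tu"),
    "unknown_part_error")
})

test_that("the fast-track pipeline bundles oligos, intermediates and the T-DNA", {
  bundle <- quiet(crispr_for_dummies(random_spacers(2, "Cas9", seed = 83)))
  final <- bundle$final
  tu_feats <- final$features[final$features$role == "TU", ]
  tu_feats <- tu_feats[order(tu_feats$start), ]
  ## comprises a multiplexed gRNA TU, Cas9, nptII and DsRed
  expect_identical(nrow(tu_feats), 4L)
  expect_setequal(tu_feats$label,
                  c("nptII_TU", "Cas9_TU", "DsRed_TU", "dummies_gRNA_TU"))
  expect_identical(sum(final$features$role == "spacer"), 2L)
  ## 2 x N oligos
  b4 <- quiet(crispr_for_dummies(random_spacers(4, "Cas9", seed = 84)))
  expect_identical(nrow(b4$oligo_sheet), 8L)
  ## cardinality errors
  expect_braidr_error(crispr_for_dummies(list()), "empty_input_error")
  expect_braidr_error(quiet(crispr_for_dummies(random_spacers(7, "Cas9", 85))),
                      "capacity_error")
  ## the bundle round-trips to disk
  dir <- tempfile(); bundle_dir <- write_bundle(b4, dir)
  expect_true(file.exists(file.path(dir, "oligos.csv")))
  expect_true(file.exists(file.path(dir, "protocol.md")))
  expect_identical(nrow(utils::read.csv(file.path(dir, "oligos.csv"))), 8L)
  gbs <- list.files(dir, pattern = "\\.gb$")
  expect_gte(length(gbs), 5L)   # L0s, array, omegas, final
})

test_that("composition chains alternate BsaI and BsmBI along provenance", {
  bundle <- quiet(crispr_for_dummies(random_spacers(3, "Cas9", seed = 86)))
  made_with <- list()
  for (rx in bundle$reactions) {
    for (p in rx$inputs) {
      if (inherits(p, "gb_part") && !is.null(made_with[[p$id]])) {
        expect_false(identical(made_with[[p$id]], rx$enzyme),
                     label = sprintf("%s: enzyme alternates into %s",
                                     p$id, rx$products[[1]]$id))
      }
    }
    made_with[[rx$products[[1]]$id]] <- rx$enzyme
  }
})

test_that("multi-array stress composition reaches the planned spacer total", {
  ## single batch of two: minimal multi-TU construct (4 TUs, 2 spacers)
  st1 <- quiet(compose_stress_test(list(random_spacers(2, "Cas9", seed = 87))))
  expect_identical(sum(st1$features$role == "spacer"), 2L)
  expect_identical(sum(st1$features$role == "TU"), 4L)
  ## a batch of 7 exceeds array capacity
  expect_braidr_error(
    quiet(compose_stress_test(list(random_sitefree_dna(20, 88, n = 7)))),
    "capacity_error")
})
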