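test_that("a two-unit Cas9 array matures into [S1+scaffold, S2+scaffold]", {
  sps <- random_spacers(2, "Cas9", seed = 91, prefix = "S")
  tu <- quiet(design_cas9_array(sps, destination = "alpha1"))
  mg <- process_transcript(tu)
  ## direct concatenation oracle, independent of the assembly path
  scaf <- registry_element_seqs(GRAMMAR)$scaffold
  expect_identical(mg$sequence,
                   c(paste0(sps[[1]]$sequence, scaf), paste0(sps[[2]]$sequence, scaf)))
  expect_identical(mg$spacer, c("S1", "S2"))
  expect_identical(attr(mg, "nuclease"), "Cas9")
})

test_that("processing requires annotations", {
  tu <- quiet(design_cas9_array(random_spacers(1, "Cas9", seed = 92)))
  bare <- tu; bare$features <- bare$features[0, ]
  expect_braidr_error(process_transcript(bare), "annotation_error")
  ## promoter present but no guide units downstream
  prom_only <- tu
  prom_only$features <- prom_only$features[prom_only$features$role %in%
                                             c("promoter", "terminator"), ]
  expect_braidr_error(process_transcript(prom_only), "annotation_error")
})

test_that("verify_scarless localizes mutations, order and count failures", {
  sps <- random_spacers(3, "Cas9", seed = 93)
  tu <- quiet(design_cas9_array(sps, destination = "alpha2"))
  plan <- attr(tu, "plan")
  mg <- process_transcript(tu)
  expect_true(verify_scarless(plan, mg)$pass)

  ## post-hoc mutation of one unit's spacer: failure names the unit index
  sp2 <- tu$features[tu$features$role == "spacer", ][2, ]
  mutated <- tu
  base <- substr(mutated$sequence, sp2$start + 3L, sp2$start + 3L)
  substr(mutated$sequence, sp2$start + 3L, sp2$start + 3L) <-
    if (base == "A") "C" else "A"
  rep_mut <- verify_scarless(plan, process_transcript(mutated))
  expect_false(rep_mut$pass)
  expect_true(2L %in% rep_mut$failures$unit)
  expect_identical(rep_mut$failures$kind, "sequence")

  ## shuffled guide order is reported as an order failure
  shuffled <- mg[c(2, 1, 3), ]
  rep_ord <- verify_scarless(plan, shuffled)
  expect_false(rep_ord$pass)
  expect_true("order" %in% rep_ord$failures$kind)

  ## count mismatch
  rep_cnt <- verify_scarless(plan, mg[1:2, ])
  expect_false(rep_cnt$pass)
  expect_identical(rep_cnt$failures$kind, "count")
})

test_that("edit-estimate bins partition [0,100] with right-closed boundaries", {
  ## the five bins, by example
  expect_identical(classify_edit_estimate(85)$category, "biallelic")
  expect_identical(classify_edit_estimate(50)$category, "heterozygous")
  expect_identical(classify_edit_estimate(15)$category, "negative")
  expect_identical(classify_edit_estimate(30)$category, "chimeric_one_allele")
  expect_identical(classify_edit_estimate(70)$category, "chimeric_both_alleles")
  ## exhaustive boundary behaviour: boundaries belong to the lower bin
  expect_identical(classify_edit_estimate(c(20, 40, 60, 80))$category,
                   c("negative", "chimeric_one_allele", "heterozygous",
                     "chimeric_both_alleles"))
  expect_identical(classify_edit_estimate(c(0, 100))$category,
                   c("negative", "biallelic"))
  ## partition: every value on a fine grid falls in exactly one bin
  grid <- seq(0, 100, by = 0.25)
  cats <- classify_edit_estimate(grid)$category
  expect_false(anyNA(cats))
  expect_identical(sort(unique(cats)),
                   sort(c("negative", "chimeric_one_allele", "heterozygous",
                          "chimeric_both_alleles", "biallelic")))
  ## monotone: category index never decreases with the estimate
  lev <- c("negative", "chimeric_one_allele", "heterozygous",
           "chimeric_both_alleles", "biallelic")
  expect_true(all(diff(match(cats, lev)) >= 0))
  expect_braidr_error(classify_edit_estimate(101), "value_range_error")
  expect_braidr_error(classify_edit_estimate(-2), "value_range_error")
})

test_that("the conservative gene-level rule assumes heterozygosity at ~50/50", {
  expect_identical(classify_gene_edits(c(50, 52))$category, "heterozygous")
  expect_identical(classify_gene_edits(c(50, 52), conservative = TRUE)$category,
                   "heterozygous")
  ## two mid-range guides would otherwise sum to a both-allele call
  expect_identical(classify_gene_edits(c(85, 10), conservative = TRUE)$category,
                   "biallelic")
  expect_identical(classify_gene_edits(c(55, 58, 85), conservative = TRUE)$category,
                   "heterozygous")
})
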