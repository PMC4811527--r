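test_that("initial genomes match their group", {
  wt <- initial_genome("wild_type")
  expect_equal(unname(wt$copies), rep(2L, 12))
  expect_equal(nrow(wt$history), 0L)
  carrier <- initial_genome("brca1_carrier")
  expect_equal(carrier$copies[["BRCA1"]], 1L)
  expect_equal(sum(carrier$copies), 23L)
  expect_equal(nrow(carrier$history), 0L)
  expect_error(initial_genome("other"))
})

test_that("apply_mutation decrements copies, appends ordered events, absorbs", {
  g <- initial_genome("wild_type")
  g1 <- apply_mutation(g, "P53", day = 10)
  expect_equal(g$copies[["P53"]], 2L)  # value semantics: input unchanged
  expect_equal(g1$copies[["P53"]], 1L)
  g2 <- apply_mutation(apply_mutation(g1, "P53", 400), "MMP3", 500)
  expect_equal(g2$history$ordinal, 1:3)
  expect_equal(g2$copies[["P53"]], 0L)
  # absorbed: no copy left, history unchanged
  g3 <- apply_mutation(g2, "P53", 600)
  expect_equal(nrow(g3$history), 3L)
  expect_error(apply_mutation(g, "TP53"), "unknown gene")
  expect_error(apply_mutation(g, "P53", day = -1))
})

test_that("one hit has no functional effect; the second activates it", {
  g1 <- apply_mutation(initial_genome("wild_type"), "MMP3", 1)
  expect_false(effect_profile(g1)$invasive_capable)
  g2 <- apply_mutation(g1, "MMP3", 2)
  expect_true(effect_profile(g2)$invasive_capable)
})

test_that("ESR1 second hit draws a variant tag carried by the profile", {
  set.seed(42)
  g <- apply_mutation(initial_genome("wild_type"), "ESR1", 1)
  expect_true(all(is.na(g$history$variant)))
  g2 <- apply_mutation(g, "ESR1", 2, variant = "V2")
  expect_equal(g2$history$variant[2], "V2")
  expect_equal(effect_profile(g2)$er_variant, "V2")
  drawn <- replicate(50, {
    effect_profile(apply_mutation(g, "ESR1", 2))$er_variant
  })
  expect_true(all(drawn %in% c("V1", "V2", "V3")))
  expect_gt(length(unique(drawn)), 1L)
})

test_that("two-hit rule: effects activate exactly at zero copies", {
  # randomized genomes, compared against the direct per-gene rule
  set.seed(7)
  flag_of <- c(
    BRCA1 = "repair_deficit_brca1", P53 = "checkpoint_loss",
    TGFB_R = "tgfb_insensitive",
    EGFR = "egfr_hyperactive", RUNX3 = "runx3_loss",
    CMYC = "hormone_independent_growth", TELOMERASE = "telomerase_active",
    ECADHERIN = "anoikis_resistant", MMP3 = "invasive_capable",
    CMET = "cmet_unsuppressed"
  )
  for (rep in 1:40) {
    g <- initial_genome("wild_type")
    hits <- sample(gene_ids(), size = sample(0:10, 1), replace = TRUE)
    for (h in hits) g <- apply_mutation(g, h, day = 1)
    prof <- effect_profile(g)
    for (gene in names(flag_of)) {
      expect_identical(prof[[flag_of[[gene]]]], g$copies[[gene]] == 0L,
                       label = paste(gene, "flag"))
    }
    expect_identical(prof$er_variant != "none", g$copies[["ESR1"]] == 0L)
    # HER-2 overexpression requires both copies lost AND the activating tag
    if (prof$her2_active) expect_equal(g$copies[["HER2"]], 0L)
  }
  g <- apply_mutation(initial_genome("wild_type"), "HER2", 1)
  expect_false(effect_profile(g)$her2_active)
  act <- apply_mutation(g, "HER2", 2, variant = "ACT")
  expect_true(effect_profile(act)$her2_active)
  expect_equal(act$history$variant[2], "ACT")
})

test_that("early_mutations returns genes within the first k events", {
  hist <- tibble::tibble(
    gene = c("P53", "P53", "ECADHERIN", "TGFB_R", "CMYC", "MMP3", "MMP3"),
    day = 1:7, ordinal = 1:7, variant = NA_character_
  )
  expect_setequal(early_mutations(hist), c("P53", "ECADHERIN", "TGFB_R", "CMYC"))
  expect_equal(early_mutations(hist[0, ]), character(0))
  expect_setequal(early_mutations(hist[1:3, ]), c("P53", "ECADHERIN"))
  expect_error(early_mutations(hist, k = 0), "at least 1")
})

test_that("lineage records round-trip through JSON lines", {
  coh <- fake_cohort()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_lineages(coh, path)
  back <- read_lineages(path)
  expect_length(back, nrow(coh))
  expect_equal(back[[2]]$outcome, "malignant")
  expect_equal(nrow(back[[2]]$history), 14)
})
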