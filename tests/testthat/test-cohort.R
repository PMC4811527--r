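test_that("run_cohort returns one record per seed and aggregates order-free", {
  cfg <- small_config(years = 2, width = 30)
  coh <- run_cohort(cfg, "wild_type", n = 6, base_seed = 10)
  expect_equal(nrow(coh), 6L)
  expect_equal(coh$seed, 10:15)
  # two half-cohorts over disjoint seed ranges equal the full cohort
  h1 <- run_cohort(cfg, "wild_type", n = 3, base_seed = 10)
  h2 <- run_cohort(cfg, "wild_type", n = 3, base_seed = 13)
  both <- dplyr::bind_rows(h1, h2)
  expect_equal(both$outcome, coh$outcome)
  expect_equal(both$total_mutation_count, coh$total_mutation_count)
  # reproducibility
  again <- run_cohort(cfg, "wild_type", n = 6, base_seed = 10)
  expect_identical(coh$er_fraction, again$er_fraction)
})

test_that("incidence_ci reproduces the Wald interval", {
  ci <- incidence_ci(78, 3000)
  expect_equal(ci$proportion, 0.026)
  expect_equal(round(ci$lower, 3), 0.020)
  expect_equal(round(ci$upper, 3), 0.032)
  expect_equal(incidence_ci(0, 100)$proportion, 0)
  expect_equal(incidence_ci(0, 100)$lower, 0)
  expect_gt(incidence_ci(0, 100, method = "wilson")$upper, 0)
  expect_equal(incidence_ci(50, 50)$proportion, 1)
  expect_equal(incidence_ci(50, 50)$upper, 1)
  expect_error(incidence_ci(5, 0), "at least 1")
  expect_error(incidence_ci(-1, 10))
})

test_that("early_mutation_table stratifies lineage histories correctly", {
  coh <- fake_cohort()
  tab <- early_mutation_table(coh, k = 5)
  expect_setequal(unique(tab$stratum),
                  c("ER+ tumors", "ER- tumors", "all tumors", "hyperplastic"))
  expect_true(all(tab$proportion >= 0 & tab$proportion <= 1, na.rm = TRUE))
  # run 1 (ER+): ECADHERIN (ordinals 1,2) early; MMP3 (7,8) not early
  erp <- tab[tab$stratum == "ER+ tumors", ]
  expect_equal(erp$proportion[erp$gene == "ECADHERIN"], 1)
  expect_equal(erp$proportion[erp$gene == "MMP3"], 0)
  # ER- tumors (runs 2, 6): both have early P53 and BRCA1
  ern <- tab[tab$stratum == "ER- tumors", ]
  expect_equal(ern$n_populations[1], 2L)
  expect_equal(ern$proportion[ern$gene == "P53"], 1)
  expect_equal(ern$proportion[ern$gene == "BRCA1"], 1)
  expect_equal(ern$proportion[ern$gene == "MMP3"], 0)
  # a gene mutated only at ordinal 6 is not early (run 6: CMYC at 5,6 is;
  # ECADHERIN at 7,8 is not)
  expect_equal(ern$proportion[ern$gene == "ECADHERIN"], 0)
  # normal populations contribute to no tumor stratum
  expect_equal(tab$n_populations[tab$stratum == "all tumors"][1], 4L)
  expect_error(early_mutation_table(coh[0, ]), "non-empty")
  expect_error(early_mutation_table(coh, k = 0), "at least 1")
})

test_that("mutation burden comparison computes means and Welch tests", {
  coh <- fake_cohort()
  mc <- mutation_count_comparison(coh)
  means <- setNames(mc$means$mean_mutations, mc$means$stratum)
  expect_equal(unname(means["ER+ tumors"]), 8)
  expect_equal(unname(means["ER- tumors"]), 13)
  expect_equal(unname(means["hyperplastic"]), 7)
  expect_equal(unname(means["normal"]), 1.5)
  # identical strata: difference 0, p = 1
  same <- coh
  same$total_mutation_count <- rep(5L, nrow(same))
  mc2 <- mutation_count_comparison(same)
  expect_equal(mc2$tests$estimate[1], 0)
  expect_equal(mc2$tests$p_value[1], 1)
  # [10,10,10] vs [2,2,2]: mean difference 8 and an extreme test
  d3 <- coh[c(1, 1, 1, 2, 2, 2), ]
  d3$outcome <- "malignant"
  d3$er_fraction <- rep(c(0.02, 0.8), each = 3)
  d3$subtype <- classify_receptor_status(d3$er_fraction, d3$her2_fraction)
  d3$total_mutation_count <- rep(c(10L, 2L), each = 3)
  mc3 <- suppressWarnings(mutation_count_comparison(d3))
  t1 <- mc3$tests[mc3$tests$contrast == "ER- tumors vs ER+ tumors", ]
  expect_equal(t1$estimate, 8)
  expect_lt(t1$p_value, 1e-6)
  # a stratum below two members is skipped with a warning
  expect_warning(mutation_count_comparison(coh[c(1, 4, 5), ]), "fewer than 2")
})

test_that("summaries are recomputable from persisted raw records", {
  coh <- fake_cohort()
  s1 <- summarize_cohort(coh)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort(coh, path)
  back <- read_cohort(path)
  s2 <- summarize_cohort(back)
  expect_equal(tidy(s2), tidy(s1))
  expect_equal(s2$early_mutation_freq, s1$early_mutation_freq)
  expect_equal(s2$mutation_counts$means, s1$mutation_counts$means)
})

test_that("cohort summary is internally consistent and reports write out", {
  coh <- fake_cohort()
  s <- summarize_cohort(coh)
  g <- s$groups$wild_type
  expect_equal(g$n_normal + g$n_hyperplastic + g$n_malignant, g$n_simulations)
  expect_equal(sum(g$subtype_proportions$proportion), 1)
  # cumulative incidence is non-decreasing and ends at the overall incidence
  expect_true(all(diff(g$incidence_by_age$cumulative_incidence) >= 0))
  expect_equal(dplyr::last(g$incidence_by_age$cumulative_incidence),
               g$incidence$proportion)
  dir <- withr::local_tempdir()
  report(s, dir, results = coh)
  expect_true(file.exists(file.path(dir, "incidence_by_age.csv")))
  subs <- read.csv(file.path(dir, "subtype_proportions.csv"))
  expect_equal(nrow(subs), 4L)  # one group, four subtypes
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(file.exists(file.path(dir, "runs.jsonl")))
  # report regenerated from the persisted raw records matches
  re <- summarize_cohort(read_cohort(file.path(dir, "runs.jsonl")))
  expect_equal(tidy(re), tidy(s))
})

test_that("tidiers and plots expose the summary", {
  s <- summarize_cohort(fake_cohort())
  td <- tidy(s)
  expect_true(all(c("group", "statistic", "value") %in% names(td)))
  expect_equal(td$value[td$statistic == "incidence"],
               s$groups$wild_type$incidence$proportion)
  gl <- glance(s)
  expect_equal(gl$n_simulations, 7L)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(plot_subtypes(s), "ggplot")
  expect_s3_class(plot_early_mutations(s), "ggplot")
  expect_s3_class(plot_hormone_cycle(), "ggplot")
})

test_that("zero-budget calibration returns the configuration unchanged", {
  cfg <- ds_config(damage = list(beta = 0.1234))
  out <- calibrate(cfg, budget = 0)
  expect_equal(out$damage$beta, 0.1234)
  expect_true(is.na(attr(out, "converged")))
})
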