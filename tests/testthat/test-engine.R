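test_that("tissue initialization builds the three-layer duct", {
  cfg <- small_config(width = 40)
  tis <- initialize_tissue(cfg, "brca1_carrier", seed = 1)
  cells <- tissue_cells(tis, include_structural = TRUE)
  expect_equal(sum(cells$cell_type == "fibroblast"), 40)
  expect_equal(sum(cells$cell_type == "myoepithelial"), 40)
  expect_equal(sum(grepl("^luminal", cells$cell_type)), 40)
  # every cell of a carrier tissue starts with a single BRCA1 copy
  expect_true(all(cells$copies[, "BRCA1"] == 1L))
  expect_true(all(cells$copies[, -1] == 2L))
  st <- tissue_state(tis)
  expect_equal(st$baseline, 40)
  expect_equal(st$census, 40)
  # initial ER+ complement at the configured proportion
  lum <- tissue_cells(tis)
  expect_equal(sum(lum$er), floor(40 * cfg$cells$p_er_daughter))
  expect_true(all(lum$telomere == cfg$cells$telomere_initial))
  expect_error(initialize_tissue(ds_config(engine = list(width = 5))),
               "degenerate")
})

test_that("same seed gives identical tissues and trajectories", {
  cfg <- small_config(width = 40)
  t1 <- initialize_tissue(cfg, "wild_type", seed = 3)
  t2 <- initialize_tissue(cfg, "wild_type", seed = 3)
  expect_identical(tissue_cells(t1), tissue_cells(t2))
  step_day(t1, 400)
  step_day(t2, 400)
  expect_identical(tissue_cells(t1), tissue_cells(t2))
  expect_identical(tissue_state(t1), tissue_state(t2))
})

test_that("step_day advances one day and bounds census growth", {
  tis <- initialize_tissue(small_config(width = 40), seed = 5)
  d0 <- tissue_state(tis)$day
  step_day(tis)
  expect_equal(tissue_state(tis)$day, d0 + 1)
  for (i in 1:50) {
    before <- tissue_state(tis)$census
    eligible <- sum(tissue_cells(tis)$akt >=
                      small_config()$cells$akt_threshold - 1e-9)
    step_day(tis)
    after <- tissue_state(tis)$census
    expect_lte(after - before, eligible)
  }
})

test_that("signal fields are local: distant columns do not leak", {
  cfg <- small_config(width = 40)
  radius <- cfg$cells$signal_radius
  tis <- initialize_tissue(cfg, seed = 2)
  sig <- tissue_signals(tis)
  # smoothing kernel support: a column's field only reflects cells within
  # the configured radius
  amph <- sig$amphiregulin
  smoothed <- as.numeric(cpp_smooth_columns(amph, radius))
  expect_equal(sig$amphiregulin_smoothed, smoothed, tolerance = 1e-12)
  x <- rep(0, 40)
  x[20] <- 1
  spread <- as.numeric(cpp_smooth_columns(x, radius))
  expect_true(all(spread[abs(seq_along(x) - 20) > radius] == 0))
})

test_that("a null-mutation run is normal, mutation-free and homeostatic", {
  res <- run_simulation(null_mutation_config(years = 10), "wild_type",
                        seed = 1, census_log = TRUE)
  expect_equal(res$outcome, "normal")
  expect_true(is.na(res$event_day))
  expect_equal(res$n_events_total, 0L)
  expect_equal(res$total_mutation_count, 0L)
  expect_false(res$breach)
  cl <- res$census_log
  expect_true(all(cl$luminal_count >= 0.7 * res$baseline_luminal_count))
  expect_true(all(cl$luminal_count <= 1.3 * res$baseline_luminal_count))
})

test_that("run_simulation is reproducible for identical (config, group, seed)", {
  cfg <- small_config(years = 3)
  a <- run_simulation(cfg, "brca1_carrier", seed = 17, census_log = TRUE)
  b <- run_simulation(cfg, "brca1_carrier", seed = 17, census_log = TRUE)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$census_log, b$census_log)
  expect_identical(a$dominant_history, b$dominant_history)
  c <- run_simulation(cfg, "brca1_carrier", seed = 18)
  expect_false(identical(tidy(a), tidy(c)))
})

test_that("receptor subtype uses strict > thresholds", {
  expect_equal(classify_receptor_status(0.09, 0), "ER-/HER2-")
  expect_equal(classify_receptor_status(0.090001, 0), "ER+/HER2-")
  expect_equal(classify_receptor_status(0.5, 0), "ER+/HER2-")
  expect_equal(classify_receptor_status(0.5, 0.050001), "ER+/HER2+")
  expect_equal(classify_receptor_status(0.04, 0.06), "ER-/HER2+")
  expect_equal(classify_receptor_status(0.04, 0.05), "ER-/HER2-")
  nonmal <- structure(list(outcome = "normal"), class = "ds_result")
  expect_error(classify_receptor_status(nonmal), "malignant")
})

test_that("config round-trips through YAML", {
  cfg <- ds_config(damage = list(beta = 0.123), engine = list(width = 55))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(cfg))
})
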