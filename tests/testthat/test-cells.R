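# build a minimal cell tibble for the per-cell kernels
make_cells <- function(er, null_genes = list(NULL), variant = 0L, akt = 0,
                       senescent = FALSE) {
  n <- length(er)
  null_genes <- rep_len(null_genes, n)
  copies <- matrix(2L, n, 12, dimnames = list(NULL, gene_ids()))
  for (i in seq_len(n)) copies[i, null_genes[[i]]] <- 0L
  tibble::tibble(
    er = er, senescent = rep_len(senescent, n),
    her2_active = FALSE,
    esr1_variant = rep_len(as.integer(variant), n),
    akt = rep_len(akt, n), copies = copies
  )
}

test_that("amphiregulin: only ER+ cells produce; V1 is estrogen-independent", {
  cfg <- ds_config()
  cells <- make_cells(er = c(FALSE, TRUE))
  expect_equal(produce_amphiregulin(cells, estrogen = 1, cfg), c(0, 1) *
                 cfg$cells$amphi_per_er_cell)
  expect_equal(produce_amphiregulin(cells, estrogen = 0, cfg), c(0, 0))
  v1 <- make_cells(er = TRUE, null_genes = list("ESR1"), variant = 1L)
  expect_equal(produce_amphiregulin(v1, estrogen = 0, cfg), cfg$cells$v1_amphi)
  v3 <- make_cells(er = TRUE, null_genes = list("ESR1"), variant = 3L)
  expect_equal(produce_amphiregulin(v3, estrogen = 0, cfg),
               0.5 * cfg$cells$v1_amphi)
  # wild-type output follows the waveform: peak day beats trough day
  cyc <- hormone_cycle(cfg)
  wt <- make_cells(er = TRUE)
  expect_gt(produce_amphiregulin(wt, max(cyc$estrogen), cfg),
            produce_amphiregulin(wt, min(cyc$estrogen), cfg))
  # senescent cells produce nothing
  sen <- make_cells(er = TRUE, senescent = TRUE)
  expect_equal(produce_amphiregulin(sen, estrogen = 1, cfg), 0)
})

test_that("HGF production saturates in local amphiregulin", {
  cfg <- ds_config()
  expect_equal(produce_hgf(0, cfg), 0)
  a <- seq(0, 5, by = 0.25)
  h <- produce_hgf(a, cfg)
  expect_true(all(diff(h) >= 0))
  k <- cfg$cells$hgf_half_sat
  expect_equal(produce_hgf(k, cfg), cfg$cells$hgf_max / 2)
  # at 10x the half-saturation constant, within 10% of the maximum
  expect_gt(produce_hgf(10 * k, cfg), 0.9 * cfg$cells$hgf_max)
  expect_error(produce_hgf(-1, cfg), "non-negative")
})

test_that("AKT update routes mitogens by cell type and clamps at zero", {
  cfg <- ds_config()
  # no inputs, no basal: decays toward zero, never negative
  cfg0 <- ds_config(cells = list(basal_inflow = 0, tgfb_per_density = 1))
  cells <- make_cells(er = c(TRUE, FALSE), akt = 0.5)
  out <- update_akt(cells, estrogen = 0, amphiregulin = 0, hgf = 0,
                    tgfb_density = 1, config = cfg0)
  expect_equal(out, c(0, 0))
  # ER- cells respond to HGF; ER+ only when c-Met suppression is lost
  cells <- make_cells(er = c(TRUE, FALSE, TRUE),
                      null_genes = list(NULL, NULL, "CMET"))
  out <- update_akt(cells, 0, amphiregulin = 0, hgf = 1, tgfb_density = 0,
                    config = cfg)
  expect_equal(out[1], cfg$cells$basal_inflow)
  expect_gt(out[2], out[1])
  expect_equal(out[3], out[2])  # c-Met-unsuppressed ER+ gains the HGF input
  # TGF-beta-insensitive cells accumulate at least as much AKT
  cells <- make_cells(er = c(FALSE, FALSE), null_genes = list(NULL, "TGFB_R"))
  out <- update_akt(cells, 0, 0, hgf = 0.5, tgfb_density = 2, config = cfg)
  expect_gte(out[2], out[1])
  # hormone-independent growth: days to mitosis threshold at zero hormones
  cfgl <- ds_config(cells = list(basal_inflow = 0, akt_decay = 0,
                                 tgfb_per_density = 0))
  myc <- make_cells(er = FALSE, null_genes = list("CMYC"))
  days <- ceiling(cfgl$cells$akt_threshold / cfgl$cells$cmyc_inflow)
  akt <- 0
  for (i in seq_len(days)) {
    myc$akt <- akt
    akt <- update_akt(myc, 0, 0, 0, 0, config = cfgl)
  }
  expect_gte(akt, cfgl$cells$akt_threshold)
})

test_that("ESR1 variants V2/V3 add a direct estrogen-to-AKT input", {
  cfg <- ds_config(cells = list(basal_inflow = 0))
  v2 <- make_cells(er = TRUE, null_genes = list("ESR1"), variant = 2L)
  v3 <- make_cells(er = TRUE, null_genes = list("ESR1"), variant = 3L)
  a2 <- update_akt(v2, estrogen = 1, 0, 0, 0, config = cfg)
  a3 <- update_akt(v3, estrogen = 1, 0, 0, 0, config = cfg)
  expect_equal(a2, cfg$cells$v2_estrogen_gain)
  expect_equal(a3, 0.5 * cfg$cells$v2_estrogen_gain)
  expect_equal(update_akt(v2, estrogen = 0, 0, 0, 0, config = cfg), 0)
})

test_that("anoikis and invasion predicates", {
  expect_false(apoptosis_check(adhered = TRUE))
  expect_true(apoptosis_check(adhered = FALSE))
  expect_false(apoptosis_check(adhered = FALSE, anoikis_resistant = TRUE))
  expect_true(apoptosis_check(adhered = TRUE, apoptosis_flagged = TRUE))
  expect_false(invasion_check(invasive_capable = FALSE))
  expect_true(invasion_check(invasive_capable = TRUE))
  expect_false(invasion_check(TRUE, alive = FALSE))
  expect_false(invasion_check(TRUE, senescent = TRUE))
})
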