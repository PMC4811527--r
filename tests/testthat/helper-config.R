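# Small, fast configurations used across the test files.

# a reduced tissue for engine-level property tests
small_config <- function(years = 5, width = 40, ...) {
  ds_config(engine = list(width = width, years = years), ...)
}

# mutation machinery fully disabled: no damage, no replication errors
null_mutation_config <- function(years = 40, width = 100) {
  ds_config(
    engine = list(width = width, years = years),
    damage = list(d_max = 0, epsilon = 0, beta = 0)
  )
}

# a minimal synthetic cohort tibble for the aggregation functions
fake_cohort <- function() {
  hist_of <- function(genes) {
    tibble::tibble(gene = genes, day = seq_along(genes) * 100L,
                   ordinal = seq_along(genes), variant = NA_character_)
  }
  out <- tibble::tibble(
    seed = 1:7,
    group = "wild_type",
    outcome = c("malignant", "malignant", "hyperplastic", "normal", "normal",
                "malignant", "malignant"),
    event_day = c(4000L, 9000L, NA, NA, NA, 14000L, 12000L),
    final_luminal_count = c(1010L, 1100L, 250L, 100L, 98L, 1005L, 1020L),
    er_fraction = c(0.80, 0.03, 0.70, 0.12, 0.10, 0.04, 0.75),
    her2_fraction = c(0.01, 0.60, 0.0, 0.0, 0.0, 0.02, 0.0),
    total_mutation_count = c(8L, 14L, 7L, 2L, 1L, 12L, 8L),
    dominant_history = list(
      hist_of(c("ECADHERIN", "ECADHERIN", "TELOMERASE", "TELOMERASE", "RUNX3",
                "RUNX3", "MMP3", "MMP3")),
      hist_of(c("P53", "P53", "BRCA1", "BRCA1", "CMYC", "CMYC", "ECADHERIN",
                "ECADHERIN", "TELOMERASE", "TELOMERASE", "MMP3", "MMP3",
                "HER2", "HER2")),
      hist_of(c("ECADHERIN", "ECADHERIN", "TGFB_R", "TGFB_R", "TELOMERASE",
                "TELOMERASE", "ESR1")),
      hist_of(c("P53", "CMET")),
      hist_of("BRCA1"),
      hist_of(c("BRCA1", "BRCA1", "P53", "P53", "CMYC", "CMYC", "ECADHERIN",
                "ECADHERIN", "MMP3", "MMP3", "TGFB_R", "EGFR")),
      hist_of(c("ECADHERIN", "ECADHERIN", "TELOMERASE", "TELOMERASE",
                "TGFB_R", "TGFB_R", "MMP3", "MMP3"))
    ),
    dominant_copies = rep(list(setNames(rep(2L, 12), gene_ids())), 7)
  )
  out$subtype <- ifelse(out$outcome == "malignant",
                        classify_receptor_status(out$er_fraction,
                                                 out$her2_fraction),
                        NA_character_)
  attr(out, "config") <- ds_config()
  class(out) <- c("ds_cohort", class(out))
  out
}
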