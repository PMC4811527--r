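#' Run a cohort of independent simulations
#'
#' Executes `n` independent 40-year simulations with seeds
#' `base_seed .. base_seed + n - 1`, one virtual patient each. Aggregation is
#' order-independent and stateless: everything in the summary can be
#' recomputed from the returned per-run records.
#'
#' @param config a [ds_config()].
#' @param group `"wild_type"` or `"brca1_carrier"`.
#' @param n number of replicate simulations.
#' @param base_seed first seed of the contiguous seed range.
#' @param progress print a dot every 100 runs.
#' @return A `ds_cohort` tibble, one row per run: `seed`, `group`, `outcome`,
#'   `event_day`, `final_luminal_count`, `er_fraction`, `her2_fraction`,
#'   `total_mutation_count`, `subtype` (malignant runs only), plus
#'   list-columns `dominant_history` and `dominant_copies`.
#' @examples
#' \donttest{
#' coh <- run_cohort(ds_config(), "brca1_carrier", n = 20, base_seed = 1)
#' table(coh$outcome)
#' }
#' @export
run_cohort <- function(config = ds_config(),
                       group = c("wild_type", "brca1_carrier"),
                       n = config$cohort$n, base_seed = 1L, progress = FALSE) {
  group <- match.arg(group)
  stopifnot(n >= 1)
  flat <- flatten_config(config)
  gcode <- group_code(group)
  ids <- gene_ids()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    raw <- cpp_run_simulation(flat, gcode, as.integer(base_seed + i - 1L),
                              FALSE, FALSE)
    rows[[i]] <- tibble::tibble(
      seed = raw$seed,
      group = group,
      outcome = c("normal", "hyperplastic", "malignant")[raw$outcome + 1L],
      event_day = if (raw$event_day < 0) NA_integer_ else raw$event_day,
      final_luminal_count = raw$final_luminal_count,
      er_fraction = raw$er_fraction,
      her2_fraction = raw$her2_fraction,
      total_mutation_count = raw$total_mutation_count,
      dominant_history = list(tibble::tibble(
        gene = ids[raw$history_gene + 1L],
        day = raw$history_day,
        ordinal = raw$history_ordinal,
        variant = c(NA_character_, "V1", "V2", "V3", "ACT")[raw$history_variant + 1L]
      )),
      dominant_copies = list(setNames(raw$dominant_copies, ids))
    )
    if (progress && i %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- dplyr::bind_rows(rows)
  out$subtype <- ifelse(
    out$outcome == "malignant",
    classify_receptor_status(out$er_fraction, out$her2_fraction, config),
    NA_character_
  )
  attr(out, "config") <- config
  class(out) <- c("ds_cohort", class(out))
  out
}

#' Binomial proportion with 95% confidence interval
#'
#' Wald (normal-approximation) interval by default, clamped to `[0, 1]`;
#' Wilson is available behind the `method` flag.
#'
#' @param k number of events.
#' @param n number of trials (must be positive).
#' @param method `"wald"` or `"wilson"`.
#' @param level confidence level.
#' @return A one-row tibble: `proportion`, `lower`, `upper`, `k`, `n`.
#' @examples
#' incidence_ci(78, 3000)   # 2.6% (2.0-3.2%)
#' @export
incidence_ci <- function(k, n, method = c("wald", "wilson"), level = 0.95) {
  method <- match.arg(method)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  p <- k / n
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half)
    hi <- min(1, p + half)
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  }
  tibble::tibble(proportion = p, lower = lo, upper = hi, k = k, n = n)
}

#' Summarize a cohort
#'
#' Computes the headline statistics of a cohort (or of two pooled cohorts):
#' outcome counts, incidence of malignancy with 95% CI, receptor-subtype
#' proportions among malignant runs, cumulative incidence by simulated year,
#' per-gene early-mutation frequencies by stratum, and mean total mutation
#' counts by outcome class with pairwise Welch t-tests.
#'
#' @param results a `ds_cohort` tibble (rows from multiple groups may be
#'   combined with [dplyr::bind_rows()]; per-group statistics are reported by
#'   group).
#' @param k early-mutation window (first `k` events), default 5.
#' @return A `ds_cohort_summary` list; see [tidy.ds_cohort_summary()] and
#'   [glance.ds_cohort_summary()].
#' @export
summarize_cohort <- function(results, k = 5L) {
  config <- attr(results, "config")
  if (is.null(config)) config <- ds_config()
  groups <- split(results, results$group)
  per_group <- purrr::map(groups, function(g) {
    n <- nrow(g)
    counts <- table(factor(g$outcome, c("normal", "hyperplastic", "malignant")))
    inc <- incidence_ci(sum(g$outcome == "malignant"), n,
                        method = config$cohort$ci_method)
    mal <- g[g$outcome == "malignant", ]
    subtypes <- table(factor(mal$subtype, subtype_levels()))
    sub_prop <- if (nrow(mal) > 0) as.numeric(subtypes) / nrow(mal) else
      rep(NA_real_, 4L)
    years <- ceiling(config$engine$years)
    ev_year <- ceiling(mal$event_day / config$engine$days_per_year)
    by_age <- tibble::tibble(
      year = seq_len(years),
      cumulative_incidence = vapply(
        seq_len(years), function(y) sum(ev_year <= y) / n, numeric(1))
    )
    list(
      n_simulations = n,
      n_normal = as.integer(counts[["normal"]]),
      n_hyperplastic = as.integer(counts[["hyperplastic"]]),
      n_malignant = as.integer(counts[["malignant"]]),
      incidence = inc,
      subtype_proportions = tibble::tibble(
        subtype = subtype_levels(), proportion = sub_prop,
        k = as.integer(subtypes)),
      incidence_by_age = by_age
    )
  })
  out <- list(
    groups = per_group,
    early_mutation_freq = early_mutation_table(results, k = k),
    mutation_counts = mutation_count_comparison(results),
    n_total = nrow(results),
    k_early = k,
    config = config
  )
  class(out) <- "ds_cohort_summary"
  out
}

#' @export
print.ds_cohort_summary <- function(x, ...) {
  cat("<ds_cohort_summary> ", x$n_total, " simulations\n", sep = "")
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    cat(sprintf(
      "  %s: n=%d, malignant %.1f%% (95%% CI %.1f-%.1f%%), hyperplastic %.1f%%\n",
      g, s$n_simulations, 100 * s$incidence$proportion,
      100 * s$incidence$lower, 100 * s$incidence$upper,
      100 * s$n_hyperplastic / s$n_simulations))
    if (s$n_malignant > 0) {
      p <- s$subtype_proportions
      cat("    subtypes: ",
          paste(sprintf("%s %.0f%%", p$subtype, 100 * p$proportion),
                collapse = ", "), "\n", sep = "")
    }
  }
  mc <- x$mutation_counts$means
  cat("  mean mutations: ",
      paste(sprintf("%s %.1f", mc$stratum, mc$mean_mutations), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# strata used for mutation analyses: tumors split by ER call, plus
# hyperplastic and normal populations
result_strata <- function(results, config) {
  er_pos <- results$er_fraction > config$engine$er_positive_threshold
  dplyr::case_when(
    results$outcome == "malignant" & er_pos ~ "ER+ tumors",
    results$outcome == "malignant" ~ "ER- tumors",
    results$outcome == "hyperplastic" ~ "hyperplastic",
    TRUE ~ "normal"
  )
}

#' Early-mutation frequencies by stratum
#'
#' For each stratum (ER+ tumors, ER- tumors, all tumors, hyperplastic
#' populations) and each gene: the proportion of populations whose dominant
#' lineage acquired a mutation to that gene among its first `k` events.
#'
#' @param results a `ds_cohort` tibble (may pool groups).
#' @param k early-mutation window, default 5.
#' @return A tibble: `stratum`, `gene`, `n_populations`, `n_early`,
#'   `proportion`.
#' @export
early_mutation_table <- function(results, k = 5L) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (nrow(results) == 0) stop("results must be non-empty", call. = FALSE)
  config <- attr(results, "config")
  if (is.null(config)) config <- ds_config()
  strata <- result_strata(results, config)
  ids <- gene_ids()
  sets <- list(
    "ER+ tumors" = which(strata == "ER+ tumors"),
    "ER- tumors" = which(strata == "ER- tumors"),
    "all tumors" = which(results$outcome == "malignant"),
    "hyperplastic" = which(strata == "hyperplastic")
  )
  purrr::map_dfr(names(sets), function(sname) {
    idx <- sets[[sname]]
    early <- purrr::map(results$dominant_history[idx], early_mutations, k = k)
    counts <- vapply(ids, function(g) {
      sum(vapply(early, function(e) g %in% e, logical(1)))
    }, numeric(1))
    tibble::tibble(
      stratum = sname, gene = ids, n_populations = length(idx),
      n_early = as.integer(counts),
      proportion = if (length(idx) > 0) unname(counts) / length(idx) else NA_real_
    )
  })
}

#' Mutation-burden comparison across outcome classes
#'
#' Mean total mutation counts (allele-loss events in the dominant lineage)
#' for ER+ tumors, ER- tumors, hyperplastic and normal populations, with
#' unpaired two-tailed Welch t-tests for the two headline contrasts: ER-
#' versus ER+ tumors, and hyperplastic versus normal populations.
#'
#' @param results a `ds_cohort` tibble (may pool groups).
#' @return A list with `means` (tibble: stratum, n, mean_mutations, sd) and
#'   `tests` (tibble: contrast, estimate = mean difference, p_value). A
#'   contrast whose stratum has fewer than two members is skipped with a
#'   warning.
#' @export
mutation_count_comparison <- function(results) {
  config <- attr(results, "config")
  if (is.null(config)) config <- ds_config()
  strata <- result_strata(results, config)
  lv <- c("ER+ tumors", "ER- tumors", "hyperplastic", "normal")
  means <- purrr::map_dfr(lv, function(s) {
    x <- results$total_mutation_count[strata == s]
    tibble::tibble(stratum = s, n = length(x),
                   mean_mutations = if (length(x)) mean(x) else NA_real_,
                   sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  })
  contrasts <- list(
    c("ER- tumors", "ER+ tumors"),
    c("hyperplastic", "normal")
  )
  tests <- purrr::map_dfr(contrasts, function(ct) {
    a <- results$total_mutation_count[strata == ct[1]]
    b <- results$total_mutation_count[strata == ct[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning("stratum with fewer than 2 members; skipping ", ct[1], " vs ",
              ct[2], call. = FALSE)
      return(tibble::tibble(contrast = paste(ct[1], "vs", ct[2]),
                            estimate = NA_real_, p_value = NA_real_))
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # degenerate: Welch statistic undefined; equal means => no evidence
      return(tibble::tibble(contrast = paste(ct[1], "vs", ct[2]),
                            estimate = mean(a) - mean(b),
                            p_value = if (mean(a) == mean(b)) 1 else 0))
    }
    tt <- t.test(a, b, alternative = "two.sided", var.equal = FALSE)
    tibble::tibble(contrast = paste(ct[1], "vs", ct[2]),
                   estimate = unname(mean(a) - mean(b)),
                   p_value = tt$p.value)
  })
  list(means = means, tests = tests)
}

#' Literature reference constants used in reports
#'
#' Published epidemiologic anchor points embedded in report tables as
#' clearly-labelled literature comparison columns (they are constants, never
#' fetched): SEER cumulative breast-cancer incidence by age 55 (2.9%) and the
#' range of published cumulative incidences in BRCA1 mutation carriers
#' (17-53%).
#'
#' @return A tibble: `quantity`, `value`, `source`.
#' @export
reference_constants <- function() {
  tibble::tibble(
    quantity = c("cumulative_incidence_by_55_pct",
                 "brca1_carrier_incidence_low_pct",
                 "brca1_carrier_incidence_high_pct"),
    value = c(2.9, 17, 53),
    source = c("SEER (literature value)",
               "published BRCA1 penetrance studies (literature value)",
               "published BRCA1 penetrance studies (literature value)")
  )
}

#' Write cohort report files
#'
#' Writes CSV tables (incidence by age, subtype proportions, early-mutation
#' table, mutation-count comparison), a JSON summary and the raw per-run
#' records as JSON lines. Reports regenerate exactly from the persisted raw
#' results via [read_cohort()] + [summarize_cohort()].
#'
#' @param summary a `ds_cohort_summary`.
#' @param dir output directory (created if missing).
#' @param results optionally, the raw `ds_cohort` tibble to persist alongside.
#' @return `dir`, invisibly.
#' @export
report <- function(summary, dir, results = NULL) {
  stopifnot(inherits(summary, "ds_cohort_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_age <- purrr::imap_dfr(summary$groups, function(s, g) {
    dplyr::mutate(s$incidence_by_age, group = g, .before = 1)
  })
  write.csv(by_age, file.path(dir, "incidence_by_age.csv"), row.names = FALSE)
  subtypes <- purrr::imap_dfr(summary$groups, function(s, g) {
    dplyr::mutate(s$subtype_proportions, group = g, .before = 1)
  })
  write.csv(subtypes, file.path(dir, "subtype_proportions.csv"),
            row.names = FALSE)
  write.csv(summary$early_mutation_freq,
            file.path(dir, "early_mutation_table.csv"), row.names = FALSE)
  write.csv(summary$mutation_counts$means,
            file.path(dir, "mutation_counts.csv"), row.names = FALSE)
  write.csv(summary$mutation_counts$tests,
            file.path(dir, "mutation_count_tests.csv"), row.names = FALSE)
  write.csv(reference_constants(), file.path(dir, "reference_constants.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(
      groups = purrr::map(summary$groups, function(s) list(
        n_simulations = s$n_simulations, n_normal = s$n_normal,
        n_hyperplastic = s$n_hyperplastic, n_malignant = s$n_malignant,
        incidence = as.list(s$incidence)
      )),
      reference_constants = reference_constants()
    ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(results)) {
    write_cohort(results, file.path(dir, "runs.jsonl"))
  }
  invisible(dir)
}

#' Persist and reload raw cohort records
#'
#' JSON-lines round-trip of the per-run records, so that every proportion and
#' CI can be recomputed from disk.
#'
#' @param results a `ds_cohort` tibble.
#' @param path a `.jsonl` file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `ds_cohort` tibble.
#' @export
write_cohort <- function(results, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(results))) {
    rec <- list(
      seed = results$seed[[i]], group = results$group[[i]],
      outcome = results$outcome[[i]], event_day = results$event_day[[i]],
      final_luminal_count = results$final_luminal_count[[i]],
      er_fraction = results$er_fraction[[i]],
      her2_fraction = results$her2_fraction[[i]],
      total_mutation_count = results$total_mutation_count[[i]],
      dominant_history = results$dominant_history[[i]],
      dominant_copies = as.list(results$dominant_copies[[i]])
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @param config config to attach to the reloaded cohort (used by
#'   summaries); defaults to [ds_config()].
#' @export
read_cohort <- function(path, config = ds_config()) {
  lines <- readLines(path)
  rows <- purrr::map(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    hist <- rec$dominant_history
    hist <- if (length(hist) == 0 || is.null(nrow(hist)) || nrow(hist) == 0) {
      tibble::tibble(gene = character(), day = integer(), ordinal = integer(),
                     variant = character())
    } else {
      h <- tibble::as_tibble(hist)
      if (!"variant" %in% names(h)) h$variant <- NA_character_
      h
    }
    tibble::tibble(
      seed = rec$seed, group = rec$group, outcome = rec$outcome,
      event_day = if (is.null(rec$event_day)) NA_integer_ else rec$event_day,
      final_luminal_count = rec$final_luminal_count,
      er_fraction = rec$er_fraction, her2_fraction = rec$her2_fraction,
      total_mutation_count = rec$total_mutation_count,
      dominant_history = list(hist),
      dominant_copies = list(unlist(rec$dominant_copies))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$subtype <- ifelse(
    out$outcome == "malignant",
    classify_receptor_status(out$er_fraction, out$her2_fraction, config),
    NA_character_
  )
  attr(out, "config") <- config
  class(out) <- c("ds_cohort", class(out))
  out
}
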