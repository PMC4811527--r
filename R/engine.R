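#' Initialize a tissue
#'
#' Builds the layered two-dimensional duct lattice: a layer of fibroblasts
#' overlaid by myoepithelial cells, both overlaid by luminal epithelial cells
#' (one adhered luminal cell per column, with an overflow band above the
#' luminal layer to hold hyperplastic expansion). Every cell receives the
#' initial genome of the simulation group; the initial ER+ complement is
#' placed at the configured baseline proportion; telomeres start at the
#' configured count. The baseline luminal census is recorded at day 0 and is
#' never rewritten.
#'
#' @param config a [ds_config()].
#' @param group `"wild_type"` or `"brca1_carrier"`.
#' @param seed integer seed; the same (config, group, seed) always produces
#'   the identical tissue and trajectory.
#' @param census_log record a daily census log (day, luminal count, ER and
#'   HER-2 cell fractions, breach flag).
#' @param trace record the full mutation-event arena and a per-division log
#'   (used by heritability checks); adds memory overhead.
#' @return A `ds_tissue` handle. Advance it with [step_day()]; inspect it
#'   with [tissue_state()] and [tissue_cells()].
#' @examples
#' tis <- initialize_tissue(ds_config(engine = list(width = 20)), seed = 1)
#' tissue_state(tis)$census
#' @export
initialize_tissue <- function(config = ds_config(),
                              group = c("wild_type", "brca1_carrier"),
                              seed = 1L, census_log = FALSE, trace = FALSE) {
  group <- match.arg(group)
  ptr <- ds_sim_new(flatten_config(config), group_code(group), as.integer(seed),
                    census_log, trace)
  structure(list(ptr = ptr, config = config, group = group,
                 seed = as.integer(seed)),
            class = "ds_tissue")
}

#' Advance a tissue by whole days
#'
#' Each simulated day executes, in order: (1) hormone update, (2) paracrine
#' signal production (amphiregulin, then HGF), (3) per-cell damage and
#' repair, (4) per-cell AKT update, (5) mitosis attempts, (6)
#' apoptosis/senescence/anoikis checks, (7) invasion checks, (8) census and
#' breach update. Cells iterate in an order randomized from the run's RNG, so
#' trajectories remain seed-reproducible.
#'
#' @param tissue a `ds_tissue` from [initialize_tissue()].
#' @param n_days number of days to advance (stops early on malignancy).
#' @return The tissue handle, invisibly.
#' @export
step_day <- function(tissue, n_days = 1L) {
  stopifnot(inherits(tissue, "ds_tissue"))
  ds_sim_step(tissue$ptr, as.integer(n_days))
  invisible(tissue)
}

#' @rdname step_day
#' @export
tissue_state <- function(tissue) {
  stopifnot(inherits(tissue, "ds_tissue"))
  st <- ds_sim_state(tissue$ptr)
  tibble::as_tibble(st[c("day", "census", "baseline", "breach", "stopped",
                         "event_day", "n_events_total")])
}

#' Cells of a tissue
#'
#' @param tissue a `ds_tissue`.
#' @param include_structural also return the (homeostatic) fibroblast and
#'   myoepithelial layer cells.
#' @return A tibble, one row per living cell: `cell_type`, `column`, `layer`,
#'   `er`, `senescent`, `telomere`, `akt`, `damage`, `n_mutations`,
#'   `esr1_variant` and a 12-column integer `copies` matrix column.
#' @export
tissue_cells <- function(tissue, include_structural = FALSE) {
  stopifnot(inherits(tissue, "ds_tissue"))
  raw <- ds_sim_cells(tissue$ptr)
  cp <- raw$copies
  colnames(cp) <- gene_ids()
  out <- tibble::tibble(
    cell_type = ifelse(raw$er, "luminal_ER_pos", "luminal_ER_neg"),
    column = raw$column, layer = raw$layer, er = raw$er,
    senescent = raw$senescent, her2_active = raw$her2_active,
    telomere = raw$telomere, akt = raw$akt,
    damage = raw$damage, n_mutations = raw$n_mutations,
    esr1_variant = raw$esr1_variant, copies = cp
  )
  if (include_structural) {
    st <- ds_sim_structural(tissue$ptr)
    w <- st$width
    mk <- function(type, copies) tibble::tibble(
      cell_type = type, column = seq_len(w) - 1L,
      layer = if (type == "fibroblast") -2L else -1L,
      er = FALSE, senescent = FALSE, her2_active = FALSE,
      telomere = NA_integer_, akt = 0,
      damage = 0, n_mutations = 0L, esr1_variant = 0L,
      copies = matrix(rep(as.integer(copies), each = w), nrow = w,
                      dimnames = list(NULL, gene_ids()))
    )
    out <- dplyr::bind_rows(mk("fibroblast", st$fibroblast_copies),
                            mk("myoepithelial", st$myoepithelial_copies), out)
    colnames(out$copies) <- gene_ids()
  }
  out
}

#' Current paracrine signal fields
#'
#' @param tissue a `ds_tissue`.
#' @return A tibble per lattice column: raw and smoothed amphiregulin, HGF,
#'   smoothed luminal density and the resulting TGF-beta tone.
#' @export
tissue_signals <- function(tissue) {
  stopifnot(inherits(tissue, "ds_tissue"))
  tibble::as_tibble(ds_sim_signals(tissue$ptr))
}

#' @export
print.ds_tissue <- function(x, ...) {
  st <- tissue_state(x)
  cat("<ds_tissue> group=", x$group, " seed=", x$seed, " day=", st$day,
      " census=", st$census, "/", st$baseline,
      if (st$breach) " [breached]" else "", "\n", sep = "")
  invisible(x)
}

#' Run one full simulation
#'
#' Runs the tissue for up to the configured number of simulated years (40 by
#' default, 365-day years), stopping early the day the malignancy criteria
#' are first met: expansion of the luminal population beyond
#' `malignancy_fold` (10x) of baseline together with invasion beyond the
#' basement membrane. Hyperplasia (luminal census above `hyperplasia_fold`,
#' 2x baseline, without malignancy) is assessed only at the end of the
#' simulated period.
#'
#' @inheritParams initialize_tissue
#' @return A `ds_result` list: `outcome` (`"normal"`, `"hyperplastic"`,
#'   `"malignant"`), `event_day` (day malignancy was declared, `NA`
#'   otherwise), `final_luminal_count`, `baseline_luminal_count`,
#'   `er_fraction`, `her2_fraction`, `total_mutation_count` (allele-loss
#'   events in the dominant final lineage's history), `dominant_history`
#'   (tibble: gene, day, ordinal, variant), `dominant_copies`, `seed`,
#'   `group`, plus `census_log` / `trace` when requested.
#' @examples
#' \donttest{
#' res <- run_simulation(ds_config(), "brca1_carrier", seed = 7)
#' res$outcome
#' }
#' @export
run_simulation <- function(config = ds_config(),
                           group = c("wild_type", "brca1_carrier"),
                           seed = 1L, census_log = FALSE, trace = FALSE) {
  group <- match.arg(group)
  raw <- cpp_run_simulation(flatten_config(config), group_code(group),
                            as.integer(seed), census_log, trace)
  as_ds_result(raw, group, config)
}

as_ds_result <- function(raw, group, config) {
  ids <- gene_ids()
  hist <- tibble::tibble(
    gene = ids[raw$history_gene + 1L],
    day = raw$history_day,
    ordinal = raw$history_ordinal,
    variant = c(NA_character_, "V1", "V2", "V3", "ACT")[raw$history_variant + 1L]
  )
  out <- list(
    outcome = c("normal", "hyperplastic", "malignant")[raw$outcome + 1L],
    event_day = if (raw$event_day < 0) NA_integer_ else raw$event_day,
    final_luminal_count = raw$final_luminal_count,
    baseline_luminal_count = raw$baseline_luminal_count,
    er_fraction = raw$er_fraction,
    her2_fraction = raw$her2_fraction,
    breach = raw$breach,
    total_mutation_count = raw$total_mutation_count,
    dominant_history = hist,
    dominant_copies = setNames(raw$dominant_copies, ids),
    n_events_total = raw$n_events_total,
    total_divisions = raw$total_divisions,
    days_run = raw$days_run,
    seed = raw$seed,
    group = group
  )
  if (!is.null(raw$census_log)) {
    out$census_log <- tibble::as_tibble(raw$census_log)
  }
  if (!is.null(raw$arena)) {
    out$arena <- tibble::as_tibble(raw$arena)
    out$divisions <- tibble::as_tibble(raw$divisions)
  }
  structure(out, class = "ds_result")
}

#' @export
print.ds_result <- function(x, ...) {
  cat("<ds_result> ", x$group, " seed=", x$seed, ": ", x$outcome,
      if (!is.na(x$event_day)) paste0(" (day ", x$event_day, ")") else "",
      ", census ", x$final_luminal_count, "/", x$baseline_luminal_count,
      ", ER ", round(100 * x$er_fraction, 1), "%, HER2 ",
      round(100 * x$her2_fraction, 1), "%, ",
      x$total_mutation_count, " mutation(s)\n", sep = "")
  invisible(x)
}

#' Receptor-status subtype of a malignant result
#'
#' A tumor is called ER+ when strictly more than 9% of its final luminal
#' cells express ER, and HER-2+ when strictly more than 5% express HER-2; the
#' subtype is the cross of the two calls. The 9% threshold corresponds to the
#' physiologic baseline rate of ER expression in normal tissue.
#'
#' @param er_fraction,her2_fraction cell fractions in `[0, 1]`, or a
#'   `ds_result` passed as the first argument.
#' @param config a [ds_config()] carrying the thresholds.
#' @return Character vector of subtype labels: `"ER+/HER2-"`, `"ER+/HER2+"`,
#'   `"ER-/HER2+"`, `"ER-/HER2-"`.
#' @examples
#' classify_receptor_status(c(0.09, 0.5), c(0.06, 0))
#' @export
classify_receptor_status <- function(er_fraction, her2_fraction = NULL,
                                     config = ds_config()) {
  if (inherits(er_fraction, "ds_result")) {
    res <- er_fraction
    if (res$outcome != "malignant") {
      stop("receptor subtyping applies to malignant results only", call. = FALSE)
    }
    er_fraction <- res$er_fraction
    her2_fraction <- res$her2_fraction
  }
  er <- er_fraction > config$engine$er_positive_threshold
  her2 <- her2_fraction > config$engine$her2_positive_threshold
  paste0(ifelse(er, "ER+", "ER-"), "/", ifelse(her2, "HER2+", "HER2-"))
}

subtype_levels <- function() {
  c("ER+/HER2-", "ER+/HER2+", "ER-/HER2+", "ER-/HER2-")
}
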