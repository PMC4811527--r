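#' Simulation configuration
#'
#' Builds the full parameter set for the duct-epithelium model, organised in
#' blocks (`endocrine`, `genome`, `damage`, `cells`, `engine`, `cohort`).
#' Every parameter has a default; pass replacements either as named blocks
#' (`ds_config(damage = list(beta = 1))`) or leave untouched. Defaults are the
#' calibrated operating point of the model: a wild-type tissue is homeostatic
#' over the full 40-year simulated period, and cohort-level incidence matches
#' the epidemiology the model was built against (see the methods vignette).
#'
#' Key parameters, with units:
#' \describe{
#'   \item{endocrine}{normalized hormone amplitudes of the 28-day cycle.}
#'   \item{damage}{`d_max` — maximum daily DNA-damage increment (damage
#'     units/day, uniform on `[0, d_max]`); `repair_capacity` — damage removed
#'     per day; `deficit_brca1`, `deficit_p53` — multiplicative repair-capacity
#'     factors once the gene is functionally lost; `beta` — slope of the
#'     damage-dependent mutation probability at division,
#'     `P = min(1, beta * damage)`; `epsilon` — damage-independent replication
#'     error probability per division product; `senescence_threshold` /
#'     `apoptosis_threshold` — damage checkpoints.}
#'   \item{cells}{AKT accumulation/threshold dynamics, paracrine gains,
#'     ESR1-variant effects, growth-effect multipliers, `telomere_initial`
#'     (replicative lifespan, divisions), `baseline_apoptosis` (daily
#'     turnover probability), `overflow_capacity` (luminal overflow band
#'     depth per column).}
#'   \item{engine}{lattice `width` (columns), simulated `years`,
#'     outcome-classification folds and receptor-positivity thresholds.}
#' }
#'
#' @param ... named blocks of overrides, e.g. `damage = list(beta = 0.5)`.
#' @return A nested list of class `ds_config`.
#' @examples
#' cfg <- ds_config(engine = list(width = 50, years = 5))
#' cfg$engine$width
#' @export
ds_config <- function(...) {
  cfg <- list(
    endocrine = list(
      estrogen_base = 0.2,
      estrogen_peak = 1.0,
      estrogen_luteal = 0.5,
      progesterone_base = 0.02,
      progesterone_peak = 1.0
    ),
    genome = list(
      include_cmet = TRUE
    ),
    damage = list(
      d_max = 0.12,
      repair_capacity = 0.10,
      deficit_brca1 = 0.59,
      deficit_p53 = 0.78,
      het_deficit_brca1 = 0.71,
      p53_checkpoint = TRUE,
      beta = 0.25,
      epsilon = 0.028,
      senescence_threshold = 1.0,
      apoptosis_threshold = 1.5,
      damage_ceiling = 1.5
    ),
    cells = list(
      akt_threshold = 1.0,
      akt_decay = 0.01,
      basal_inflow = 0.055,
      amphi_per_er_cell = 1.0,
      hgf_max = 1.0,
      hgf_half_sat = 1.0,
      mitogen_gain_hgf = 0.28,
      mitogen_gain_amphi = 0.08,
      amphi_half_sat = 0.08,
      tgfb_per_density = 0.044,
      tgfb_escapable = 0.6,
      cmyc_inflow = 0.095,
      v1_amphi = 1.0,
      v2_estrogen_gain = 0.10,
      her2_activation_prob = 0.42,
      her2_multiplier = 1.15,
      egfr_multiplier = 1.15,
      runx3_multiplier = 2.2,
      p_er_daughter = 0.04,
      differentiation_prob = 0.08,
      telomere_initial = 70,
      baseline_apoptosis = 0.004,
      overflow_apoptosis_factor = 0.15,
      senescent_clearance = 0.02,
      signal_radius = 2,
      overflow_capacity = 5,
      invasion_prob = 0.0075,
      invaded_brake = 0.8
    ),
    engine = list(
      width = 100,
      years = 40,
      days_per_year = 365,
      malignancy_fold = 10,
      hyperplasia_fold = 2,
      er_positive_threshold = 0.09,
      her2_positive_threshold = 0.05
    ),
    cohort = list(
      n = 3000,
      ci_method = "wald"
    )
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  for (block in names(overrides)) {
    if (!block %in% names(cfg)) {
      stop("unknown config block: ", block, call. = FALSE)
    }
    for (key in names(overrides[[block]])) {
      if (!key %in% names(cfg[[block]])) {
        stop("unknown config parameter: ", block, "$", key, call. = FALSE)
      }
      cfg[[block]][[key]] <- overrides[[block]][[key]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "ds_config")
}

validate_config <- function(cfg) {
  d <- cfg$damage
  if (d$senescence_threshold >= d$apoptosis_threshold) {
    stop("senescence_threshold must be below apoptosis_threshold", call. = FALSE)
  }
  if (cfg$engine$width < 10) {
    stop("lattice width below 10 columns is degenerate", call. = FALSE)
  }
  stopifnot(
    d$d_max >= 0, d$repair_capacity >= 0, d$beta >= 0,
    d$damage_ceiling >= d$senescence_threshold,
    d$epsilon >= 0, d$epsilon <= 1,
    cfg$cells$telomere_initial >= 0,
    cfg$engine$years > 0
  )
  invisible(cfg)
}

# Flatten the nested config into the single named list the C++ engine reads.
flatten_config <- function(cfg) {
  flat <- c(
    cfg$endocrine,
    list(include_cmet = as.numeric(cfg$genome$include_cmet)),
    cfg$damage,
    cfg$cells,
    cfg$engine
  )
  flat$p53_checkpoint <- as.numeric(cfg$damage$p53_checkpoint)
  flat$n_days <- as.integer(cfg$engine$years * cfg$engine$days_per_year)
  flat
}

#' Read or write a configuration file
#'
#' Configurations round-trip through YAML so that a calibrated parameter set
#' can be saved and reused.
#'
#' @param cfg a `ds_config` object.
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a `ds_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(ds_config, raw)
}

#' @export
print.ds_config <- function(x, ...) {
  cat("<ds_config>\n")
  for (block in names(x)) {
    vals <- vapply(x[[block]], function(v) format(v, digits = 4), character(1))
    cat("  ", block, ": ", paste0(names(vals), "=", vals, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

group_code <- function(group) {
  group <- match.arg(group, c("wild_type", "brca1_carrier"))
  c(wild_type = 0L, brca1_carrier = 1L)[[group]]
}
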