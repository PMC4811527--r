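#' Tidy a cohort summary
#'
#' One row per (group, statistic): malignant/hyperplastic/normal counts and
#' proportions with CI for incidence, plus subtype proportions.
#'
#' @param x a `ds_cohort_summary`.
#' @param ... unused.
#' @return A tibble with columns `group`, `statistic`, `value`, `lower`,
#'   `upper`, `n`.
#' @export
tidy.ds_cohort_summary <- function(x, ...) {
  purrr::imap_dfr(x$groups, function(s, g) {
    base <- tibble::tibble(
      group = g,
      statistic = c("incidence", "hyperplastic_fraction", "normal_fraction"),
      value = c(s$incidence$proportion,
                s$n_hyperplastic / s$n_simulations,
                s$n_normal / s$n_simulations),
      lower = c(s$incidence$lower, NA, NA),
      upper = c(s$incidence$upper, NA, NA),
      n = s$n_simulations
    )
    subs <- tibble::tibble(
      group = g,
      statistic = paste0("subtype ", s$subtype_proportions$subtype),
      value = s$subtype_proportions$proportion,
      lower = NA_real_, upper = NA_real_,
      n = s$n_malignant
    )
    dplyr::bind_rows(base, subs)
  })
}

#' Glance at a cohort summary
#'
#' @param x a `ds_cohort_summary`.
#' @param ... unused.
#' @return A one-row tibble: totals, per-group incidence, pooled hyperplasia
#'   fraction and the mutation-burden contrast p-values.
#' @export
glance.ds_cohort_summary <- function(x, ...) {
  inc <- purrr::imap(x$groups, function(s, g) {
    setNames(s$incidence$proportion, paste0("incidence_", g))
  })
  hyper <- sum(purrr::map_int(x$groups, "n_hyperplastic")) / x$n_total
  tests <- x$mutation_counts$tests
  tibble::as_tibble(c(
    list(n_simulations = x$n_total),
    purrr::flatten(purrr::map(inc, as.list)),
    list(hyperplastic_fraction = hyper),
    setNames(as.list(tests$p_value),
             c("p_er_neg_vs_er_pos", "p_hyper_vs_normal"))
  ))
}

#' Tidy a single simulation result
#'
#' @param x a `ds_result`.
#' @param ... unused.
#' @return A one-row tibble of the scalar outcome fields.
#' @export
tidy.ds_result <- function(x, ...) {
  tibble::tibble(
    group = x$group, seed = x$seed, outcome = x$outcome,
    event_day = x$event_day, final_luminal_count = x$final_luminal_count,
    baseline_luminal_count = x$baseline_luminal_count,
    er_fraction = x$er_fraction, her2_fraction = x$her2_fraction,
    breach = x$breach, total_mutation_count = x$total_mutation_count
  )
}

#' Cohort-summary plots
#'
#' `autoplot()` draws the cumulative-incidence curves per group;
#' `plot_subtypes()` the receptor-subtype profile of malignant runs;
#' `plot_early_mutations()` the per-gene early-mutation frequencies by
#' stratum.
#'
#' @param object a `ds_cohort_summary`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ds_cohort_summary <- function(object, ...) {
  by_age <- purrr::imap_dfr(object$groups, function(s, g) {
    dplyr::mutate(s$incidence_by_age, group = g)
  })
  ggplot2::ggplot(by_age, ggplot2::aes(.data$year,
                                       100 * .data$cumulative_incidence,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "simulated year", y = "cumulative incidence (%)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ds_cohort_summary
#' @param summary a `ds_cohort_summary`.
#' @export
plot_subtypes <- function(summary) {
  subs <- purrr::imap_dfr(summary$groups, function(s, g) {
    dplyr::mutate(s$subtype_proportions, group = g)
  })
  ggplot2::ggplot(subs, ggplot2::aes(.data$subtype, 100 * .data$proportion,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "share of malignant runs (%)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ds_cohort_summary
#' @export
plot_early_mutations <- function(summary) {
  ggplot2::ggplot(summary$early_mutation_freq,
                  ggplot2::aes(.data$gene, 100 * .data$proportion,
                               fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "populations with early mutation (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
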