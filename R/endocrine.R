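#' Hormonal environment of the menstrual cycle
#'
#' The tissue model is forced by a deterministic, strictly periodic 28-day
#' hormone waveform: estrogen with a follicular baseline rising to a single
#' periovulatory peak at day 12 and a smaller luteal plateau (days 17-24), and
#' progesterone with a broad luteal peak centred on day 21. Amplitudes are
#' normalized signalling units set in the `endocrine` config block.
#' Progesterone is carried in the state (PR expression follows ER expression)
#' but has no behavioural hook by default.
#'
#' @param day non-negative simulation day(s); day 0 is the first day of a
#'   cycle and the waveform repeats every 28 days.
#' @param config a [ds_config()] object.
#' @return A tibble with columns `day`, `day_in_cycle`, `estrogen`,
#'   `progesterone`.
#' @examples
#' hormone_level(0:55)
#' @export
hormone_level <- function(day, config = ds_config()) {
  if (any(day < 0)) stop("simulation day must be non-negative", call. = FALSE)
  day <- as.integer(day)
  tab <- cpp_hormone_table(flatten_config(config))
  cyc <- day %% 28L
  tibble::tibble(
    day = day,
    day_in_cycle = cyc,
    estrogen = tab[cyc + 1L, "estrogen"],
    progesterone = tab[cyc + 1L, "progesterone"]
  )
}

#' One full hormone cycle
#'
#' @param config a [ds_config()] object.
#' @return A 28-row tibble (`day_in_cycle`, `estrogen`, `progesterone`),
#'   suitable for writing to CSV for inspection.
#' @examples
#' cyc <- hormone_cycle()
#' which.max(cyc$estrogen) - 1   # periovulatory peak day
#' @export
hormone_cycle <- function(config = ds_config()) {
  hormone_level(0:27, config)[, c("day_in_cycle", "estrogen", "progesterone")]
}

#' Plot the hormone waveform
#'
#' @param config a [ds_config()] object.
#' @return A ggplot object.
#' @export
plot_hormone_cycle <- function(config = ds_config()) {
  cyc <- tidyr::pivot_longer(hormone_cycle(config), -"day_in_cycle",
                             names_to = "hormone", values_to = "level")
  ggplot2::ggplot(cyc, ggplot2::aes(.data$day_in_cycle, .data$level,
                                    colour = .data$hormone)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day of cycle", y = "level (normalized units)") +
    ggplot2::theme_minimal()
}
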