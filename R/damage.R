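#' Daily stochastic DNA damage
#'
#' Each simulated day a cell acquires a random but bounded amount of DNA
#' damage, uniform on `[0, d_max]` (abstract damage units). `d_max` lives in
#' the `damage` config block.
#'
#' @param n number of draws.
#' @param config a [ds_config()].
#' @param seed integer seed for the draw stream.
#' @return Numeric vector of damage increments.
#' @examples
#' mean(daily_damage(1e4, seed = 1))   # ~ d_max / 2
#' @export
daily_damage <- function(n, config = ds_config(), seed = 1L) {
  cpp_daily_damage(as.integer(n), config$damage$d_max, as.integer(seed))
}

#' Daily DNA-damage repair
#'
#' Repair removes a fixed daily capacity of damage, never producing negative
#' damage. Loss of a DNA-repair gene multiplies the capacity by a deficit
#' factor below one (BRCA1 strongly, P53 mildly; the factors compound when
#' both are lost), so damaged lineages with repair deficits accumulate
#' unrepaired damage.
#'
#' A single remaining BRCA1 copy is haploinsufficient for repair: the milder
#' `het_deficit_brca1` multiplier applies in the heterozygous state.
#'
#' @param damage numeric vector of unrepaired damage levels.
#' @param brca1_copies remaining BRCA1 copies (2, 1 or 0).
#' @param p53_null has the cell lost both P53 copies?
#' @param config a [ds_config()].
#' @return Numeric vector of post-repair damage.
#' @export
repair_damage <- function(damage, brca1_copies = 2L, p53_null = FALSE,
                          config = ds_config()) {
  stopifnot(brca1_copies %in% 0:2)
  cpp_repair(as.numeric(damage), as.integer(brca1_copies), p53_null,
             flatten_config(config))
}

#' Mutation hits acquired by one division product
#'
#' At mitosis each product (parent and daughter independently) receives
#' `Bernoulli(min(1, beta * damage)) + Bernoulli(epsilon)` allele hits: a
#' damage-dependent deleterious mutation whose probability is directly
#' (linearly, capped at one) related to the unrepaired damage carried into
#' division, plus an independent baseline replication error. Each hit targets
#' a uniformly chosen gene.
#'
#' @param n number of simulated division products.
#' @param damage unrepaired damage at division (scalar).
#' @param config a [ds_config()].
#' @param seed integer seed.
#' @return Integer vector of hit counts (0, 1 or 2 per product).
#' @export
mutation_count_at_division <- function(n, damage, config = ds_config(),
                                       seed = 1L) {
  cpp_division_hits(as.integer(n), as.numeric(damage), config$damage$beta,
                    config$damage$epsilon, as.integer(seed))
}

#' Damage checkpoint
#'
#' Excessive unrepaired damage triggers apoptosis (above the apoptosis
#' threshold) or senescence (above the lower senescence threshold). Cells
#' that have lost P53 bypass the checkpoint entirely and may divide despite
#' damage.
#'
#' @param damage numeric vector of unrepaired damage levels.
#' @param p53_null has the cell lost both P53 copies?
#' @param config a [ds_config()]; thresholds live in the `damage` block and
#'   must satisfy `senescence_threshold < apoptosis_threshold`.
#' @return A tibble with logical columns `senescence_flagged` and
#'   `apoptosis_flagged` (mutually exclusive).
#' @export
damage_checkpoint <- function(damage, p53_null = FALSE, config = ds_config()) {
  code <- cpp_checkpoint(as.numeric(damage), p53_null, flatten_config(config))
  tibble::tibble(
    damage = as.numeric(damage),
    senescence_flagged = code == 1L,
    apoptosis_flagged = code == 2L
  )
}
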