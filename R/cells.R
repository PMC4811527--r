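#' Amphiregulin production by luminal cells
#'
#' ER+ luminal cells respond to estrogen by producing amphiregulin in
#' proportion to the estrogen level. ESR1 variant V1 produces a high constant
#' output regardless of estrogen supply; V3 a moderate constant output (half
#' of V1). All other cell states produce none.
#'
#' @param cells a cell tibble (as returned by [tissue_cells()]) or any data
#'   frame with columns `er` (logical), `senescent` (logical),
#'   `esr1_variant` (0-3) and a `copies` matrix column (12 genes in
#'   [gene_ids()] order).
#' @param estrogen scalar estrogen level.
#' @param config a [ds_config()].
#' @return Numeric vector, one production rate per cell.
#' @export
produce_amphiregulin <- function(cells, estrogen, config = ds_config()) {
  cpp_amphi(cells$er, cells$senescent, copies_matrix(cells),
            as.integer(cells$esr1_variant), estrogen, flatten_config(config))
}

#' HGF production by fibroblasts
#'
#' Fibroblasts convert local amphiregulin into hepatocyte growth factor with
#' a saturating (Michaelis) response: zero output at zero input, approaching
#' `hgf_max` at high amphiregulin with half-saturation constant
#' `hgf_half_sat`.
#'
#' @param amphiregulin numeric vector of local amphiregulin levels.
#' @param config a [ds_config()].
#' @return Numeric vector of HGF output.
#' @examples
#' produce_hgf(c(0, 1, 10))
#' @export
produce_hgf <- function(amphiregulin, config = ds_config()) {
  if (any(amphiregulin < 0)) stop("amphiregulin must be non-negative", call. = FALSE)
  cpp_hgf(as.numeric(amphiregulin), config$cells$hgf_max, config$cells$hgf_half_sat)
}

#' Intracellular AKT update
#'
#' One day of AKT dynamics for luminal (or myoepithelial) cells: mitogen
#' inputs raise AKT, the TGF-beta tone lowers it, and the level decays toward
#' zero, clamped at zero and capped at the mitosis threshold. ER- luminal and
#' myoepithelial cells respond to HGF through c-Met; ER+ cells respond to
#' amphiregulin through EGFR and to HGF only when c-Met suppression is lost.
#' The HER-2 activating variant and EGFR hyperactivity multiply the mitogen
#' response, RUNX3 loss
#' amplifies the estrogen-driven (amphiregulin) path, c-MYC loss adds a
#' hormone-independent increment, and ESR1 variants V2/V3 add a direct
#' estrogen-to-AKT increment.
#'
#' @param cells a cell data frame with columns `akt`, `er`, `senescent`,
#'   `esr1_variant` and a `copies` matrix column; rows for myoepithelial
#'   cells can be marked with `myoepithelial = TRUE`.
#' @param estrogen scalar estrogen level.
#' @param amphiregulin,hgf,tgfb_density per-cell local signal values
#'   (recycled if scalar): smoothed amphiregulin, HGF, and the smoothed
#'   luminal density driving the TGF-beta tone.
#' @param config a [ds_config()].
#' @return Numeric vector of updated AKT levels.
#' @export
update_akt <- function(cells, estrogen, amphiregulin, hgf, tgfb_density,
                       config = ds_config()) {
  n <- nrow(cells)
  myo <- if ("myoepithelial" %in% names(cells)) cells$myoepithelial else rep(FALSE, n)
  h2a <- if ("her2_active" %in% names(cells)) cells$her2_active else rep(FALSE, n)
  cpp_akt_update(cells$akt, cells$er, myo, copies_matrix(cells),
                 as.integer(cells$esr1_variant), h2a, estrogen,
                 rep_len(as.numeric(amphiregulin), n),
                 rep_len(as.numeric(hgf), n),
                 rep_len(as.numeric(tgfb_density), n),
                 flatten_config(config))
}

#' Anoikis / apoptosis decision
#'
#' A cell dies when it is unadhered (outside the supported luminal layer)
#' without having lost E-cadherin, or when its damage exceeded the apoptosis
#' checkpoint. Anoikis resistance through E-cadherin loss is how
#' non-invasive (hyperplastic) population expansion occurs.
#'
#' @param adhered logical: does the cell occupy a supported layer position?
#' @param anoikis_resistant logical: E-cadherin lost (both copies)?
#' @param apoptosis_flagged logical: damage checkpoint flagged apoptosis?
#' @return Logical: does the cell die?
#' @examples
#' apoptosis_check(adhered = FALSE, anoikis_resistant = FALSE)  # anoikis
#' @export
apoptosis_check <- function(adhered, anoikis_resistant = FALSE,
                            apoptosis_flagged = FALSE) {
  (!adhered & !anoikis_resistant) | apoptosis_flagged
}

#' Basement-membrane invasion decision
#'
#' Only cells that have lost both copies of MMP3 are invasion-capable; a
#' wild-type MMP3 cell can never breach the basement membrane, regardless of
#' position. The engine converts capability into a daily breach probability.
#'
#' @param invasive_capable logical: MMP3 lost (both copies)?
#' @param alive logical.
#' @param senescent logical.
#' @return Logical: can the cell breach the membrane?
#' @export
invasion_check <- function(invasive_capable, alive = TRUE, senescent = FALSE) {
  invasive_capable & alive & !senescent
}

copies_matrix <- function(cells) {
  cp <- cells$copies
  if (is.null(cp)) stop("cells must carry a `copies` matrix column", call. = FALSE)
  cp <- as.matrix(cp)
  storage.mode(cp) <- "integer"
  if (ncol(cp) != 12L) stop("`copies` must have 12 gene columns", call. = FALSE)
  cp
}
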