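#' The twelve-gene functional genome
#'
#' Cells carry two copies of each of twelve genes prominently implicated in
#' breast cancer. A gene's functional effect manifests only when both copies
#' are lost (the two-hit rule). `gene_ids()` returns the fixed reporting
#' order; `gene_table()` maps each gene to the cellular function it governs.
#'
#' @return `gene_ids()`: a character vector of length 12 (or 11 when the
#'   c-Met axis is disabled in the config); `gene_table()`: a tibble with
#'   columns `gene` and `function_class`.
#' @examples
#' gene_ids()
#' @export
gene_ids <- function(include_cmet = TRUE) {
  ids <- c("BRCA1", "P53", "HER2", "TGFB_R", "EGFR", "RUNX3",
           "CMYC", "ESR1", "TELOMERASE", "ECADHERIN", "MMP3", "CMET")
  if (include_cmet) ids else ids[-12L]
}

#' @rdname gene_ids
#' @param include_cmet keep the c-Met axis as gene 12 (default); the 11-gene
#'   variant of the genome is available for comparison.
#' @export
gene_table <- function(include_cmet = TRUE) {
  tibble::tibble(
    gene = gene_ids(TRUE),
    function_class = c(
      "DNA damage repair", "DNA damage repair / cell-cycle checkpoint",
      "growth-factor receptor (mitogen response)",
      "growth inhibition (TGF-beta receptor)",
      "growth-factor receptor (mitogen response)",
      "estrogen-driven proliferation restraint",
      "hormone-independent growth",
      "estrogen receptor (variant signalling)",
      "replicative lifespan / senescence",
      "cell-cell adhesion (anoikis)",
      "basement-membrane invasion",
      "HGF receptor suppression in ER+ cells"
    )
  )[seq_len(if (include_cmet) 12L else 11L), ]
}

#' Initial genome for a simulation group
#'
#' Wild-type cells start with two functioning copies of every gene and an
#' empty mutation history. BRCA1-carrier cells start with a single copy of
#' BRCA1 (the germline heterozygote analogue): one further hit suffices to
#' lose DNA-repair function, but the carrier state itself has no functional
#' effect and no recorded history.
#'
#' @param group `"wild_type"` or `"brca1_carrier"`.
#' @return A `ds_genome`: list with `copies` (named integer vector in
#'   `{0,1,2}`) and `history` (tibble of mutation events: `gene`, `day`,
#'   `ordinal`, `variant`).
#' @examples
#' initial_genome("brca1_carrier")$copies[["BRCA1"]]
#' @export
initial_genome <- function(group = c("wild_type", "brca1_carrier")) {
  group <- match.arg(group)
  copies <- setNames(rep(2L, 12L), gene_ids())
  if (group == "brca1_carrier") copies[["BRCA1"]] <- 1L
  new_genome(copies, empty_history())
}

empty_history <- function() {
  tibble::tibble(gene = character(), day = integer(), ordinal = integer(),
                 variant = character())
}

new_genome <- function(copies, history) {
  structure(list(copies = copies, history = history), class = "ds_genome")
}

#' @export
print.ds_genome <- function(x, ...) {
  lost <- names(x$copies)[x$copies == 0L]
  het <- names(x$copies)[x$copies == 1L]
  cat("<ds_genome> ", nrow(x$history), " mutation event(s)",
      if (length(het)) paste0("; 1 copy: ", paste(het, collapse = ",")) else "",
      if (length(lost)) paste0("; lost: ", paste(lost, collapse = ",")) else "",
      "\n", sep = "")
  invisible(x)
}

#' Apply one mutation (allele loss) to a genome
#'
#' Decrements the gene's copy number by one and appends a mutation event with
#' the next ordinal. Mutations are value-semantic: the input genome is
#' unchanged, so daughter cells inherit snapshots. A hit to a gene already at
#' zero copies is absorbed (no functional meaning; not recorded). When the
#' hit drops ESR1 to zero copies, one of three variant behaviours (V1-V3) is
#' drawn uniformly; use `variant` to force a specific one.
#'
#' @param genome a `ds_genome`.
#' @param gene a gene symbol from [gene_ids()].
#' @param day non-negative simulation day of the event.
#' @param variant optional: `"V1"`, `"V2"` or `"V3"` for the second ESR1 hit
#'   (default draws uniformly), or `"ACT"` to force the HER-2 activating
#'   variant at the second HER2 hit.
#' @param her2_activation probability that the second HER2 hit produces the
#'   activating (overexpressing) variant rather than a plain loss.
#' @return The mutated `ds_genome`.
#' @examples
#' g <- initial_genome("wild_type")
#' g2 <- apply_mutation(apply_mutation(g, "P53", 10), "P53", 400)
#' effect_profile(g2)$checkpoint_loss
#' @export
apply_mutation <- function(genome, gene, day = 0L, variant = NULL,
                           her2_activation = 0.5) {
  stopifnot(inherits(genome, "ds_genome"))
  if (!gene %in% names(genome$copies)) stop("unknown gene: ", gene, call. = FALSE)
  if (day < 0) stop("day must be non-negative", call. = FALSE)
  if (genome$copies[[gene]] == 0L) {
    return(genome)  # absorbed: no copy left to lose
  }
  copies <- genome$copies
  copies[[gene]] <- copies[[gene]] - 1L
  tag <- NA_character_
  if (gene == "ESR1" && copies[[gene]] == 0L) {
    tag <- if (is.null(variant)) sample(c("V1", "V2", "V3"), 1L) else {
      match.arg(variant, c("V1", "V2", "V3"))
    }
  }
  if (gene == "HER2" && copies[[gene]] == 0L) {
    tag <- if (is.null(variant)) {
      if (stats::runif(1) < her2_activation) "ACT" else NA_character_
    } else {
      match.arg(variant, "ACT")
    }
  }
  event <- tibble::tibble(gene = gene, day = as.integer(day),
                          ordinal = nrow(genome$history) + 1L, variant = tag)
  new_genome(copies, dplyr::bind_rows(genome$history, event))
}

#' Functional effect profile of a genome
#'
#' Pure function of the copy-number map plus the stored variant tags: each
#' behavioural flag is active iff the corresponding gene is at zero copies,
#' except HER-2, whose overexpression additionally requires that the second
#' hit produced the activating variant (tag `"ACT"`).
#'
#' @param genome a `ds_genome`.
#' @return A one-row tibble of logical flags (`repair_deficit_brca1`,
#'   `repair_deficit_p53`, `checkpoint_loss`, `her2_active`,
#'   `tgfb_insensitive`, `egfr_hyperactive`, `runx3_loss`,
#'   `hormone_independent_growth`, `telomerase_active`, `anoikis_resistant`,
#'   `invasive_capable`, `cmet_unsuppressed`) and `er_variant`
#'   (`"none"`, `"V1"`, `"V2"` or `"V3"`).
#' @export
effect_profile <- function(genome) {
  stopifnot(inherits(genome, "ds_genome"))
  cp <- genome$copies
  null_of <- function(g) unname(cp[[g]] == 0L)
  variant <- "none"
  if (null_of("ESR1")) {
    tags <- genome$history$variant[genome$history$gene == "ESR1"]
    tags <- tags[!is.na(tags)]
    if (length(tags)) variant <- tags[[length(tags)]]
  }
  her2_act <- null_of("HER2") &&
    any(genome$history$variant[genome$history$gene == "HER2"] == "ACT",
        na.rm = TRUE)
  tibble::tibble(
    repair_deficit_brca1 = null_of("BRCA1"),
    repair_deficit_p53 = null_of("P53"),
    checkpoint_loss = null_of("P53"),
    her2_active = her2_act,
    tgfb_insensitive = null_of("TGFB_R"),
    egfr_hyperactive = null_of("EGFR"),
    runx3_loss = null_of("RUNX3"),
    hormone_independent_growth = null_of("CMYC"),
    er_variant = variant,
    telomerase_active = null_of("TELOMERASE"),
    anoikis_resistant = null_of("ECADHERIN"),
    invasive_capable = null_of("MMP3"),
    cmet_unsuppressed = null_of("CMET")
  )
}

#' Early mutations of a lineage history
#'
#' A mutation is "early" when it is one of the first `k` events acquired by a
#' cell lineage (default `k = 5`). A gene may qualify through either of its
#' two hits.
#'
#' @param history a mutation-history tibble (`gene`, `ordinal`, ...), e.g.
#'   `genome$history` or the `dominant_history` of a simulation result.
#' @param k early-window size (events), default 5.
#' @return Character vector of unique genes mutated within the window.
#' @export
early_mutations <- function(history, k = 5L) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  unique(history$gene[history$ordinal <= k])
}

#' Serialize lineage records as JSON lines
#'
#' One record per population: the final copy-number map of the dominant
#' lineage and its ordered mutation history. The format round-trips and is
#' shared with the cohort reports.
#'
#' @param results a cohort run tibble from [run_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(results, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(results))) {
    rec <- list(
      seed = results$seed[[i]],
      group = results$group[[i]],
      outcome = results$outcome[[i]],
      copies = as.list(results$dominant_copies[[i]]),
      history = results$dominant_history[[i]]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_lineages
#' @export
read_lineages <- function(path) {
  lines <- readLines(path)
  purrr::map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}
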