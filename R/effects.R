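# The four headline contrasts of the analysis, bundled so simulation
# studies can score them per dataset.

#' Run the four headline contrasts on one dataset
#'
#' Computes, from a dataset list (simulated or read from disk):
#' \describe{
#'   \item{lethal_disease}{Fisher p for disease-status by lethality among
#'     genes with a knockout report (DL/DV vs L/V).}
#'   \item{dl_dv_degree}{Wilcoxon-Mann-Whitney p comparing the network
#'     degrees of DL and DV member proteins.}
#'   \item{dl_nuclear}{BH-adjusted q for nucleus over-representation in DL
#'     against all disease genes (cellular_component namespace).}
#'   \item{dl_dominant}{Fisher p for the DL autosomal-dominant vs
#'     autosomal-recessive excess over the other disease genes.}
#' }
#'
#' @param dataset A dataset list from [simulate_dataset()] or
#'   [read_dataset()].
#' @return A tibble with columns `effect`, `estimate` (odds ratio or mean
#'   degree difference), `p_value` (`dl_nuclear` reports the BH-adjusted q);
#'   `NA` rows where a contrast is not computable (e.g. an empty group).
#' @export
detect_effects <- function(dataset) {
  cl <- classify_dataset(dataset)
  counts <- table(factor(cl$group, levels = c("DL", "DV", "DU", "L", "V",
                                              "NONDISEASE_UNKNOWN")))

  # disease x lethality among knockouts
  led <- if (counts[["DL"]] + counts[["DV"]] > 0 && counts[["L"]] + counts[["V"]] > 0) {
    fisher_2x2(c(counts[["DL"]], counts[["DV"]], counts[["L"]], counts[["V"]]))
  }

  # DL vs DV member degrees
  net <- build_network(dataset$ppi)
  deg_dl <- degree_sequence(net, members = cl$gene_id[cl$group == "DL"])
  deg_dv <- degree_sequence(net, members = cl$gene_id[cl$group == "DV"])
  dd <- if (length(deg_dl) > 0 && length(deg_dv) > 0) {
    compare_degree_distributions(deg_dl, deg_dv)
  }

  # nucleus over-representation in DL vs all disease genes
  cc <- dataset$annotations |>
    filter(.data$namespace == "cellular_component") |>
    distinct(.data$gene_id, .data$term)
  nuc <- if (nrow(cc) > 0 && counts[["DL"]] > 0) {
    enr <- class_term_enrichment(cl, cc, groups = "DL", background = "all_disease")
    enr[enr$term == "nucleus", ]
  }

  # DL dominant excess
  tally <- tally_inheritance(cl, dataset$disease)
  dvr <- if (sum(tally$n[tally$group == "DL" & tally$mode %in% c("AD", "AR")]) > 0 &&
             sum(tally$n[tally$group != "DL" & tally$mode %in% c("AD", "AR")]) > 0) {
    dominant_vs_recessive_test(tally, "DL")
  }

  tibble(
    effect = c("lethal_disease", "dl_dv_degree", "dl_nuclear", "dl_dominant"),
    estimate = c(
      if (is.null(led)) NA_real_ else led$odds_ratio,
      if (is.null(dd)) NA_real_ else mean(deg_dl) - mean(deg_dv),
      if (is.null(nuc) || nrow(nuc) == 0) NA_real_ else nuc$odds_ratio,
      if (is.null(dvr)) NA_real_ else dvr$odds_ratio
    ),
    p_value = c(
      if (is.null(led)) NA_real_ else led$p_value,
      if (is.null(dd)) NA_real_ else dd$p_value[dd$method == "wilcoxon_mann_whitney"],
      if (is.null(nuc) || nrow(nuc) == 0) NA_real_ else nuc$q_bh,
      if (is.null(dvr)) NA_real_ else dvr$p_value
    )
  )
}
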