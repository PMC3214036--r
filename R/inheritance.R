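# Mode-of-inheritance tallies per essentiality group. A gene can carry
# several modes (different alleles with different inheritance patterns), so
# it may count once in AD and once in AR; proportions are over genes in the
# group that have any inheritance annotation and need not sum to 1.

#' Tally inheritance modes per essentiality group
#'
#' Counts, per group, the genes with at least one autosomal-dominant (AD),
#' autosomal-recessive (AR) or X-linked (X) allele. Duplicate association
#' rows are collapsed (set semantics per gene x mode). The denominator is
#' the number of genes in the group with any inheritance annotation.
#'
#' @param classified Tibble from [classify_essentiality()].
#' @param disease Disease-association tibble from [read_disease_table()]
#'   (columns `gene_id`, `inheritance_mode`).
#' @param groups Groups to report.
#' @return A tibble with columns `group`, `mode`, `n`, `n_annotated`,
#'   `proportion` (`NA` when the group has no annotated genes).
#' @export
tally_inheritance <- function(classified, disease,
                              groups = c("DL", "DV", "DU")) {
  stopifnot(all(c("gene_id", "group") %in% names(classified)),
            all(c("gene_id", "inheritance_mode") %in% names(disease)))
  pairs <- disease |>
    filter(.data$inheritance_mode %in% c("AD", "AR", "X")) |>
    distinct(.data$gene_id, .data$inheritance_mode) |>
    inner_join(select(classified, "gene_id", "group"), by = "gene_id")
  list_rbind(map(groups, function(g) {
    gp <- filter(pairs, .data$group == g)
    denom <- n_distinct(gp$gene_id)
    n_mode <- vapply(c("AD", "AR", "X"),
                     function(m) sum(gp$inheritance_mode == m), integer(1))
    tibble(
      group = g,
      mode = c("AD", "AR", "X"),
      n = unname(n_mode),
      n_annotated = denom,
      proportion = if (denom == 0) NA_real_ else unname(n_mode) / denom
    )
  }))
}

#' Test a group's dominant-vs-recessive excess
#'
#' 2x2 Fisher contrast of (group vs all other disease genes) by (AD vs AR
#' mode assignments), testing whether the group — typically the
#' disease-lethal set — carries proportionally more dominant alleles than
#' the rest of the disease genes.
#'
#' @param tally Tibble from [tally_inheritance()]; must include `group` and
#'   at least one other group as the comparison.
#' @param group Focal group, default `"DL"`.
#' @return A one-row tibble from [fisher_2x2()] (`a` = focal AD count,
#'   `b` = focal AR, `c`/`d` = comparison AD/AR).
#' @export
dominant_vs_recessive_test <- function(tally, group = "DL") {
  stopifnot(all(c("group", "mode", "n") %in% names(tally)))
  focal <- filter(tally, .data$group == !!group)
  rest <- filter(tally, .data$group != !!group)
  if (nrow(focal) == 0 || nrow(rest) == 0) {
    abort("tally must contain the focal group and at least one comparison group")
  }
  n_of <- function(df, m) sum(df$n[df$mode == m])
  a <- n_of(focal, "AD"); b <- n_of(focal, "AR")
  c_ <- n_of(rest, "AD"); d <- n_of(rest, "AR")
  if ((a + b) == 0 || (c_ + d) == 0) {
    abort("empty margin in dominant-vs-recessive contrast")
  }
  fisher_2x2(c(a, b, c_, d))
}
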