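# Class-vs-rest annotation enrichment: for each (group, term) pair, a 2x2
# Fisher contrast of the group against the background minus the group, with
# BH-FDR control within each namespace-by-group family.

#' Annotation enrichment of essentiality groups
#'
#' For every requested group and every term in the annotation namespace,
#' builds the 2x2 table (group vs background-minus-group) x (has term vs
#' lacks term), tests it with [fisher_2x2()], and adjusts p-values with
#' [bh_adjust()] separately within each group (the FDR family is
#' namespace x group). A gene carrying a term any number of times counts
#' once per term.
#'
#' @param classified Tibble from [classify_essentiality()].
#' @param annotations Tibble from [read_annotations()] (columns `gene_id`,
#'   `term`).
#' @param groups Character vector of groups to test (e.g. `c("DL", "DV")`).
#' @param background `"all_disease"` (default; the usual group-vs-all-disease
#'   contrast) or `"all_genes"` (genome-style contrasts).
#' @return A tibble with columns `group`, `term`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_raw`, `q_bh`, `direction` (`over` when the odds ratio
#'   exceeds 1, else `under`), sorted by `group` then `q_bh`.
#' @export
class_term_enrichment <- function(classified, annotations,
                                  groups = c("DL", "DV"),
                                  background = c("all_disease", "all_genes")) {
  background <- arg_match(background)
  stopifnot(all(c("gene_id", "group") %in% names(classified)),
            all(c("gene_id", "term") %in% names(annotations)))
  bg_genes <- if (background == "all_disease") {
    classified$gene_id[classified$group %in% c("DL", "DV", "DU")]
  } else {
    classified$gene_id
  }
  if (length(bg_genes) == 0) {
    abort("empty background gene set")
  }
  ann <- annotations |>
    filter(.data$gene_id %in% bg_genes) |>
    distinct(.data$gene_id, .data$term)
  terms <- sort(unique(ann$term))
  grp_of <- set_names(classified$group, classified$gene_id)

  rows <- map(groups, function(g) {
    members <- intersect(classified$gene_id[classified$group == g], bg_genes)
    rest <- setdiff(bg_genes, members)
    if (length(rest) == 0) {
      abort(paste0("group '", g, "' equals the whole background; no contrast possible"))
    }
    per_term <- map(terms, function(tm) {
      with_term <- ann$gene_id[ann$term == tm]
      a <- sum(members %in% with_term)
      c_ <- sum(rest %in% with_term)
      f <- fisher_2x2(c(a, length(members) - a, c_, length(rest) - c_))
      mutate(f, group = g, term = tm, .before = 1)
    })
    list_rbind(per_term) |>
      mutate(q_bh = bh_adjust(.data$p_value))
  })
  list_rbind(rows) |>
    mutate(
      direction = dplyr::if_else(!is.na(.data$odds_ratio) & .data$odds_ratio > 1,
                                 "over", "under"),
      p_raw = .data$p_value
    ) |>
    select("group", "term", "a", "b", "c", "d",
           "odds_ratio", "p_raw", "q_bh", "direction") |>
    arrange(match(.data$group, groups), .data$q_bh, .data$term)
}
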