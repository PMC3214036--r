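# Essentiality groups inferred from mouse knockout phenotypes:
#   L  — knockout lethal, not a disease gene
#   V  — knockout viable, not a disease gene
#   DL — disease gene, knockout lethal ("essential disease gene")
#   DV — disease gene, knockout viable
#   DU — disease gene, no knockout report
#   NONDISEASE_UNKNOWN — neither disease nor knockout data

#' Default lethal phenotype term stems
#'
#' Knockout phenotype annotations counted as lethal: embryonic, prenatal,
#' perinatal and postnatal lethality. Stems are matched case-insensitively as
#' substrings, because phenotype strings vary ("embryonic lethality",
#' "lethal, embryonic").
#'
#' @return A character vector of lethal term stems.
#' @export
default_lethal_terms <- function() {
  c("embryonic lethal", "prenatal lethal", "perinatal lethal",
    "postnatal lethal", "lethality")
}

#' Decide lethality from a gene's phenotype term set
#'
#' A gene is `"lethal"` if any phenotype term contains any lethal stem
#' (case-insensitive substring; any-lethal-wins across alleles), `"viable"`
#' if it has at least one phenotype report and none match, and `"unknown"`
#' if it has no knockout report at all.
#'
#' @param phenotype_terms Character vector of phenotype terms for one gene
#'   (possibly empty).
#' @param lethal_terms Character vector of lethal stems; see
#'   [default_lethal_terms()].
#' @return One of `"lethal"`, `"viable"`, `"unknown"`.
#' @export
is_lethal <- function(phenotype_terms, lethal_terms = default_lethal_terms()) {
  stopifnot(length(lethal_terms) > 0)
  if (length(phenotype_terms) == 0) {
    return("unknown")
  }
  hay <- tolower(phenotype_terms)
  hit <- any(vapply(
    tolower(lethal_terms),
    function(stem) any(grepl(stem, hay, fixed = TRUE)),
    logical(1)
  ))
  if (hit) "lethal" else "viable"
}

#' Assign every gene to an essentiality group
#'
#' Combines knockout lethality (see [is_lethal()]) with disease status.
#' Disease genes fall in exactly one of DL, DV, DU; non-disease genes get
#' L, V or NONDISEASE_UNKNOWN.
#'
#' @param gene_table Tibble from [read_gene_table()] (columns `gene_id`,
#'   `ko_phenotypes`, `is_disease`, ...).
#' @param lethal_terms Lethal stems passed to [is_lethal()].
#' @return The input tibble with added columns `lethality`
#'   (`lethal`/`viable`/`unknown`) and `group`.
#' @export
classify_essentiality <- function(gene_table, lethal_terms = default_lethal_terms()) {
  stopifnot(is.data.frame(gene_table),
            all(c("gene_id", "ko_phenotypes", "is_disease") %in% names(gene_table)))
  if (anyDuplicated(gene_table$gene_id) > 0) {
    abort("gene_id must be unique in a gene table")
  }
  gene_table |>
    mutate(
      lethality = map_chr(.data$ko_phenotypes, is_lethal, lethal_terms = lethal_terms),
      group = case_when(
        .data$is_disease & .data$lethality == "lethal" ~ "DL",
        .data$is_disease & .data$lethality == "viable" ~ "DV",
        .data$is_disease ~ "DU",
        .data$lethality == "lethal" ~ "L",
        .data$lethality == "viable" ~ "V",
        TRUE ~ "NONDISEASE_UNKNOWN"
      )
    )
}

#' Tabulate essentiality groups and headline shares
#'
#' Counts genes per group and derives the headline percentages: the lethal
#' share among disease genes of known essentiality, DL/(DL+DV); the lethal
#' share among all knockouts, (DL+L)/(DL+L+DV+V); and each disease group's
#' share of all disease genes. Shares with a zero denominator are reported
#' as `NA` rather than NaN.
#'
#' @param classified Tibble from [classify_essentiality()].
#' @return An object of class `essgenes_tab`: a tibble with columns `group`,
#'   `n`, `pct_of_disease` (for DL/DV/DU rows, percent of all disease genes,
#'   integer precision), carrying the headline shares as attributes
#'   (retrieve them with [glance()]).
#' @export
tabulate_groups <- function(classified) {
  stopifnot("group" %in% names(classified))
  counts <- classified |>
    count(.data$group, name = "n") |>
    arrange(match(.data$group, c("V", "L", "DV", "DL", "DU", "NONDISEASE_UNKNOWN")))
  n_of <- function(g) sum(counts$n[counts$group == g])
  dl <- n_of("DL"); dv <- n_of("DV"); du <- n_of("DU")
  l_tot <- n_of("L") + dl
  v_tot <- n_of("V") + dv
  d_tot <- dl + dv + du
  tab <- counts |>
    mutate(pct_of_disease = dplyr::if_else(
      .data$group %in% c("DL", "DV", "DU"),
      map_dbl(.data$n, pct_of, denom = d_tot, digits = 0),
      NA_real_
    ))
  structure(
    tab,
    class = c("essgenes_tab", class(tab)),
    shares = list(
      lethal_share_known_pct = pct_of(dl, dl + dv, digits = 0),
      lethal_share_knockouts_pct = pct_of(l_tot, l_tot + v_tot, digits = 0),
      dl_share_of_disease_pct = pct_of(dl, d_tot, digits = 0),
      dv_share_of_disease_pct = pct_of(dv, d_tot, digits = 0),
      du_share_of_disease_pct = pct_of(du, d_tot, digits = 0),
      n_disease = d_tot,
      n_knockout = l_tot + v_tot
    )
  )
}

#' @export
glance.essgenes_tab <- function(x, ...) {
  as_tibble(attr(x, "shares"))
}

#' Housekeeping-gene overlap with the disease-unknown group
#'
#' Contrasts the housekeeping-gene fraction inside the DU group with the
#' genome-wide fraction. The non-DU side of the 2x2 is computed against the
#' full genome size, since input files cover only annotated genes: non-DU
#' housekeeping count = housekeeping genes in the table outside DU, and the
#' remaining genome fills the last cell.
#'
#' @param classified Tibble from [classify_essentiality()] with
#'   `is_housekeeping` flags.
#' @param genome_size Total number of genes in the genome (default 24789);
#'   must be at least the number of observed genes.
#' @param group Group contrasted against the rest of the genome (default
#'   `"DU"`).
#' @return A list with `table` (2x2 matrix, rows in-group/not-in-group,
#'   columns housekeeping/not), `group_pct`, `genome_pct` (one decimal,
#'   half-up), and `test` (chi-square statistic and p-value; `NULL` when a
#'   margin is empty, in which case `odds_ratio` is `NA`).
#' @export
housekeeping_overlap <- function(classified, genome_size = 24789, group = "DU") {
  stopifnot(all(c("group", "is_housekeeping") %in% names(classified)))
  n_obs <- nrow(classified)
  if (genome_size < n_obs) {
    abort(paste0("genome_size (", genome_size, ") smaller than observed genes (", n_obs, ")"))
  }
  in_grp <- classified$group == group
  a <- sum(in_grp & classified$is_housekeeping)
  b <- sum(in_grp & !classified$is_housekeeping)
  c_ <- sum(!in_grp & classified$is_housekeeping)
  d <- genome_size - (a + b) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("in_group", "not_in_group"),
                                c("housekeeping", "not_housekeeping")))
  hk_total <- a + c_
  res <- list(
    table = tab,
    group_pct = pct_of(a, a + b, digits = 1),
    genome_pct = pct_of(hk_total, genome_size, digits = 1),
    odds_ratio = if (b == 0 || c_ == 0) NA_real_ else (a * d) / (b * c_),
    test = NULL
  )
  if (hk_total > 0 && (a + b) > 0 && (c_ + d) > 0 && (b + d) > 0) {
    res$test <- chi_square_2x2(tab, continuity_correction = FALSE)
  }
  res
}
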