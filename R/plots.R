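# ggplot2 views of the main result types. Each returns a ggplot object so
# callers can restyle freely.

#' Bar chart of essentiality group sizes
#'
#' @param tab An `essgenes_tab` from [tabulate_groups()].
#' @return A ggplot object.
#' @export
plot_group_counts <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("group", "n") %in% names(tab)))
  df <- as_tibble(tab)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$group, levels = .data$group),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "essentiality group", y = "genes") +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment results
#'
#' Odds ratio (log scale) against term, coloured by direction, with solid
#' points for contrasts significant at `alpha` after FDR adjustment.
#'
#' @param enrichment Tibble from [class_term_enrichment()].
#' @param alpha FDR threshold marking significance.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, alpha = 0.05) {
  stopifnot(all(c("term", "odds_ratio", "q_bh", "group") %in% names(enrichment)))
  df <- enrichment |>
    filter(is.finite(.data$odds_ratio), .data$odds_ratio > 0) |>
    mutate(significant = .data$q_bh < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$term,
                                   colour = .data$direction,
                                   alpha = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "odds ratio", y = NULL) +
    ggplot2::theme_minimal()
}

#' Empirical degree distributions of group subnetworks
#'
#' @param classified Tibble from [classify_essentiality()].
#' @param network An `igraph` graph from [build_network()].
#' @param groups Groups to overlay.
#' @return A ggplot object (complementary cumulative degree distribution,
#'   log-log).
#' @export
plot_degree_distributions <- function(classified, network,
                                      groups = c("DL", "DV", "L", "V", "DU")) {
  df <- list_rbind(map(groups, function(g) {
    members <- classified$gene_id[classified$group == g]
    sub <- category_subnetwork(network, members, mode = "one_or_both")
    deg <- degree_sequence(sub)
    if (length(deg) == 0) {
      return(NULL)
    }
    tibble(group = g, degree = sort(deg),
           ccdf = rev(seq_along(deg)) / length(deg))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$ccdf,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "P(degree >= d)") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-group mechanism proportions
#'
#' @param proportions The `proportions` tibble from [classify_corpus()].
#' @return A ggplot object.
#' @export
plot_mechanism <- function(proportions) {
  stopifnot(all(c("group", "call", "proportion", "method") %in% names(proportions)))
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$call, y = .data$proportion,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
    ggplot2::labs(x = "mechanism", y = "proportion of classified records") +
    ggplot2::theme_minimal()
}

#' Bar chart of inheritance-mode proportions per group
#'
#' @param tally Tibble from [tally_inheritance()].
#' @return A ggplot object.
#' @export
plot_inheritance <- function(tally) {
  stopifnot(all(c("group", "mode", "proportion") %in% names(tally)))
  ggplot2::ggplot(filter(tally, !is.na(.data$proportion)),
                  ggplot2::aes(x = .data$mode, y = .data$proportion,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "mode of inheritance", y = "proportion of annotated genes") +
    ggplot2::theme_minimal()
}
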