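# Protein-protein interaction network construction and per-group summaries.
# Networks are undirected simple graphs: self-edges dropped, duplicate pairs
# (in either order) collapsed, node set = endpoints of surviving edges.

#' Build a simple undirected interaction network from raw pairs
#'
#' Self-pairs are ignored and duplicate pairs (either orientation) are
#' collapsed, so degree counts each interaction partner once.
#'
#' @param edge_list Tibble from [read_edge_list()] (columns `protein_a`,
#'   `protein_b`), or any data frame whose first two columns are protein ids.
#' @return An `igraph` undirected simple graph.
#' @export
build_network <- function(edge_list) {
  stopifnot(is.data.frame(edge_list), ncol(edge_list) >= 2)
  a <- as.character(edge_list[[1]])
  b <- as.character(edge_list[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  pairs <- unique(tibble(lo = lo, hi = hi))
  igraph::graph_from_data_frame(pairs, directed = FALSE)
}

#' Extract a category subnetwork
#'
#' Quantitative summaries use the one-or-both rule: every interaction where
#' at least one partner belongs to the category is kept, so partner proteins
#' of other categories appear in the subnetwork. The both rule (both
#' endpoints in the category) is the visualization convention. The node set
#' is always the endpoints of the kept edges.
#'
#' @param network An `igraph` graph from [build_network()].
#' @param members Character vector of category member ids (ids absent from
#'   the network are allowed).
#' @param mode `"one_or_both"` (default) or `"both"`.
#' @return An `igraph` subnetwork.
#' @export
category_subnetwork <- function(network, members, mode = c("one_or_both", "both")) {
  mode <- arg_match(mode)
  el <- igraph::as_edgelist(network, names = TRUE)
  in_a <- el[, 1] %in% members
  in_b <- el[, 2] %in% members
  keep <- if (mode == "both") in_a & in_b else in_a | in_b
  kept <- el[keep, , drop = FALSE]
  igraph::graph_from_data_frame(as.data.frame(kept), directed = FALSE)
}

#' Summarise an interaction network
#'
#' Computes the standard group-network report: protein and interaction
#' counts, maximum and average degree (average degree = 2E/V over
#' interacting proteins), component count, and the largest connected
#' component's protein and interaction percentages and average degree. The
#' LCC is the component with most proteins; ties break by higher edge count,
#' then by lexicographically smallest member id.
#'
#' @param network An `igraph` graph.
#' @return A one-row tibble: `proteins`, `interactions`, `max_degree`,
#'   `avg_degree`, `components`, `lcc_protein_pct`, `lcc_interaction_pct`,
#'   `lcc_avg_degree`. An empty network yields zeros (percentages `NA`).
#' @export
summarize_network <- function(network) {
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  if (n == 0) {
    return(tibble(
      proteins = 0L, interactions = 0L, max_degree = 0L, avg_degree = 0,
      components = 0L, lcc_protein_pct = NA_real_,
      lcc_interaction_pct = NA_real_, lcc_avg_degree = NA_real_
    ))
  }
  deg <- igraph::degree(network)
  comp <- igraph::components(network)
  names_v <- igraph::V(network)$name
  # per-component edge counts: both endpoints share the component label
  el <- igraph::as_edgelist(network, names = TRUE)
  edge_comp <- comp$membership[el[, 1]]
  edges_per_comp <- tabulate(edge_comp, nbins = comp$no)
  smallest_member <- vapply(
    seq_len(comp$no),
    function(i) min(names_v[comp$membership == i]),
    character(1)
  )
  ord <- order(-comp$csize, -edges_per_comp, smallest_member)
  lcc <- ord[[1]]
  lcc_n <- comp$csize[[lcc]]
  lcc_m <- edges_per_comp[[lcc]]
  tibble(
    proteins = as.integer(n),
    interactions = as.integer(m),
    max_degree = as.integer(max(deg)),
    avg_degree = 2 * m / n,
    components = as.integer(comp$no),
    lcc_protein_pct = 100 * lcc_n / n,
    lcc_interaction_pct = if (m == 0) NA_real_ else 100 * lcc_m / m,
    lcc_avg_degree = if (lcc_n == 0) NA_real_ else 2 * lcc_m / lcc_n
  )
}

#' Degree sequence of a network
#'
#' @param network An `igraph` graph.
#' @param members Optional character vector restricting the sequence to
#'   nodes in this set (nodes absent from the network are ignored).
#' @return An integer vector of node degrees, ordered by node name.
#' @export
degree_sequence <- function(network, members = NULL) {
  deg <- igraph::degree(network)
  if (!is.null(members)) {
    deg <- deg[names(deg) %in% members]
  }
  unname(deg[order(names(deg))])
}

#' Per-group network summary table
#'
#' For each essentiality group (rows ordered DL, DV, L, V, DU), extracts the
#' one-or-both subnetwork and summarises it with [summarize_network()].
#' Percentages are rounded to integers and averages to one decimal in the
#' report columns.
#'
#' @param classified Tibble from [classify_essentiality()].
#' @param network An `igraph` graph from [build_network()].
#' @param groups Groups to report, in report order.
#' @return A tibble with a `group` column followed by the
#'   [summarize_network()] columns.
#' @export
network_group_summary <- function(classified, network,
                                  groups = c("DL", "DV", "L", "V", "DU")) {
  stopifnot("group" %in% names(classified))
  rows <- map(groups, function(g) {
    members <- classified$gene_id[classified$group == g]
    sub <- category_subnetwork(network, members, mode = "one_or_both")
    mutate(summarize_network(sub), group = g, .before = 1)
  })
  list_rbind(rows) |>
    mutate(
      avg_degree = round_half_up(.data$avg_degree, 1),
      lcc_avg_degree = round_half_up(.data$lcc_avg_degree, 1),
      lcc_protein_pct = round_half_up(.data$lcc_protein_pct, 0),
      lcc_interaction_pct = round_half_up(.data$lcc_interaction_pct, 0)
    )
}

#' Per-group edge lists for visualization
#'
#' Returns, for each group, the both-endpoint subnetwork's edge list (the
#' convention used to draw group networks) as a tibble.
#'
#' @inheritParams network_group_summary
#' @return A named list of tibbles with columns `protein_a`, `protein_b`.
#' @export
group_edge_lists <- function(classified, network,
                             groups = c("DL", "DV", "L", "V", "DU")) {
  stopifnot("group" %in% names(classified))
  out <- map(set_names(groups), function(g) {
    members <- classified$gene_id[classified$group == g]
    sub <- category_subnetwork(network, members, mode = "both")
    el <- igraph::as_edgelist(sub, names = TRUE)
    tibble(protein_a = as.character(el[, 1]), protein_b = as.character(el[, 2]))
  })
  out
}
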