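# Independent oracles, deliberately naive: plain-R BFS for network
# summaries, factorial enumeration for exact tests, and a literal step-up
# loop for the FDR adjustment. They share no code with the implementation.

# --- network: brute-force summary from an edge data.frame (cols a, b) ---
oracle_network_summary <- function(edges) {
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b), paste(edges$b, edges$a))
  edges <- edges[!duplicated(key), , drop = FALSE]
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  if (n == 0) {
    return(list(proteins = 0L, interactions = 0L, max_degree = 0L,
                avg_degree = 0, components = 0L,
                lcc_protein_pct = NA_real_, lcc_interaction_pct = NA_real_,
                lcc_avg_degree = NA_real_))
  }
  adj <- setNames(vector("list", n), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges$a[r]; b <- edges$b[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  comp <- setNames(rep(NA_integer_, n), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[[start]])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  csize <- tabulate(comp, nbins = cid)
  ecomp <- comp[edges$a]
  cedges <- tabulate(ecomp, nbins = cid)
  smallest <- vapply(seq_len(cid), function(i) min(nodes[comp == i]), character(1))
  ord <- order(-csize, -cedges, smallest)
  lcc <- ord[[1]]
  list(
    proteins = n,
    interactions = nrow(edges),
    max_degree = as.integer(max(deg)),
    avg_degree = 2 * nrow(edges) / n,
    components = cid,
    lcc_protein_pct = 100 * csize[[lcc]] / n,
    lcc_interaction_pct = if (nrow(edges) == 0) NA_real_ else 100 * cedges[[lcc]] / nrow(edges),
    lcc_avg_degree = 2 * cedges[[lcc]] / csize[[lcc]]
  )
}

random_edge_df <- function(n_nodes, n_pairs) {
  nodes <- sprintf("p%03d", seq_len(n_nodes))
  data.frame(
    a = sample(nodes, n_pairs, replace = TRUE),
    b = sample(nodes, n_pairs, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# --- Fisher: exhaustive fixed-margin enumeration with choose() products ---
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n_ <- c_ + d; k <- a + c_
  total <- choose(m + n_, k)
  xs <- max(0, k - n_):min(k, m)
  probs <- choose(m, xs) * choose(n_, k - xs) / total
  p_obs <- choose(m, a) * choose(n_, k - a) / total
  min(1, sum(probs[probs <= p_obs * (1 + 1e-07)]))
}

# --- BH: literal step-up as written in the definition ---
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    q[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# --- WMW: exact two-sided p by full enumeration of rank assignments ---
oracle_wmw_p <- function(x, y) {
  m <- length(x); n_ <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n_, m)
  w_all <- apply(idx, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
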