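# One-command orchestration: classification -> network summaries ->
# enrichments -> mechanism -> inheritance, writing every intermediate table
# as TSV plus one JSON summary. All outputs are plain text so runs diff
# cleanly; re-running with unchanged inputs yields byte-identical files.

#' Run the full analysis pipeline on a dataset directory
#'
#' Reads the flat-file set from `input_dir` (layout of [write_dataset()]),
#' runs every stage, and writes `table1.tsv` (group counts),
#' `table2.tsv` (per-group network summaries),
#' `enrichment_<namespace>.tsv` per annotation namespace,
#' `mechanism.tsv`, `inheritance.tsv`, `summary.json` (headline shares and
#' per-stage row counts) and `run.log` to `output_dir`.
#'
#' @param input_dir Directory of input files.
#' @param output_dir Output directory, created if needed.
#' @param genome_size Genome size for the housekeeping contrast.
#' @param lethal_terms Lethal phenotype stems.
#' @param background Enrichment background (see [class_term_enrichment()]).
#' @param enrichment_groups Groups tested for enrichment.
#' @param fdr_alpha Significance threshold recorded in the summary.
#' @param genicity_filter Mechanism-stage record filter (`"monogenic_only"`
#'   drops genes with any polygenic association).
#' @param train_nb_on_labels Train the naive-Bayes route on the records'
#'   `label` column when present.
#' @return Invisibly, a list with every stage result plus the output paths.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         genome_size = 24789,
                         lethal_terms = default_lethal_terms(),
                         background = "all_disease",
                         enrichment_groups = c("DL", "DV"),
                         fdr_alpha = 0.05,
                         genicity_filter = "monogenic_only",
                         train_nb_on_labels = TRUE) {
  if (!(is.numeric(fdr_alpha) && fdr_alpha > 0 && fdr_alpha < 1)) {
    abort("fdr_alpha must lie in (0, 1)")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            parent = e)
    })
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  logf <- file.path(output_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  say("essgenes pipeline, package version ",
      as.character(utils::packageVersion("essgenes")))
  say("input_dir=", normalizePath(input_dir),
      " genome_size=", genome_size, " background=", background,
      " fdr_alpha=", fdr_alpha, " genicity_filter=", genicity_filter)

  dataset <- stage("read", read_dataset(input_dir))
  say("read: ", nrow(dataset$orthology), " orthology rows, ",
      nrow(dataset$disease), " disease rows, ", nrow(dataset$ppi), " raw pairs")

  classified <- stage("classify", classify_dataset(dataset, lethal_terms))
  tab <- stage("tabulate", tabulate_groups(classified))
  shares <- glance(tab)
  hk <- stage("housekeeping", housekeeping_overlap(classified, genome_size))
  say("classify: ", nrow(classified), " genes")

  network <- stage("network", build_network(dataset$ppi))
  table2 <- stage("network_summary", network_group_summary(classified, network))
  say("network: ", igraph::vcount(network), " proteins, ",
      igraph::ecount(network), " interactions")

  namespaces <- sort(unique(dataset$annotations$namespace))
  enrichments <- stage("enrichment", {
    set_names(map(namespaces, function(ns) {
      ann <- dataset$annotations |>
        filter(.data$namespace == ns) |>
        distinct(.data$gene_id, .data$term)
      class_term_enrichment(classified, ann, groups = enrichment_groups,
                            background = background)
    }), namespaces)
  })
  for (ns in namespaces) {
    say("enrichment[", ns, "]: ", nrow(enrichments[[ns]]), " contrasts")
  }

  model <- NULL
  if (train_nb_on_labels && any(!is.na(dataset$records$label)) &&
      all(c("gain", "loss", "neutral") %in% dataset$records$label)) {
    model <- stage("train_nb",
                   train_nb(filter(dataset$records, !is.na(.data$label))))
  }
  lexicon <- dataset$lexicon %||% default_lexicon()
  mechanism <- stage("mechanism", classify_corpus(
    dataset$records, classified, lexicon = lexicon, model = model,
    disease = dataset$disease, genicity_filter = genicity_filter
  ))
  say("mechanism: ", nrow(mechanism$calls), " records classified; agreement=",
      format(mechanism$agreement, digits = 3))

  tally <- stage("inheritance", tally_inheritance(classified, dataset$disease))
  dvr <- NULL
  if (sum(tally$n[tally$group == "DL"]) > 0 &&
      sum(tally$n[tally$group != "DL"]) > 0) {
    dvr <- stage("inheritance_test", dominant_vs_recessive_test(tally, "DL"))
  }

  # ---- write outputs ----
  p <- function(f) file.path(output_dir, f)
  write_tsv_plain(as_tibble(tab), p("table1.tsv"))
  write_tsv_plain(table2, p("table2.tsv"))
  for (ns in namespaces) {
    write_tsv_plain(enrichments[[ns]], p(paste0("enrichment_", ns, ".tsv")))
  }
  write_tsv_plain(mechanism$calls, p("mechanism.tsv"))
  write_tsv_plain(tally, p("inheritance.tsv"))
  summary <- list(
    shares = as.list(shares),
    housekeeping = list(
      group_pct = hk$group_pct, genome_pct = hk$genome_pct,
      table = as.vector(t(hk$table)),
      chisq_p = if (is.null(hk$test)) NA else hk$test$p_value
    ),
    mechanism_agreement = mechanism$agreement,
    dominant_vs_recessive = if (is.null(dvr)) NULL else
      list(odds_ratio = dvr$odds_ratio, p_value = dvr$p_value),
    fdr_alpha = fdr_alpha,
    n_genes = nrow(classified)
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  writeLines(log_lines, logf)

  invisible(list(
    classified = classified, tabulation = tab, housekeeping = hk,
    network = network, table2 = table2, enrichments = enrichments,
    mechanism = mechanism, inheritance = tally,
    dominant_vs_recessive = dvr, summary = summary, output_dir = output_dir
  ))
}
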