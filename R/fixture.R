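# Deterministic benchmark fixture: a gene universe whose group sizes equal
# the 2011-era survey landscape of human disease genes by mouse-knockout
# essentiality (673 disease-lethal, 120 disease-viable, 1172
# disease-unknown, 626 lethal and 552 viable non-disease genes, with 64
# housekeeping genes inside the disease-unknown set and 609 in a
# 24,789-gene genome), so the tabulation stage has exact known answers.

#' Deterministic fixture with realistic group sizes
#'
#' Builds, with no randomness, the flat-file inputs for a gene table whose
#' essentiality groups have the canonical sizes above. Lethal genes carry an
#' "embryonic lethality" phenotype row, viable genes "abnormal gait";
#' disease-unknown genes have an ortholog but no phenotype report.
#' Housekeeping flags place 64 genes in the disease-unknown group and the
#' remaining 545 (of a 609-gene genome-wide set) among the other observed
#' genes, so the genome-level housekeeping contrast at `genome_size = 24789`
#' is fully determined.
#'
#' @return A dataset list in the [simulate_dataset()] layout (without
#'   records/lexicon), plus `genome_size`.
#' @export
reference_fixture <- function() {
  sizes <- c(DL = 673, DV = 120, DU = 1172, L = 626, V = 552)
  group <- rep(names(sizes), sizes)
  n <- length(group)
  gene_id <- sprintf("g%05d", seq_len(n))
  is_disease <- group %in% c("DL", "DV", "DU")
  has_ko <- group %in% c("DL", "DV", "L", "V")
  lethal <- group %in% c("DL", "L")

  mouse_id <- sprintf("Mm_%05d", seq_len(n))
  orthology <- tibble(human_gene_id = gene_id, mouse_gene_id = mouse_id)
  phenotypes <- tibble(
    mouse_gene_id = mouse_id[has_ko],
    phenotype_term = ifelse(lethal[has_ko], "embryonic lethality", "abnormal gait")
  )
  disease <- tibble(
    gene_id = gene_id[is_disease],
    disease_id = sprintf("dis%05d", seq_len(sum(is_disease))),
    disease_class = "unclassified system",
    inheritance_mode = "",
    genicity = ""
  )
  # 64 housekeeping genes inside DU, 545 spread over the other groups
  du_ids <- gene_id[group == "DU"]
  other_ids <- gene_id[group != "DU"]
  housekeeping <- c(head(du_ids, 64), head(other_ids, 545))

  list(
    orthology = orthology,
    phenotypes = phenotypes,
    disease = disease,
    housekeeping = housekeeping,
    ppi = tibble(protein_a = character(), protein_b = character(),
                 source = character()),
    annotations = tibble(gene_id = character(), namespace = character(),
                         term = character()),
    records = tibble(record_id = character(), gene_id = character(),
                     label = character(), text = character()),
    ground_truth = tibble(gene_id = gene_id, group = group),
    genome_size = 24789L
  )
}

#' Classify a dataset list without touching disk
#'
#' Convenience wrapper used by the pipeline and tests: builds the joined
#' gene table from in-memory dataset tibbles and classifies it.
#'
#' @param dataset A dataset list from [simulate_dataset()],
#'   [reference_fixture()] or [read_dataset()].
#' @param lethal_terms Lethal stems for [is_lethal()].
#' @return A classified gene table (see [classify_essentiality()]).
#' @export
classify_dataset <- function(dataset, lethal_terms = default_lethal_terms()) {
  gene_table <- build_gene_table(dataset$orthology, dataset$phenotypes,
                                 unique(dataset$disease$gene_id),
                                 dataset$housekeeping)
  classify_essentiality(gene_table, lethal_terms = lethal_terms)
}
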