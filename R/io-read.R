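# Flat-file readers. All files are UTF-8 TSV with a header row; lines starting
# with "!" are comments (GAF convention). Missing optional fields are empty
# strings, never "NA". Identifiers are opaque case-sensitive strings.

read_tsv_strict <- function(path, required_cols, optional_cols = character()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "!")
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    abort(paste0(path, ": no header line"))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required_cols, header)
  if (length(missing) > 0) {
    abort(paste0(path, ": missing column(s): ", paste(missing, collapse = ", ")))
  }
  body <- lines[-1]
  body_no <- line_no[-1]
  nonblank <- nzchar(body)
  body <- body[nonblank]
  body_no <- body_no[nonblank]
  cols <- c(required_cols, intersect(optional_cols, header))
  if (length(body) == 0) {
    out <- as_tibble(setNames(rep(list(character()), length(cols)), cols))
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty field is dropped by strsplit; pad rather than error
  short <- which(nf < length(header))
  hard_short <- short[nf[short] < length(required_cols)]
  if (length(hard_short) > 0) {
    i <- hard_short[[1]]
    abort(paste0(
      path, ", line ", body_no[[i]], ": expected at least ",
      length(required_cols), " fields, found ", nf[[i]]
    ))
  }
  mat <- t(vapply(fields, function(f) {
    length(f) <- length(header)
    f
  }, character(length(header))))
  mat[is.na(mat)] <- ""
  out <- as_tibble(setNames(lapply(match(cols, header), function(j) mat[, j]), cols))
  out
}

#' Read and join the per-gene input files into a gene table
#'
#' Builds one row per human gene from four flat files: a disease-gene table,
#' a human-mouse orthology table, a mouse knockout-phenotype table and a
#' housekeeping gene list. Phenotype terms are attached to human genes through
#' the orthology mapping; genes without any knockout report keep an empty
#' phenotype set. The gene universe is the union of genes seen in the disease,
#' orthology and housekeeping files.
#'
#' @param orthology Path to a TSV with columns `human_gene_id`,
#'   `mouse_gene_id`.
#' @param phenotypes Path to a TSV with columns `mouse_gene_id`,
#'   `phenotype_term`, one row per phenotype report.
#' @param disease Path to a TSV with columns `gene_id`, `disease_id`,
#'   `disease_class`, `inheritance_mode` (`AD`, `AR`, `X` or empty) and
#'   `genicity` (`monogenic`, `polygenic` or empty).
#' @param housekeeping Path to a text file with one gene id per line, or
#'   `NULL` for no housekeeping flags.
#'
#' @return A tibble with one row per gene: `gene_id`, `mouse_ortholog`
#'   (`NA` when unmapped), `ko_phenotypes` (list-column of character vectors,
#'   `character(0)` when no knockout report exists), `is_disease`,
#'   `is_housekeeping`.
#' @seealso [classify_essentiality()]
#' @export
read_gene_table <- function(orthology, phenotypes, disease, housekeeping = NULL) {
  orth <- read_tsv_strict(orthology, c("human_gene_id", "mouse_gene_id"))
  if (anyDuplicated(orth$human_gene_id) > 0) {
    dup <- orth$human_gene_id[duplicated(orth$human_gene_id)][[1]]
    abort(paste0(orthology, ": duplicate human_gene_id: ", dup))
  }
  phen <- read_tsv_strict(phenotypes, c("mouse_gene_id", "phenotype_term"))
  dis <- read_disease_table(disease)
  hk <- if (is.null(housekeeping)) character() else read_gene_list(housekeeping)

  build_gene_table(orth, phen, unique(dis$gene_id), hk)
}

# Shared left-join assembly of the per-gene view; the gene universe is the
# union of genes seen in the orthology, disease and housekeeping inputs.
build_gene_table <- function(orth, phen, disease_ids, hk_ids) {
  universe <- unique(c(orth$human_gene_id, disease_ids, hk_ids))
  pheno_sets <- phen |>
    distinct(.data$mouse_gene_id, .data$phenotype_term) |>
    group_by(.data$mouse_gene_id) |>
    summarise(terms = list(sort(.data$phenotype_term)), .groups = "drop")

  tibble(gene_id = universe) |>
    left_join(orth, by = c(gene_id = "human_gene_id")) |>
    left_join(pheno_sets, by = "mouse_gene_id") |>
    mutate(
      mouse_ortholog = dplyr::if_else(
        is.na(.data$mouse_gene_id) | .data$mouse_gene_id == "",
        NA_character_, .data$mouse_gene_id
      ),
      ko_phenotypes = map(.data$terms, \(x) x %||% character()),
      is_disease = .data$gene_id %in% disease_ids,
      is_housekeeping = .data$gene_id %in% hk_ids
    ) |>
    select("gene_id", "mouse_ortholog", "ko_phenotypes", "is_disease", "is_housekeeping")
}

#' Read a disease-association table
#'
#' One row per (gene, disease) association with the flattened disease class,
#' inheritance mode and genicity labels.
#'
#' @param path Path to the disease TSV (see [read_gene_table()]).
#' @return A tibble with columns `gene_id`, `disease_id`, `disease_class`,
#'   `inheritance_mode`, `genicity`.
#' @export
read_disease_table <- function(path) {
  dis <- read_tsv_strict(
    path, c("gene_id", "disease_id"),
    optional_cols = c("disease_class", "inheritance_mode", "genicity")
  )
  for (col in c("disease_class", "inheritance_mode", "genicity")) {
    if (!col %in% names(dis)) dis[[col]] <- ""
  }
  bad <- which(!dis$inheritance_mode %in% c("AD", "AR", "X", ""))
  if (length(bad) > 0) {
    abort(paste0(
      path, ": invalid inheritance_mode '", dis$inheritance_mode[bad[[1]]],
      "' (row ", bad[[1]], "); expected AD, AR, X or empty"
    ))
  }
  bad <- which(!dis$genicity %in% c("monogenic", "polygenic", ""))
  if (length(bad) > 0) {
    abort(paste0(
      path, ": invalid genicity '", dis$genicity[bad[[1]]],
      "' (row ", bad[[1]], "); expected monogenic, polygenic or empty"
    ))
  }
  dis
}

#' Read a one-id-per-line gene list
#'
#' @param path Path to a text file with one gene id per line; "!" comment
#'   lines and blank lines are skipped.
#' @return A character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  unique(lines[nzchar(lines) & !startsWith(lines, "!")])
}

#' Read a protein-protein interaction edge list
#'
#' Returns the raw pairs verbatim — duplicates, reversed duplicates and
#' self-pairs included. Cleaning (self-edge removal, deduplication) happens in
#' [build_network()].
#'
#' @param path Path to a TSV with columns `protein_a`, `protein_b` and an
#'   optional `source` tag.
#' @return A tibble with columns `protein_a`, `protein_b`, `source`.
#' @export
read_edge_list <- function(path) {
  el <- read_tsv_strict(path, c("protein_a", "protein_b"), optional_cols = "source")
  if (!"source" %in% names(el)) el$source <- ""
  el
}

#' Read a gene-annotation table for one namespace
#'
#' Accepts the native three-column layout (`gene_id`, `namespace`, `term`) or
#' a GAF-style file via `col_map`, mapping those roles onto other column
#' names (e.g. `DB Object ID`, `Aspect`, `GO ID`). Only rows in the requested
#' namespace are kept; multi-term genes are aggregated.
#'
#' @param path Path to the annotation TSV.
#' @param namespace Namespace to retain, e.g. `"cellular_component"` or
#'   `"disease_class"`.
#' @param col_map Named character vector mapping the roles `gene_id`,
#'   `namespace`, `term` to column names in the file.
#' @return A tibble with columns `gene_id`, `term` (one row per distinct
#'   pair) and a `namespace` attribute. An empty tibble plus a warning if the
#'   file holds none of the requested namespace.
#' @export
read_annotations <- function(path, namespace,
                             col_map = c(gene_id = "gene_id",
                                         namespace = "namespace",
                                         term = "term")) {
  stopifnot(all(c("gene_id", "namespace", "term") %in% names(col_map)))
  raw <- read_tsv_strict(path, unname(col_map))
  ann <- tibble(
    gene_id = raw[[col_map[["gene_id"]]]],
    namespace = raw[[col_map[["namespace"]]]],
    term = raw[[col_map[["term"]]]]
  )
  blank <- which(ann$term == "")
  if (length(blank) > 0) {
    abort(paste0(path, ": empty term string (data row ", blank[[1]], ")"))
  }
  out <- ann |>
    filter(.data$namespace == !!namespace) |>
    distinct(.data$gene_id, .data$term)
  if (nrow(out) == 0) {
    warn(paste0(path, ": no annotations in namespace '", namespace, "'"))
  }
  structure(out, namespace = namespace)
}

#' Read free-text disease records
#'
#' @param path Path to a TSV with columns `record_id`, `gene_id`, `text` and
#'   an optional `label` column holding a known mechanism class (`gain`,
#'   `loss` or `neutral`).
#' @return A tibble with columns `record_id`, `gene_id`, `label` (`NA` when
#'   unknown), `text`.
#' @export
read_text_records <- function(path) {
  rec <- read_tsv_strict(path, c("record_id", "gene_id", "text"),
                         optional_cols = "label")
  if (!"label" %in% names(rec)) rec$label <- NA_character_
  rec$label[!is.na(rec$label) & rec$label == ""] <- NA_character_
  bad <- which(!is.na(rec$label) & !rec$label %in% c("gain", "loss", "neutral"))
  if (length(bad) > 0) {
    abort(paste0(path, ": invalid label '", rec$label[bad[[1]]], "'"))
  }
  if (anyDuplicated(rec$record_id) > 0) {
    dup <- rec$record_id[duplicated(rec$record_id)][[1]]
    abort(paste0(path, ": duplicate record_id: ", dup))
  }
  select(rec, "record_id", "gene_id", "label", "text")
}
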