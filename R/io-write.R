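# Writers mirror the readers field-for-field so every table round-trips.

write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, na = "", escape = "none", eol = "\n")
  invisible(path)
}

#' Write a synthetic or real dataset as the pipeline's flat-file set
#'
#' Emits the file layout the readers consume: `orthology.tsv`,
#' `phenotypes.tsv`, `disease.tsv`, `housekeeping.txt`, `ppi.tsv`,
#' `annotations.tsv`, `records.tsv`, `lexicon.tsv`, and — when ground truth
#' is present — `ground_truth.tsv`.
#'
#' @param dataset A dataset list as returned by [simulate_dataset()] or
#'   [reference_fixture()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv_plain(dataset$orthology, p("orthology.tsv"))
  write_tsv_plain(dataset$phenotypes, p("phenotypes.tsv"))
  write_tsv_plain(dataset$disease, p("disease.tsv"))
  writeLines(dataset$housekeeping, p("housekeeping.txt"))
  write_tsv_plain(dataset$ppi, p("ppi.tsv"))
  write_tsv_plain(dataset$annotations, p("annotations.tsv"))
  write_tsv_plain(dataset$records, p("records.tsv"))
  if (!is.null(dataset$lexicon)) {
    write_tsv_plain(dataset$lexicon, p("lexicon.tsv"))
  }
  if (!is.null(dataset$ground_truth)) {
    write_tsv_plain(dataset$ground_truth, p("ground_truth.tsv"))
  }
  invisible(dir)
}

#' Read a flat-file dataset directory back into memory
#'
#' Inverse of [write_dataset()]: loads the file set from `dir` into the raw
#' tibbles the analysis functions consume.
#'
#' @param dir Directory holding the flat-file set.
#' @return A list with elements `orthology`, `phenotypes`, `disease`,
#'   `housekeeping`, `ppi`, `annotations`, `records` and, when present,
#'   `lexicon`.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("orthology.tsv", "phenotypes.tsv", "disease.tsv",
              "housekeeping.txt", "ppi.tsv", "annotations.tsv", "records.tsv")) {
    if (!file.exists(p(f))) abort(paste0("missing input file: ", p(f)))
  }
  out <- list(
    orthology = read_tsv_strict(p("orthology.tsv"), c("human_gene_id", "mouse_gene_id")),
    phenotypes = read_tsv_strict(p("phenotypes.tsv"), c("mouse_gene_id", "phenotype_term")),
    disease = read_disease_table(p("disease.tsv")),
    housekeeping = read_gene_list(p("housekeeping.txt")),
    ppi = read_edge_list(p("ppi.tsv")),
    annotations = read_tsv_strict(p("annotations.tsv"), c("gene_id", "namespace", "term")),
    records = read_text_records(p("records.tsv"))
  )
  if (file.exists(p("lexicon.tsv"))) {
    out$lexicon <- read_lexicon(p("lexicon.tsv"))
  }
  out
}
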