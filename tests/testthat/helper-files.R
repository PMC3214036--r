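# Tiny file-writing helpers for reader tests. Everything is generated in
# code at test time; nothing is stored in the repository.

write_lines_tmp <- function(lines, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

tsv_lines <- function(header, rows) {
  c(paste(header, collapse = "\t"),
    vapply(rows, paste, character(1), collapse = "\t"))
}

# Minimal consistent input set: 3 genes (one lethal disease, one viable,
# one disease with no knockout data).
tiny_input_dir <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  writeLines(c("human_gene_id\tmouse_gene_id", "TP53\tTrp53", "ACTB\tActb"),
             file.path(dir, "orthology.tsv"))
  writeLines(c("mouse_gene_id\tphenotype_term",
               "Trp53\tembryonic lethality",
               "Actb\tabnormal gait"),
             file.path(dir, "phenotypes.tsv"))
  writeLines(c("gene_id\tdisease_id\tdisease_class\tinheritance_mode\tgenicity",
               "TP53\tdis1\tcancer\tAD\tmonogenic",
               "BRCA9\tdis2\tcancer\tAR\tmonogenic"),
             file.path(dir, "disease.tsv"))
  writeLines("TP53", file.path(dir, "housekeeping.txt"))
  writeLines(c("protein_a\tprotein_b\tsource", "TP53\tACTB\tsyn"),
             file.path(dir, "ppi.tsv"))
  writeLines(c("gene_id\tnamespace\tterm",
               "TP53\tcellular_component\tnucleus",
               "ACTB\tcellular_component\tcytoplasm"),
             file.path(dir, "annotations.tsv"))
  writeLines(c("record_id\tgene_id\tlabel\ttext",
               "r1\tTP53\tloss\tdeficiency of protein"),
             file.path(dir, "records.tsv"))
  dir
}
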