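# essgenes

Essentiality-stratified analysis of human disease genes.

## The problem

Are essential genes — genes whose mouse-ortholog knockouts are lethal —
real human disease genes, or do they only cause miscarriage and birth
defects? Earlier disease-gene surveys lumped genes with *no* knockout data
into the "non-essential" class, which swamps that class with genes of
unknown status and drives the conclusion that most disease genes are
non-essential. `essgenes` implements the stratification that avoids this:
disease genes are split into **DL** (disease, knockout lethal), **DV**
(disease, knockout viable) and **DU** (disease, knockout unknown), with
non-disease knockouts as **L** / **V**, and each group is characterised
separately.

The package is aimed at computational biologists who want to run — or
stress-test — this stratified characterisation on their own flat-file
snapshots of orthology, knockout-phenotype, disease, interaction and
annotation data.

## What it computes

- **Classification**: per-gene essentiality groups from knockout phenotype
  terms (configurable lethal stems, any-lethal-wins), group tabulations
  with headline shares, and the housekeeping-gene overlap of DU against a
  genome background.
- **PPI networks**: undirected simple graph construction, per-group
  subnetworks under the one-or-both membership rule, Table-style summaries
  (proteins, interactions, max/average degree = 2E/V, components, largest
  connected component shares), and degree-distribution comparisons
  (two-sided Wilcoxon–Mann–Whitney and Kolmogorov–Smirnov).
- **Enrichment**: two-sided Fisher's exact test on 2×2 tables (p = sum of
  hypergeometric probabilities ≤ the observed table's; odds ratio ad/bc),
  Pearson chi-square, and Benjamini–Hochberg step-up FDR within each
  namespace × group family, applied to disease-class and GO-slim-style
  annotations against an all-disease or all-genes background.
- **Mechanism**: gain / loss / other classification of free-text disease
  records by lexicon word scoring (prefix stems) and by an in-package
  multinomial naive-Bayes classifier with frequent- and shared-word
  exclusion, plus their agreement rate.
- **Inheritance**: per-group AD / AR / X tallies (a gene counts in every
  mode it exhibits) and the DL dominant-vs-recessive Fisher contrast.
- **Synthetic data**: a seeded generator (`simulate_dataset()`) emitting
  the full input file set with known ground truth — Chung–Lu interaction
  network with lethality/nuclearity degree boosts, group-tilted label
  distributions, keyword-emission mechanism texts — and a deterministic
  fixture (`reference_fixture()`) whose group sizes make the tabulation
  stage exactly checkable.

All user-facing functions take data frames and return tibbles, so stages
chain with the pipe; `run_pipeline()` orchestrates everything over a
directory of inputs and writes plain TSV/JSON outputs.

## Worked example

```r
library(essgenes)

# deterministic fixture with canonical group sizes
fx <- reference_fixture()
cl <- classify_dataset(fx)
glance(tabulate_groups(cl))
#>   lethal_share_known_pct lethal_share_knockouts_pct dl_share_of_disease_pct
#> 1                     85                         66                      34
#>   dv_share_of_disease_pct du_share_of_disease_pct n_disease n_knockout
#> 1                       6                      60      1965       1971
```

85% of disease genes with a knockout report are essential (673/793), even
though lethal knockouts are only 66% of all published knockouts — the
disease set is enriched for essential genes. DL alone is 34% of all
disease genes; DV just 6%.

```r
# a full synthetic run with known ground truth
ds <- simulate_dataset(synthetic_config(), seed = 1)
dir <- tempfile(); write_dataset(ds, dir)
res <- run_pipeline(dir, file.path(dir, "out"), genome_size = 5000)

res$table2
#>   group proteins interactions max_degree avg_degree components lcc_protein_pct ...
#> 1    DL     1160         1192         14        2.1         38              86
#> 2    DV      132          103          8        1.6         29               8
#> 3     L     1651         1888         12        2.3         36              93
#> 4     V      966          789          7        1.6        177               6
#> 5    DU      564          436          9        1.5        128               4

dplyr::filter(res$enrichments$cellular_component, group == "DL") |> head(2)
#>   group            term   a   b  c   d odds_ratio        p_raw         q_bh direction
#> 1    DL         nucleus 159 125 69 149      2.747 5.390e-08    2.695e-07      over
#> 2    DL plasma membrane  36 248 54 164      0.441 6.171e-04    1.543e-03     under

res$dominant_vs_recessive
#>   odds_ratio      p_value   a   b  c   d
#> 1      2.091 0.0001124729 155 100 86 116
```

The planted structure is recovered: DL proteins have the highest average
degree after L, the nucleus is over-represented in DL (odds ratio 2.7,
q ≈ 3e-07) while the plasma membrane is under-represented, and DL shows a
significant autosomal-dominant excess over the other disease genes
(odds ratio 2.1).

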