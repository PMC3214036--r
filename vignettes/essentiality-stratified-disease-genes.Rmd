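---
title: "Essentiality-stratified analysis of human disease genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essentiality-stratified analysis of human disease genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essgenes)
library(dplyr)
```

## The scientific question

Human disease genes are often treated as one homogeneous class, and genes
whose mouse-knockout orthologs die during development ("essential" genes)
have historically been assumed to cause miscarriage rather than recognisable
disease. `essgenes` implements the opposite stratification: it splits
disease genes by the phenotype of their mouse ortholog's targeted deletion
and then asks whether the resulting groups differ — in the physiological
systems their diseases affect, in how connected their proteins are in
protein–protein interaction (PPI) networks, in subcellular localization, in
the mutational mechanism (gain vs loss of function), and in mode of
inheritance.

The key modelling decision is the treatment of missing knockout data. A gene
whose ortholog has never been knocked out is *not* evidence of viability.
The package therefore assigns every gene to one of six groups:

| group | definition |
|---|---|
| `DL` | disease gene, knockout lethal ("essential disease gene") |
| `DV` | disease gene, knockout viable |
| `DU` | disease gene, no knockout report |
| `L`, `V` | non-disease genes with lethal / viable knockouts |
| `NONDISEASE_UNKNOWN` | neither disease association nor knockout data |

Collapsing `DU` into `DV`, as earlier stratifications did, dominates the
"non-essential" class with genes of unknown status and reverses the headline
conclusion; keeping `DU` separate is the whole point of the design.

## Lethality calls

A knockout is called lethal when any of its phenotype annotations contains
any of the configurable lethal stems (default: embryonic / prenatal /
perinatal / postnatal lethality, matched case-insensitively as substrings,
because curated phenotype strings vary in word order). A gene with both
lethal and viable reports — different alleles, different papers — is called
lethal: *any-lethal-wins*. This replaces manual curation of redundant
reports with a deterministic precedence rule; it is monotone (adding a
lethal report can only move a gene into the lethal class and affects no
other gene) which is what the test suite asserts.

Tabulated percentages are reported at integer precision for the headline
shares and one decimal for the housekeeping contrast, rounded half-up, so a
share of 84.87% prints as 85%.

## Network statistics

The PPI network is an undirected simple graph: self-interactions are
dropped and duplicate pairs (in either orientation) collapsed, pooling all
interaction sources as a plain union without evidence weighting. For each
gene group the *one-or-both* rule defines the quantitative subnetwork —
every interaction with at least one partner in the group — so partner
proteins of other groups legitimately appear in a group's subnetwork. The
*both-endpoint* rule is used only for exported visualization edge lists.

Each subnetwork is summarised by protein and interaction counts, maximum
and average degree (average degree is $2E/V$ over interacting proteins;
isolated category members are excluded by construction since the node set
is the endpoints of kept edges), component count, and the largest connected
component's share of proteins and interactions. LCC ties — which real data
of this size never produce — break by protein count, then edge count, then
lexicographically smallest member, making the summary fully deterministic.
Degree distributions of two groups are compared with two-sided
Wilcoxon–Mann–Whitney and Kolmogorov–Smirnov tests.

Component labelling and degrees are delegated to `igraph`; the test suite
checks every summary field against an independent plain-R BFS
recomputation on hundreds of random graphs.

## Enrichment machinery

Every categorical contrast is a 2×2 table — rows: in-group vs rest;
columns: has-term vs lacks-term. `fisher_2x2()` implements the two-sided
conditional exact test directly: with margins fixed, the p-value sums the
hypergeometric probabilities of all tables whose point probability does not
exceed the observed one (with the standard `1 + 1e-7` tolerance against
floating-point ties). The reported odds ratio is the sample estimate
$ad/bc$, with 0, `Inf` and `NA` conventions for zero cells. The
chi-square route is the Pearson 1-df statistic (Yates correction available
but off by default, since the tables of interest here have large counts).

For annotation enrichment (`class_term_enrichment()`), the default
background is *all disease genes*, matching the group-vs-disease-set
contrasts this analysis makes; `all_genes` serves genome-style contrasts
such as the housekeeping overlap. False-discovery control uses
Benjamini–Hochberg step-up adjustment, applied within each namespace ×
group family — the most conservative family structure consistent with
per-analysis correction. Genes carrying a term multiple times count once
per term.

## Mechanism text classification

Free-text disease records are classified as gain / loss / other by two
deliberately independent routes, whose agreement rate is itself a reported
statistic:

1. **Lexicon word score.** Each category owns a set of lowercase stems
   (e.g. loss: "deficien", gain: "activat", neutral: "translocat"); a
   token matches a stem by *prefix*, so "activat" hits "activation" and
   "activating". The category with the most matching tokens wins; all-zero
   scores and exact ties return `unclassified`, which is excluded from
   proportion denominators. The shipped `default_lexicon()` is a small
   seed meant to be replaced by users with curated vocabularies.
2. **Multinomial naive Bayes** with add-$\alpha$ smoothing
   ($\alpha = 1$), trained on labelled records. Two vocabulary filters
   mirror classical practice: words whose document frequency reaches 0.5
   of training documents are dropped, and words occurring in training
   documents of *every* class are dropped as non-discriminating. Neither
   cutoff has a canonical value; 0.5 removes function-word-like tokens
   while keeping class keywords in corpora where keywords appear in under
   half the documents. Out-of-vocabulary tokens are ignored at
   classification time, so a document with no vocabulary words receives
   the prior as posterior, and an exact posterior tie is `unclassified`.

The final per-record call is the word-score call, falling back to naive
Bayes when the word score is unclassifiable. Genicity filtering
(`monogenic_only`) drops records for genes with any polygenic association
before proportions are tabulated, since mono- and polygenic records behave
similarly but the monogenic-only view is the cleaner contrast.

## Inheritance modes

A gene may carry alleles with different inheritance patterns, so the tally
counts a gene once per mode it exhibits (set semantics over duplicate
association rows); proportions are over genes in the group with *any*
inheritance annotation and need not sum to one. X-linked inheritance is a
single category, not subdivided by dominance. The headline contrast —
dominant-vs-recessive excess in `DL` against the other disease genes — is
a Fisher test on (group vs rest) × (AD vs AR assignments).

## The synthetic-data generator

`simulate_dataset()` emits the complete flat-file input set with known
ground truth, so every stage of the pipeline can be exercised and
calibrated offline. What it emulates:

- **Partial knockout coverage.** Each gene has a knockout report with
  probability 0.40 (the coverage observed among disease genes in curated
  mouse data); reported knockouts are lethal with probability 0.66 (the
  lethal share of published knockouts). Unreported genes have status
  `unknown` and flow into `DU`.
- **Disease enrichment among lethal genes.** Disease status is Bernoulli
  with baseline rate 0.10 and a five-fold odds multiplier for lethal
  genes, mirroring the observed lethal:viable disease odds ratio of
  roughly five.
- **Localization tilts.** Compartments are drawn per essentiality status:
  lethal genes are nucleus-tilted (0.55), viable genes membrane/
  extracellular-tilted, unknown genes intermediate — the qualitative
  pattern reported for essential vs non-essential proteins.
- **A Chung–Lu fitness network.** Edges are independent Bernoulli with
  $p_{ij} = \min(1, w_i w_j / \sum_g w_g)$ and
  $w_g = 2\,e^{0.5\cdot[\text{lethal}] + 0.5\cdot[\text{nuclear}]}$.
  The fitness model was chosen over preferential attachment because its
  expected degrees have a closed form (`expected_mean_degree()`), giving
  the generator an exact oracle: realized mean degree must sit within 10%
  of the direct pairwise summation. The resulting average degrees (about
  2–4) are in the range seen in curated human PPI subnetworks.
- **Group-tilted labels.** Disease classes (seven flattened labels
  including "cancer" and "multiple"-system), inheritance modes (AD/AR/X,
  with a dominant tilt of 0.58/0.33/0.09 in `DL` versus 0.45/0.47/0.08 in
  `DU`), and genicity (15% polygenic) are drawn from group-conditioned
  vectors.
- **Mechanism texts.** True classes are drawn 70/10/20 loss/gain/other
  (the reported mechanism mix); each record is a bag of tokens of Poisson
  length (mean 30) over a synthetic vocabulary — 200 background words plus
  8 keywords per class with 6:1 per-token emission odds. Tokens are
  synthetic (`w0001`, `losskw001`, ...) with the matching lexicon emitted
  alongside, so classifier recovery is testable without English-language
  assumptions.

All randomness flows from one master seed through deterministically derived
per-stage sub-seeds, making output files byte-identical across runs and
stages independently regeneratable.

**What the generator does not emulate** — and hence what passing recovery
tests do *not* show about real data: scale-free degree tails and hub
structure of real interactomes, correlated and hierarchical GO
annotations, OMIM's English prose (real mechanism text is far harder than
the separable synthetic corpus), ascertainment bias in which genes get
knocked out, curation error, and identifier-mapping noise. The generator's
job is to verify that the *machinery* detects effects of known size and
stays calibrated under the null, not to impersonate the 2011 database
snapshots.

The deterministic companion, `reference_fixture()`, contains no randomness
at all: its group sizes (673/120/1172/626/552) and housekeeping overlap
(64 of 609 in a 24,789-gene genome) are fixed so the tabulation stage has
exact known answers (85%, 66%, 34%, 6%, 5.5%, 2.5%).

## Numerical and degenerate-input choices

- Percentages round half-up (base R rounds half-to-even).
- Shares with a zero denominator are `NA`, never `NaN`; an all-zero
  housekeeping table flags the odds ratio as undefined.
- `fisher_2x2` treats any degenerate margin as the single-table case,
  p = 1; `chi_square_2x2` errors on a zero expected count and points to
  Fisher.
- Empty networks summarise to zeros with `components = 0` and `NA`
  percentages.
- Readers reject duplicate gene or record identifiers, malformed rows
  (with file and line), invalid inheritance/genicity labels, and p-values
  outside [0, 1]; an absent annotation namespace is a warning plus an
  empty table, not an error, because mixed-namespace files are normal.

## Problem sizes

The simulation studies in the test suite and acceptance script use a
3,000-gene universe (the default `synthetic_config()`), 50 seeds for
effect-recovery rates, 200 null namespaces for FDR calibration, 200 random
graphs (≤ 200 nodes) for the network oracle, all 46,376 2×2 tables with
total count ≤ 30 for the exact-test oracle, and all sample-size pairs up
to 6 for exact rank-sum enumeration. These sizes give stable rates (binomial
standard errors of a few percent) while keeping a full run in the
minutes range on a single core.

## Worked example

```{r example, eval = FALSE}
library(essgenes)

ds <- simulate_dataset(synthetic_config(), seed = 1)
dir <- tempfile()
write_dataset(ds, dir)
res <- run_pipeline(dir, file.path(dir, "out"), genome_size = 5000)

glance(res$tabulation)     # headline shares
res$table2                 # per-group network summary
res$enrichments$cellular_component |> dplyr::filter(group == "DL")
res$dominant_vs_recessive  # DL AD-vs-AR Fisher test
plot_inheritance(res$inheritance)
```

## Known limitations

- The lexicon and naive-Bayes training sets that produced the original
  mechanism proportions are not published; the shipped defaults reproduce
  the *method*, not the exact historical figures.
- Identifiers are opaque strings; no symbol-to-ID resolution or cross-
  database reconciliation is attempted — inputs must arrive reconciled.
- No GO-graph propagation: annotations are consumed pre-slimmed.
- Essentiality of `DU` genes is never inferred or imputed; the group
  exists precisely to be reported separately.
- Network analysis stops at degree/component statistics; no betweenness,
  no layouts.
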