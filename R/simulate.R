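# Synthetic-data generator. Emits the full flat-file input set with known
# ground truth: a gene universe with partial knockout coverage, disease
# labels enriched among (latently) lethal genes, a Chung-Lu interaction
# network whose expected degree rises with lethality and nuclear
# localization, group-tilted disease-class and inheritance distributions,
# and mechanism texts with class-specific keyword emission.

COMPARTMENTS <- c("nucleus", "cytoplasm", "plasma membrane",
                  "extracellular region", "other compartment")
DISEASE_CLASSES <- c("cancer", "multiple", "neurological", "cardiovascular",
                     "immune", "metabolic", "unclassified system")
INHERITANCE_MODES <- c("AD", "AR", "X")

# All unordered gene pairs (i < j), without materialising an n x n matrix.
upper_pairs <- function(n) {
  if (n < 2) {
    return(list(i = integer(), j = integer()))
  }
  lens <- rev(seq_len(n - 1L))
  list(
    i = rep.int(seq_len(n - 1L), lens),
    j = sequence(lens, from = seq_len(n - 1L) + 1L)
  )
}

check_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0(nm, " must be a probability in [0, 1]"))
  }
}

check_prob_vec <- function(x, nm, len) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(x < 0)) {
    abort(paste0(nm, " must be ", len, " non-negative probabilities"))
  }
  if (abs(sum(x) - 1) > 1e-9) {
    abort(paste0(nm, " must sum to 1"))
  }
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale universe of 2000 genes whose statistical
#' structure mirrors the landscape the analysis targets: 40% knockout
#' coverage, two thirds of knockouts lethal, roughly five-fold disease odds
#' for lethal genes, nucleus-tilted compartments for lethal genes, a
#' lethality/nuclearity-boosted Chung-Lu interaction network, a 70/10/20
#' loss/gain/other mechanism mix, and a dominant-inheritance tilt in the
#' disease-lethal group.
#'
#' @param n_genes Number of genes in the universe.
#' @param knockout_coverage Probability a gene has a knockout report; genes
#'   without one have essentiality status `unknown`.
#' @param p_lethal Probability a reported knockout is lethal.
#' @param disease_rate_base Disease probability for a non-lethal gene.
#' @param lethal_disease_odds_multiplier Multiplier on the disease odds for
#'   lethal genes.
#' @param housekeeping_rate Probability a gene is flagged housekeeping.
#' @param degree_base Baseline Chung-Lu fitness (expected degree scale).
#' @param beta_lethal,beta_nuclear Log-scale fitness boosts for lethal and
#'   nuclear genes.
#' @param compartment_probs Named list (`lethal`, `viable`, `unknown`) of
#'   probability vectors over the five compartments, conditioned on
#'   essentiality status.
#' @param disease_class_probs Named list (`DL`, `DV`, `DU`) of probability
#'   vectors over the seven disease classes.
#' @param inheritance_probs Named list (`DL`, `DV`, `DU`) of probability
#'   vectors over AD/AR/X.
#' @param monogenic_prob Probability a disease association is monogenic.
#' @param mechanism_mix Probability vector (loss, gain, other) of true
#'   mechanism classes.
#' @param keyword_emission_odds Per-token odds of each true-class keyword
#'   relative to each background word.
#' @param n_keywords_per_class,n_background_words Vocabulary sizes.
#' @param doc_length_mean Poisson mean of record token counts.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 3000,
                             knockout_coverage = 0.40,
                             p_lethal = 0.66,
                             disease_rate_base = 0.10,
                             lethal_disease_odds_multiplier = 5,
                             housekeeping_rate = 0.025,
                             degree_base = 2,
                             beta_lethal = 0.5,
                             beta_nuclear = 0.5,
                             compartment_probs = list(
                               lethal = c(0.55, 0.17, 0.12, 0.06, 0.10),
                               viable = c(0.25, 0.20, 0.30, 0.15, 0.10),
                               unknown = c(0.35, 0.20, 0.20, 0.12, 0.13)
                             ),
                             disease_class_probs = list(
                               DL = c(0.15, 0.30, 0.10, 0.12, 0.08, 0.10, 0.15),
                               DV = c(0.04, 0.12, 0.22, 0.05, 0.22, 0.12, 0.23),
                               DU = c(0.06, 0.18, 0.16, 0.10, 0.14, 0.14, 0.22)
                             ),
                             inheritance_probs = list(
                               DL = c(0.58, 0.33, 0.09),
                               DV = c(0.30, 0.62, 0.08),
                               DU = c(0.45, 0.47, 0.08)
                             ),
                             monogenic_prob = 0.85,
                             mechanism_mix = c(loss = 0.70, gain = 0.10, other = 0.20),
                             keyword_emission_odds = 6,
                             n_keywords_per_class = 8,
                             n_background_words = 200,
                             doc_length_mean = 30) {
  stopifnot(n_genes >= 1, degree_base > 0, keyword_emission_odds > 0,
            n_keywords_per_class >= 1, n_background_words >= 1,
            doc_length_mean > 0, lethal_disease_odds_multiplier > 0)
  check_prob(knockout_coverage, "knockout_coverage")
  check_prob(p_lethal, "p_lethal")
  check_prob(disease_rate_base, "disease_rate_base")
  check_prob(housekeeping_rate, "housekeeping_rate")
  check_prob(monogenic_prob, "monogenic_prob")
  stopifnot(all(c("lethal", "viable", "unknown") %in% names(compartment_probs)))
  for (s in c("lethal", "viable", "unknown")) {
    check_prob_vec(compartment_probs[[s]], paste0("compartment_probs$", s), 5)
  }
  stopifnot(all(c("DL", "DV", "DU") %in% names(disease_class_probs)),
            all(c("DL", "DV", "DU") %in% names(inheritance_probs)))
  for (g in c("DL", "DV", "DU")) {
    check_prob_vec(disease_class_probs[[g]], paste0("disease_class_probs$", g), 7)
    check_prob_vec(inheritance_probs[[g]], paste0("inheritance_probs$", g), 3)
  }
  check_prob_vec(unname(mechanism_mix), "mechanism_mix", 3)
  structure(
    list(
      n_genes = as.integer(n_genes),
      knockout_coverage = knockout_coverage,
      p_lethal = p_lethal,
      disease_rate_base = disease_rate_base,
      lethal_disease_odds_multiplier = lethal_disease_odds_multiplier,
      housekeeping_rate = housekeeping_rate,
      degree_base = degree_base,
      beta_lethal = beta_lethal,
      beta_nuclear = beta_nuclear,
      compartment_probs = compartment_probs,
      disease_class_probs = disease_class_probs,
      inheritance_probs = inheritance_probs,
      monogenic_prob = monogenic_prob,
      mechanism_mix = c(loss = unname(mechanism_mix[["loss"]]),
                        gain = unname(mechanism_mix[["gain"]]),
                        other = unname(mechanism_mix[["other"]])),
      keyword_emission_odds = keyword_emission_odds,
      n_keywords_per_class = as.integer(n_keywords_per_class),
      n_background_words = as.integer(n_background_words),
      doc_length_mean = doc_length_mean
    ),
    class = "synthetic_config"
  )
}

sim_vocab <- function(config) {
  kw <- function(prefix) {
    sprintf("%skw%03d", prefix, seq_len(config$n_keywords_per_class))
  }
  list(
    gain = kw("gain"),
    loss = kw("loss"),
    neutral = kw("neut"),
    background = sprintf("w%04d", seq_len(config$n_background_words))
  )
}

#' Generate a complete synthetic input dataset
#'
#' Draws every latent label and observable file from `config` under a single
#' master seed; per-stage sub-seeds are derived deterministically, so the
#' same seed always yields byte-identical files.
#'
#' Generative model: each gene has a knockout report with
#' `knockout_coverage`; reported genes are lethal with `p_lethal` and their
#' status is written out as a phenotype row, while unreported genes have
#' status `unknown`. Disease status is Bernoulli with odds
#' `disease_rate_base`-odds times `lethal_disease_odds_multiplier` for
#' lethal genes. Compartments are drawn conditional on essentiality status.
#' Interaction edges are independent Bernoulli with
#' `p_ij = min(1, w_i w_j / sum(w))`,
#' `w_g = degree_base * exp(beta_lethal * lethal_g + beta_nuclear *
#' nuclear_g)` (a Chung-Lu fitness model, chosen for its closed-form
#' expected degrees); self-pairs are never emitted. Disease classes,
#' inheritance modes and genicity are drawn from group-conditioned vectors,
#' and each disease gene gets one free-text record whose tokens give the
#' true mechanism class's keywords `keyword_emission_odds : 1` odds over
#' each background word.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer master seed.
#' @return A list of tibbles (`orthology`, `phenotypes`, `disease`,
#'   `housekeeping`, `ppi`, `annotations`, `records`, `lexicon`,
#'   `ground_truth`) plus `config`; write it out with [write_dataset()].
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  mouse_id <- sprintf("Mm_%05d", seq_len(n))

  set.seed(derive_seed(seed, 1))
  reported <- runif(n) < config$knockout_coverage
  lethal <- reported & runif(n) < config$p_lethal
  status <- dplyr::case_when(
    !reported ~ "unknown",
    lethal ~ "lethal",
    TRUE ~ "viable"
  )

  set.seed(derive_seed(seed, 2))
  base_odds <- config$disease_rate_base / (1 - config$disease_rate_base)
  odds <- base_odds * ifelse(lethal, config$lethal_disease_odds_multiplier, 1)
  p_disease <- odds / (1 + odds)
  disease <- runif(n) < p_disease
  housekeeping <- runif(n) < config$housekeeping_rate

  set.seed(derive_seed(seed, 3))
  compartment <- character(n)
  for (s in c("lethal", "viable", "unknown")) {
    idx <- status == s
    compartment[idx] <- sample(COMPARTMENTS, sum(idx), replace = TRUE,
                               prob = config$compartment_probs[[s]])
  }
  nuclear <- compartment == "nucleus"

  group <- dplyr::case_when(
    disease & lethal ~ "DL",
    disease & status == "viable" ~ "DV",
    disease ~ "DU",
    lethal ~ "L",
    status == "viable" ~ "V",
    TRUE ~ "NONDISEASE_UNKNOWN"
  )

  set.seed(derive_seed(seed, 4))
  w <- config$degree_base *
    exp(config$beta_lethal * lethal + config$beta_nuclear * nuclear)
  sw <- sum(w)
  ij <- upper_pairs(n)
  p_edge <- pmin(1, w[ij$i] * w[ij$j] / sw)
  hit <- runif(length(p_edge)) < p_edge
  ppi <- tibble(protein_a = gene_id[ij$i[hit]], protein_b = gene_id[ij$j[hit]],
                source = "synthetic")

  set.seed(derive_seed(seed, 5))
  dis_idx <- which(disease)
  dis_group <- group[dis_idx]
  draw_from <- function(choices, probs_by_group) {
    vapply(dis_group, function(g) {
      sample(choices, 1, prob = probs_by_group[[g]])
    }, character(1), USE.NAMES = FALSE)
  }
  dclass <- draw_from(DISEASE_CLASSES, config$disease_class_probs)
  dmode <- draw_from(INHERITANCE_MODES, config$inheritance_probs)
  genicity <- ifelse(runif(length(dis_idx)) < config$monogenic_prob,
                     "monogenic", "polygenic")
  disease_tbl <- tibble(
    gene_id = gene_id[dis_idx],
    disease_id = sprintf("dis%05d", seq_along(dis_idx)),
    disease_class = dclass,
    inheritance_mode = dmode,
    genicity = genicity
  )

  set.seed(derive_seed(seed, 6))
  vocab <- sim_vocab(config)
  truth_class <- sample(c("loss", "gain", "other"), length(dis_idx),
                        replace = TRUE, prob = unname(config$mechanism_mix))
  emit_doc <- function(cls) {
    len <- rpois(1, config$doc_length_mean)
    if (len == 0) {
      return("")
    }
    kws <- vocab[[if (cls == "other") "neutral" else cls]]
    words <- c(kws, vocab$background)
    weights <- c(rep(config$keyword_emission_odds, length(kws)),
                 rep(1, length(vocab$background)))
    paste(sample(words, len, replace = TRUE, prob = weights), collapse = " ")
  }
  records <- tibble(
    record_id = sprintf("rec%05d", seq_along(dis_idx)),
    gene_id = gene_id[dis_idx],
    label = dplyr::recode(truth_class, other = "neutral"),
    text = map_chr(truth_class, emit_doc)
  )
  lexicon_tbl <- tibble(
    category = rep(c("gain", "loss", "neutral"),
                   each = config$n_keywords_per_class),
    stem = c(vocab$gain, vocab$loss, vocab$neutral)
  )

  phen_rows <- tibble(
    mouse_gene_id = mouse_id[reported],
    phenotype_term = ifelse(lethal[reported], "embryonic lethality", "abnormal gait")
  )
  annotations <- bind_rows(
    tibble(gene_id = gene_id, namespace = "cellular_component", term = compartment),
    tibble(gene_id = gene_id[dis_idx], namespace = "disease_class", term = dclass)
  )
  ground_truth <- tibble(
    gene_id = gene_id,
    status = status,
    knockout_reported = reported,
    is_disease = disease,
    is_housekeeping = housekeeping,
    compartment = compartment,
    group = group,
    fitness = w
  )

  list(
    orthology = tibble(human_gene_id = gene_id, mouse_gene_id = mouse_id),
    phenotypes = phen_rows,
    disease = disease_tbl,
    housekeeping = gene_id[housekeeping],
    ppi = ppi,
    annotations = annotations,
    records = records,
    lexicon = lexicon_tbl,
    ground_truth = ground_truth,
    config = config
  )
}

#' Expected mean degree of the generator's Chung-Lu model
#'
#' Brute-force expectation `sum over unordered pairs of min(1, w_i w_j /
#' sum(w)) * 2 / n`, for checking realized degrees against the model.
#'
#' @param config A [synthetic_config()].
#' @param ground_truth The generator's ground-truth tibble (for the realized
#'   fitness values).
#' @return Expected mean degree over all genes.
#' @export
expected_mean_degree <- function(config, ground_truth) {
  w <- ground_truth$fitness
  n <- length(w)
  ij <- upper_pairs(n)
  sum(pmin(1, w[ij$i] * w[ij$j] / sum(w))) * 2 / n
}
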