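toy_lexicon <- function() {
  essgenes:::as_lexicon(list(
    gain = c("activat", "neomorph"),
    loss = c("deficien", "truncat"),
    neutral = c("translocat", "fusion")
  ))
}

test_that("tokenization splits on non-alphanumeric runs and lowercases", {
  expect_identical(tokenize("Loss-of-function; deficiency."),
                   c("loss", "of", "function", "deficiency"))
  expect_identical(tokenize(""), character())
  expect_identical(tokenize("p53 (TP53): G>A, 3'UTR!!"),
                   c("p53", "tp53", "g", "a", "3", "utr"))
})

test_that("word scoring picks the highest-scoring category with tie safety", {
  lex <- toy_lexicon()
  expect_identical(
    word_score_classify("deficiency and deficiency with activation", lex),
    "loss")
  expect_identical(word_score_classify("", lex), "unclassified")
  expect_identical(word_score_classify("nothing matches here", lex), "unclassified")
  # tie: one gain token, one loss token
  expect_identical(word_score_classify("activation deficiency", lex), "unclassified")
  # stems match by token prefix
  expect_identical(word_score_classify("an activating mutation", lex), "gain")
  expect_identical(word_score_classify("chromosomal translocation seen", lex), "other")
})

test_that("naive-Bayes training applies the exclusion rules", {
  records <- tibble::tibble(
    text = c("deficiency mutation alpha", "truncating mutation alpha beta",
             "activation mutation beta", "neomorphic mutation gamma",
             "translocation mutation gamma", "fusion mutation delta"),
    label = c("loss", "loss", "gain", "gain", "neutral", "neutral")
  )
  model <- train_nb(records, frequent_df_cutoff = 0.9)
  # "mutation" occurs in documents of every class: excluded as shared
  expect_false("mutation" %in% model$vocabulary)
  expect_true("mutation" %in% model$excluded)
  expect_true(all(c("deficiency", "activation", "fusion") %in% model$vocabulary))
  # document frequency cutoff: with cutoff 1/3, "alpha"/"beta"/"gamma" (df 2/6) go too
  model2 <- train_nb(records, frequent_df_cutoff = 2 / 6)
  expect_false(any(c("alpha", "beta", "gamma") %in% model2$vocabulary))
  expect_equal(sum(model$priors), 1, tolerance = 1e-9)
  expect_error(train_nb(records[records$label != "gain", ]), "gain")
  expect_error(train_nb(records, alpha = 0), "alpha")
})

test_that("posteriors equal a hand-applied Bayes rule on a toy corpus", {
  records <- tibble::tibble(
    text = c("aa aa bb", "aa cc", "dd dd", "dd ee"),
    label = c("loss", "loss", "gain", "gain")
  )
  # neutral class needed: add one disjoint doc
  records <- dplyr::bind_rows(records,
                              tibble::tibble(text = "ff ff", label = "neutral"))
  model <- train_nb(records, alpha = 1, frequent_df_cutoff = 0.99,
                    exclude_shared = FALSE)
  # vocabulary: aa bb cc dd ee ff (6 words)
  # loss counts: aa=3 bb=1 cc=1 (total 5); gain: dd=3 ee=1 (4); neutral: ff=2 (2)
  v <- 6
  lik <- function(count, total) (count + 1) / (total + v)
  post_unnorm <- c(
    gain = (2 / 5) * lik(0, 4) * lik(0, 4),
    loss = (2 / 5) * lik(3, 5) * lik(1, 5),
    neutral = (1 / 5) * lik(0, 2) * lik(0, 2)
  )
  want <- post_unnorm / sum(post_unnorm)
  got <- nb_classify(model, "aa bb")
  expect_equal(got$posterior_loss, want[["loss"]], tolerance = 1e-12)
  expect_equal(got$posterior_gain, want[["gain"]], tolerance = 1e-12)
  expect_equal(got$posterior_neutral, want[["neutral"]], tolerance = 1e-12)
  expect_identical(got$call, "loss")
})

test_that("out-of-vocabulary documents fall back to the priors", {
  records <- tibble::tibble(
    text = c("aa bb", "cc dd", "ee ff"),
    label = c("loss", "gain", "neutral")
  )
  model <- train_nb(records, frequent_df_cutoff = 0.99, exclude_shared = FALSE)
  got <- nb_classify(model, "zz yy xx")
  expect_equal(c(got$posterior_gain, got$posterior_loss, got$posterior_neutral),
               rep(1 / 3, 3), tolerance = 1e-12)
  expect_identical(got$call, "unclassified")  # flat posterior is a tie
  expect_equal(got$posterior_gain + got$posterior_loss + got$posterior_neutral, 1,
               tolerance = 1e-9)
})

test_that("training is invariant under corpus duplication", {
  records <- tibble::tibble(
    text = c("aa bb loss", "cc dd gainword", "ee ff neutralword"),
    label = c("loss", "gain", "neutral")
  )
  m1 <- train_nb(records, frequent_df_cutoff = 0.99, exclude_shared = FALSE)
  m2 <- train_nb(dplyr::bind_rows(records, records),
                 frequent_df_cutoff = 0.99, exclude_shared = FALSE)
  expect_equal(m1$priors, m2$priors)
  expect_identical(m1$vocabulary, m2$vocabulary)
  # likelihoods are exactly invariant when the smoothing mass scales with
  # the corpus; at fixed alpha the smoothed estimates differ slightly
  m2s <- train_nb(dplyr::bind_rows(records, records), alpha = 2,
                  frequent_df_cutoff = 0.99, exclude_shared = FALSE)
  expect_equal(m1$log_likelihood, m2s$log_likelihood)
})

test_that("word-score classification ignores token order", {
  lex <- toy_lexicon()
  expect_identical(word_score_classify("x deficiency y activation deficiency", lex),
                   word_score_classify("deficiency deficiency activation x y", lex))
})

test_that("corpus classification tabulates proportions and filters polygenic genes", {
  classified <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    group = rep(c("DL", "DV"), 5)
  )
  records <- tibble::tibble(
    record_id = sprintf("r%02d", 1:10),
    gene_id = sprintf("g%02d", 1:10),
    label = NA_character_,
    text = "deficiency observed"
  )
  res <- classify_corpus(records, classified, lexicon = toy_lexicon())
  expect_true(all(res$proportions$call == "loss"))
  expect_true(all(res$proportions$proportion == 1))

  disease <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    genicity = c(rep("polygenic", 3), rep("monogenic", 7))
  )
  res2 <- classify_corpus(records, classified, lexicon = toy_lexicon(),
                          disease = disease, genicity_filter = "monogenic_only")
  expect_identical(nrow(res2$calls), 7L)
  expect_error(classify_corpus(records, classified, lexicon = toy_lexicon(),
                               genicity_filter = "monogenic_only"),
               "disease association")
})

test_that("both classifiers recover the generating mechanism mix", {
  ds <- simulate_dataset(synthetic_config(n_genes = 3000), seed = 99)
  lex <- essgenes:::as_lexicon(split(ds$lexicon$stem, ds$lexicon$category))
  records <- ds$records
  truth <- ifelse(records$label == "neutral", "other", records$label)
  # hold out half for evaluation, train on the rest
  train_idx <- seq_len(nrow(records)) %% 2 == 0
  model <- train_nb(records[train_idx, ])
  res <- classify_corpus(records[!train_idx, ], classify_dataset(ds),
                         lexicon = lex, model = model)
  truth_eval <- truth[!train_idx]
  expect_gte(mean(res$calls$wordscore_call == truth_eval), 0.95)
  expect_gte(mean(res$calls$nb_call == truth_eval), 0.95)
  # recovered loss fraction within 5 points of the 70% emission rate
  loss_frac <- mean(res$calls$final_call == "loss")
  expect_lt(abs(loss_frac - 0.70), 0.05)
  expect_gte(res$agreement, 0.95)
})
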