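# Disease-mechanism classification of free-text records as gain / loss /
# other, by two independent routes: (1) lexicon word scoring with prefix-stem
# matching, (2) a multinomial naive-Bayes classifier trained on labelled
# records with frequent- and shared-word exclusion. Internally the classes
# are {gain, loss, neutral}; "neutral" is reported as "other" (chromosomal
# translocations, chimeric proteins).

MECH_CLASSES <- c("gain", "loss", "neutral")

#' Tokenize free text
#'
#' Splits on runs of non-alphanumeric characters, lowercases, and drops
#' empty tokens.
#'
#' @param text A character string.
#' @return A character vector of lowercase tokens.
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(character())
  }
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Read a mechanism lexicon
#'
#' @param path TSV with columns `category` (`gain`, `loss`, `neutral`) and
#'   `stem` (lowercase word stem).
#' @return A lexicon: named list of character stem vectors per category.
#' @export
read_lexicon <- function(path) {
  raw <- read_tsv_strict(path, c("category", "stem"))
  bad <- which(!raw$category %in% MECH_CLASSES)
  if (length(bad) > 0) {
    abort(paste0(path, ": invalid lexicon category '", raw$category[bad[[1]]], "'"))
  }
  as_lexicon(split(tolower(raw$stem), factor(raw$category, levels = MECH_CLASSES)))
}

as_lexicon <- function(x) {
  stopifnot(is.list(x), all(MECH_CLASSES %in% names(x)))
  lex <- lapply(x[MECH_CLASSES], function(v) unique(tolower(v)))
  if (any(vapply(lex, function(v) any(!nzchar(v)), logical(1)))) {
    abort("lexicon stems must be non-empty")
  }
  # shared-stem removal keeps categories disjoint
  shared <- Reduce(intersect, lex)
  lapply(lex, setdiff, y = shared)
}

#' Default mechanism lexicon
#'
#' A small seed lexicon built around canonical mechanism vocabulary:
#' loss-of-function stems such as "deficien", gain-of-function stems such as
#' "activat" and "neomorph", and translocation/fusion stems for the neutral
#' ("other") category. Stems match tokens by prefix, so "activat" hits
#' "activation" and "activating". Intended as a starting point; supply your
#' own lexicon for serious use.
#'
#' @return A lexicon list with elements `gain`, `loss`, `neutral`.
#' @export
default_lexicon <- function() {
  as_lexicon(list(
    gain = c("activat", "neomorph", "gain", "hypermorph", "overexpress",
             "constitutive", "dominant negative"),
    loss = c("deficien", "loss", "null", "hypomorph", "truncat", "nonsense",
             "frameshift", "absent", "inactivat"),
    neutral = c("translocat", "fusion", "chimeric", "rearrangement", "breakpoint")
  ))
}

#' Classify one text by lexicon word score
#'
#' Scores each category by the number of tokens matching any of its stems by
#' prefix; the highest-scoring category wins. `gain`/`loss` map to
#' themselves, `neutral` maps to `"other"`. All-zero scores and ties yield
#' `"unclassified"`.
#'
#' @param text A character string.
#' @param lexicon A lexicon from [default_lexicon()] or [read_lexicon()].
#' @return One of `"gain"`, `"loss"`, `"other"`, `"unclassified"`.
#' @export
word_score_classify <- function(text, lexicon = default_lexicon()) {
  toks <- tokenize(text)
  if (length(toks) == 0) {
    return("unclassified")
  }
  scores <- vapply(lexicon[MECH_CLASSES], function(stems) {
    if (length(stems) == 0) {
      return(0L)
    }
    sum(vapply(toks, function(tk) any(startsWith(tk, stems)), logical(1)))
  }, integer(1))
  top <- max(scores)
  if (top == 0 || sum(scores == top) > 1) {
    return("unclassified")
  }
  cls <- MECH_CLASSES[[which.max(scores)]]
  if (cls == "neutral") "other" else cls
}

#' Train a multinomial naive-Bayes mechanism classifier
#'
#' Standard bag-of-words multinomial naive Bayes with add-alpha smoothing,
#' plus two vocabulary filters: words whose document frequency reaches
#' `frequent_df_cutoff` (fraction of training documents) are excluded, and —
#' when `exclude_shared` — words occurring in training documents of every
#' class are excluded as non-discriminating. Class priors come from class
#' frequencies in the training set.
#'
#' @param records Tibble with columns `text` and `label` (every label one of
#'   `gain`, `loss`, `neutral`; each class needs at least one record).
#' @param alpha Additive smoothing parameter (> 0), default 1.
#' @param frequent_df_cutoff Document-frequency fraction at or above which a
#'   word is dropped, default 0.5.
#' @param exclude_shared Drop words seen in documents of all classes,
#'   default `TRUE`.
#' @return An object of class `mechanism_nb` with elements `priors`,
#'   `log_likelihood` (word x class matrix), `vocabulary`, `excluded`,
#'   `alpha`.
#' @export
train_nb <- function(records, alpha = 1, frequent_df_cutoff = 0.5,
                     exclude_shared = TRUE) {
  stopifnot(is.data.frame(records), all(c("text", "label") %in% names(records)))
  if (alpha <= 0) {
    abort("alpha must be > 0")
  }
  labs <- records$label
  if (anyNA(labs) || !all(labs %in% MECH_CLASSES)) {
    abort("every training record needs a label in {gain, loss, neutral}")
  }
  missing_cls <- setdiff(MECH_CLASSES, unique(labs))
  if (length(missing_cls) > 0) {
    abort(paste0("no training records for class: ", paste(missing_cls, collapse = ", ")))
  }
  docs <- map(records$text, tokenize)
  n_docs <- length(docs)
  doc_words <- map(docs, unique)
  df <- table(unlist(doc_words))
  frequent <- names(df)[as.numeric(df) / n_docs >= frequent_df_cutoff]
  shared <- character()
  if (exclude_shared) {
    per_class_vocab <- lapply(split(doc_words, labs), function(dw) unique(unlist(dw)))
    shared <- Reduce(intersect, per_class_vocab)
  }
  excluded <- union(frequent, shared)
  vocab <- sort(setdiff(names(df), excluded))
  if (length(vocab) == 0) {
    abort("vocabulary is empty after frequent/shared-word exclusion")
  }
  counts <- matrix(0, nrow = length(vocab), ncol = length(MECH_CLASSES),
                   dimnames = list(vocab, MECH_CLASSES))
  for (i in seq_len(n_docs)) {
    toks <- docs[[i]]
    toks <- toks[toks %in% vocab]
    if (length(toks) == 0) next
    tab <- table(toks)
    counts[names(tab), labs[[i]]] <- counts[names(tab), labs[[i]]] + as.numeric(tab)
  }
  smoothed <- sweep(counts + alpha, 2, colSums(counts) + alpha * length(vocab), "/")
  model <- list(
    priors = as.numeric(table(factor(labs, levels = MECH_CLASSES))) / n_docs,
    log_likelihood = log(smoothed),
    vocabulary = vocab,
    excluded = sort(excluded),
    alpha = alpha
  )
  names(model$priors) <- MECH_CLASSES
  structure(model, class = "mechanism_nb")
}

#' Classify one text with a trained naive-Bayes model
#'
#' Out-of-vocabulary and excluded tokens are ignored, so a document with no
#' vocabulary words gets the prior as its posterior. The call maps `neutral`
#' to `"other"`; an exact posterior tie yields `"unclassified"`.
#'
#' @param model A `mechanism_nb` model from [train_nb()].
#' @param text A character string.
#' @return A one-row tibble: `call`, `posterior_gain`, `posterior_loss`,
#'   `posterior_neutral`.
#' @export
nb_classify <- function(model, text) {
  stopifnot(inherits(model, "mechanism_nb"))
  toks <- tokenize(text)
  toks <- toks[toks %in% model$vocabulary]
  logpost <- log(model$priors)
  if (length(toks) > 0) {
    tab <- table(toks)
    logpost <- logpost + colSums(model$log_likelihood[names(tab), , drop = FALSE] *
                                   as.numeric(tab))
  }
  logpost <- logpost - max(logpost)
  post <- exp(logpost) / sum(exp(logpost))
  top <- max(post)
  tied <- sum(abs(post - top) < 1e-12) > 1
  cls <- if (tied) "unclassified" else MECH_CLASSES[[which.max(post)]]
  if (cls == "neutral") cls <- "other"
  tibble(call = cls, posterior_gain = post[["gain"]],
         posterior_loss = post[["loss"]], posterior_neutral = post[["neutral"]])
}

#' @export
tidy.mechanism_nb <- function(x, ...) {
  ll <- x$log_likelihood
  tibble(
    word = rep(rownames(ll), times = ncol(ll)),
    class = rep(colnames(ll), each = nrow(ll)),
    log_likelihood = as.numeric(ll)
  )
}

#' @export
glance.mechanism_nb <- function(x, ...) {
  tibble(
    n_vocabulary = length(x$vocabulary),
    n_excluded = length(x$excluded),
    alpha = x$alpha,
    prior_gain = x$priors[["gain"]],
    prior_loss = x$priors[["loss"]],
    prior_neutral = x$priors[["neutral"]]
  )
}

#' @export
print.mechanism_nb <- function(x, ...) {
  cat("Multinomial naive-Bayes mechanism classifier\n")
  cat("  vocabulary:", length(x$vocabulary), "words;",
      length(x$excluded), "excluded\n")
  cat("  priors:", paste(sprintf("%s=%.3f", names(x$priors), x$priors),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Classify a record corpus and summarise per-group mechanism proportions
#'
#' Runs both classifiers over every record, joins the calls to essentiality
#' groups, and tabulates the gain/loss/other proportions per group and
#' method. Unclassified records are excluded from proportion denominators.
#' The final call is the word-score call, falling back to the naive-Bayes
#' call when the word score is unclassified.
#'
#' @param records Tibble from [read_text_records()].
#' @param classified Tibble from [classify_essentiality()].
#' @param lexicon Lexicon for [word_score_classify()].
#' @param model `mechanism_nb` model from [train_nb()], or `NULL` to skip
#'   the naive-Bayes route.
#' @param disease Optional disease-association tibble; when supplied with
#'   `genicity_filter = "monogenic_only"`, records for genes with any
#'   polygenic association are dropped before tabulation.
#' @param genicity_filter `"all"` or `"monogenic_only"`.
#' @return A list with `calls` (per-record tibble: `record_id`, `gene_id`,
#'   `group`, `wordscore_call`, `nb_call`, posteriors, `final_call`),
#'   `proportions` (per group x method x class), and `agreement` (the simple
#'   agreement rate between the two methods over records both classified).
#' @export
classify_corpus <- function(records, classified, lexicon = default_lexicon(),
                            model = NULL, disease = NULL,
                            genicity_filter = c("all", "monogenic_only")) {
  genicity_filter <- arg_match(genicity_filter)
  stopifnot(all(c("record_id", "gene_id", "text") %in% names(records)))
  if (genicity_filter == "monogenic_only") {
    if (is.null(disease)) {
      abort("monogenic_only filtering needs the disease association table")
    }
    polygenic <- unique(disease$gene_id[disease$genicity == "polygenic"])
    records <- filter(records, !.data$gene_id %in% polygenic)
  }
  grp <- select(classified, "gene_id", "group")
  calls <- records |>
    mutate(wordscore_call = map_chr(.data$text, word_score_classify, lexicon = lexicon))
  if (!is.null(model)) {
    nb <- list_rbind(map(records$text, nb_classify, model = model))
    calls <- calls |>
      mutate(
        nb_call = nb$call,
        nb_posterior_gain = nb$posterior_gain,
        nb_posterior_loss = nb$posterior_loss,
        nb_posterior_neutral = nb$posterior_neutral
      )
  } else {
    calls <- calls |>
      mutate(nb_call = NA_character_, nb_posterior_gain = NA_real_,
             nb_posterior_loss = NA_real_, nb_posterior_neutral = NA_real_)
  }
  calls <- calls |>
    mutate(final_call = dplyr::if_else(
      .data$wordscore_call == "unclassified" & !is.na(.data$nb_call),
      .data$nb_call, .data$wordscore_call
    )) |>
    left_join(grp, by = "gene_id") |>
    select("record_id", "gene_id", "group", "wordscore_call", "nb_call",
           "nb_posterior_gain", "nb_posterior_loss", "nb_posterior_neutral",
           "final_call")

  prop_for <- function(col, method) {
    calls |>
      filter(!is.na(.data[[col]]), .data[[col]] != "unclassified",
             !is.na(.data$group)) |>
      count(.data$group, call = .data[[col]]) |>
      group_by(.data$group) |>
      mutate(proportion = .data$n / sum(.data$n), method = method) |>
      ungroup()
  }
  proportions <- bind_rows(
    prop_for("wordscore_call", "word_score"),
    if (!is.null(model)) prop_for("nb_call", "naive_bayes")
  ) |>
    select("method", "group", "call", "n", "proportion")

  both <- filter(calls, !is.na(.data$nb_call),
                 .data$wordscore_call != "unclassified",
                 .data$nb_call != "unclassified")
  agreement <- if (nrow(both) == 0) NA_real_ else {
    mean(both$wordscore_call == both$nb_call)
  }
  list(calls = calls, proportions = proportions, agreement = agreement)
}
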