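# Hybrid sentiment: a dictionary polarity score blended with the class
# probabilities of a pluggable three-class classifier.

#' Read a polarity lexicon
#'
#' TSV with columns `word` and `polarity` (positive/negative/neutral).
#' Words are passed through the same normalizer as the corpus so lookups
#' align. Duplicate rows with a consistent polarity are deduplicated
#' silently; conflicting duplicates are an error.
#'
#' @param path TSV file.
#' @param normalizer Token normalizer, see [identity_normalizer()].
#' @return A `polarity_lexicon`: named character vector word -> polarity.
#' @export
read_polarity_lexicon <- function(path, normalizer = identity_normalizer) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("word", "polarity") %in% names(df))) {
    stop("polarity lexicon needs 'word' and 'polarity' columns")
  }
  polarity_lexicon(df$word, df$polarity, normalizer = normalizer)
}

#' Construct a polarity lexicon
#'
#' @param words Character vector.
#' @param polarities Matching vector with values in
#'   positive/negative/neutral.
#' @inheritParams read_polarity_lexicon
#' @return A `polarity_lexicon` (named character vector).
#' @export
polarity_lexicon <- function(words, polarities,
                             normalizer = identity_normalizer) {
  stopifnot(length(words) == length(polarities))
  bad <- setdiff(unique(polarities), .sentiment_classes)
  if (length(bad)) stop("unknown polarity label(s): ", paste(bad, collapse = ", "))
  words <- normalizer(tolower(as.character(words)))
  keep <- !duplicated(paste(words, polarities))
  words <- words[keep]
  polarities <- polarities[keep]
  if (anyDuplicated(words)) {
    dup <- unique(words[duplicated(words)])
    stop("conflicting polarity for word(s): ", paste(dup, collapse = ", "))
  }
  structure(stats::setNames(as.character(polarities), words),
            class = "polarity_lexicon")
}

#' Dictionary polarity score of a note
#'
#' score = (positive token count - negative token count) / (count of
#' tokens found in the lexicon), with token multiplicities; 0 when the
#' note contains no lexicon word. Neutral-labelled tokens enter the
#' denominator only, pulling the score toward 0.
#'
#' @param pnote A `processed_note`.
#' @param lex A `polarity_lexicon`.
#' @return Score in \[-1, 1\].
#' @export
dictionary_polarity_score <- function(pnote, lex) {
  stopifnot(inherits(pnote, "processed_note"), inherits(lex, "polarity_lexicon"))
  pol <- unclass(lex)[names(pnote$counts)]
  hit <- !is.na(pol)
  if (!any(hit)) {
    return(0)
  }
  cnt <- pnote$counts[hit]
  pol <- pol[hit]
  (sum(cnt[pol == "positive"]) - sum(cnt[pol == "negative"])) / sum(cnt)
}

#' Uniform stub classifier
#'
#' Minimal object satisfying the classifier contract: it returns the
#' uniform distribution over the three classes for any note. Useful as a
#' placeholder and for testing the hybrid path.
#'
#' @return A `sentiment_classifier`.
#' @export
uniform_sentiment_classifier <- function() {
  structure(list(), class = c("uniform_sentiment_classifier",
                              "sentiment_classifier"))
}

#' Class probabilities from a sentiment classifier
#'
#' Generic for the pluggable classifier contract: any model class may
#' provide a method returning named probabilities over
#' negative/neutral/positive.
#'
#' @param model A classifier object.
#' @param pnote A `processed_note`.
#' @return Named numeric vector of three probabilities.
#' @export
sentiment_probs <- function(model, pnote) UseMethod("sentiment_probs")

#' @export
sentiment_probs.uniform_sentiment_classifier <- function(model, pnote) {
  stats::setNames(rep(1 / 3, 3), .sentiment_classes)
}

#' Validated classifier probabilities for a note
#'
#' Calls [sentiment_probs()] and enforces the contract: probabilities over
#' exactly the three classes, nonnegative, summing to 1 within 1e-9.
#'
#' @param pnote A `processed_note`.
#' @param model A classifier honouring the [sentiment_probs()] contract,
#'   or `NULL` (absent model) -- then `NULL` is returned and the hybrid
#'   falls back to the dictionary path.
#' @return Named probability vector in canonical class order, or `NULL`.
#' @export
classifier_probabilities <- function(pnote, model) {
  if (is.null(model)) {
    return(NULL)
  }
  p <- sentiment_probs(model, pnote)
  if (!all(.sentiment_classes %in% names(p))) {
    stop("classifier must return probabilities named ",
         paste(.sentiment_classes, collapse = "/"))
  }
  p <- p[.sentiment_classes]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("classifier contract violation: probabilities must be nonnegative ",
         "and sum to 1 (got sum ", format(sum(p)), ")")
  }
  p
}

# mean embedding of a note's tokens (count-weighted); zero vector when no
# token is embedded
note_embedding_features <- function(pnote, space) {
  hit <- names(pnote$counts)[names(pnote$counts) %in% rownames(space)]
  if (length(hit) == 0L) {
    return(numeric(ncol(space)))
  }
  w <- pnote$counts[hit]
  as.numeric(crossprod(space[hit, , drop = FALSE], w)) / sum(w)
}

#' Train the reference bag-of-embeddings classifier
#'
#' A small stand-in honouring the classifier contract: each note is
#' represented by the count-weighted mean of its token embedding vectors
#' and a multinomial logistic model (one softmax layer) is fitted over the
#' three classes. It trains in seconds on synthetic corpora and plugs into
#' [hybrid_sentiment()] through [classifier_probabilities()].
#'
#' @param pnotes List of `processed_note` objects.
#' @param labels Character vector of true labels (negative/neutral/positive),
#'   one per note; all three classes must be present.
#' @param space An `embedding_space` providing token vectors.
#' @param ... Passed to [nnet::multinom()].
#' @return An `embedding_sentiment_classifier`.
#' @export
train_sentiment_classifier <- function(pnotes, labels, space, ...) {
  stopifnot(length(pnotes) == length(labels))
  labels <- factor(labels, levels = .sentiment_classes)
  if (anyNA(labels)) stop("labels must be negative/neutral/positive")
  if (nlevels(droplevels(labels)) < 3L) {
    stop("training data must contain all three classes")
  }
  x <- t(vapply(pnotes, note_embedding_features, numeric(ncol(space)), space))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(.label = labels, x, check.names = FALSE)
  fit <- nnet::multinom(.label ~ ., data = df, trace = FALSE,
                        MaxNWts = 100000, ...)
  structure(list(fit = fit, space = space, dim = ncol(space)),
            class = c("embedding_sentiment_classifier", "sentiment_classifier"))
}

#' @export
sentiment_probs.embedding_sentiment_classifier <- function(model, pnote) {
  f <- note_embedding_features(pnote, model$space)
  nd <- as.data.frame(t(f))
  names(nd) <- paste0("f", seq_along(f))
  p <- stats::predict(model$fit, newdata = nd, type = "probs")
  stats::setNames(as.numeric(p[.sentiment_classes]), .sentiment_classes)
}

#' Hybrid sentiment decision
#'
#' The dictionary score s is mapped to pseudo-probabilities
#' (negative = max(-s, 0), neutral = 1 - |s|, positive = max(s, 0)) and
#' blended with the classifier's probabilities as
#' alpha * dict + (1 - alpha) * ml. When `ml_probs` is absent the blend
#' degenerates to the pure dictionary path (alpha forced to 1). The label
#' is the argmax; exact ties give `neutral`.
#'
#' @param dict_score Dictionary score in \[-1, 1\].
#' @param ml_probs Optional named probability vector (see
#'   [classifier_probabilities()]).
#' @param alpha Mixing weight in \[0, 1\]; alpha = 1 is the pure dictionary
#'   path, alpha = 0 the pure classifier path.
#' @return List with `label`, blended `probs`, and the effective `alpha`.
#' @export
hybrid_sentiment <- function(dict_score, ml_probs = NULL, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, abs(dict_score) <= 1 + 1e-12)
  dict <- c(negative = max(-dict_score, 0),
            neutral = 1 - abs(dict_score),
            positive = max(dict_score, 0))
  if (is.null(ml_probs)) {
    alpha <- 1
    probs <- dict
  } else {
    ml <- ml_probs[.sentiment_classes]
    if (anyNA(ml)) stop("ml_probs must be named negative/neutral/positive")
    probs <- alpha * dict + (1 - alpha) * ml
  }
  winners <- names(probs)[probs >= max(probs) - 1e-12]
  label <- if (length(winners) > 1L) "neutral" else winners
  list(label = label, probs = probs, alpha = alpha)
}

#' Hybrid sentiment label
#'
#' @inheritParams hybrid_sentiment
#' @return The label only; see [hybrid_sentiment()].
#' @export
hybrid_label <- function(dict_score, ml_probs = NULL, alpha = 0.5) {
  hybrid_sentiment(dict_score, ml_probs, alpha)$label
}

#' Sentiment analysis over a note collection
#'
#' @param pnotes List of `processed_note` objects.
#' @param lex A `polarity_lexicon`.
#' @param model Optional classifier (see [sentiment_probs()]); `NULL` uses
#'   the dictionary path only.
#' @param alpha Mixing weight, see [hybrid_sentiment()].
#' @return Data frame: `note_id`, `dict_score`, `ml_negative`,
#'   `ml_neutral`, `ml_positive` (NA without a model), `label`, `alpha`.
#' @export
analyze_sentiment <- function(pnotes, lex, model = NULL, alpha = 0.5) {
  rows <- lapply(pnotes, function(p) {
    s <- dictionary_polarity_score(p, lex)
    ml <- classifier_probabilities(p, model)
    h <- hybrid_sentiment(s, ml, alpha)
    data.frame(note_id = p$id, dict_score = s,
               ml_negative = if (is.null(ml)) NA_real_ else ml[["negative"]],
               ml_neutral = if (is.null(ml)) NA_real_ else ml[["neutral"]],
               ml_positive = if (is.null(ml)) NA_real_ else ml[["positive"]],
               label = h$label, alpha = h$alpha)
  })
  do.call(rbind, rows)
}

#' Label counts over sentiment results
#'
#' @param results Data frame with a `label` column (or a character vector
#'   of labels).
#' @return Named integer vector over negative/neutral/positive; counts sum
#'   to the number of notes.
#' @export
sentiment_summary <- function(results) {
  labels <- if (is.data.frame(results)) results$label else results
  bad <- setdiff(unique(labels), .sentiment_classes)
  if (length(bad)) stop("unknown sentiment label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(labels, levels = .sentiment_classes))
  stats::setNames(as.integer(tab), .sentiment_classes)
}
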