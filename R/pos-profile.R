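# Morphological profile of the corpus: adjectives split by polarity, verbs
# split by "to be"/other and by tense, the possessive "MY", and
# characteristic-term extraction. Tagging itself is a pluggable contract;
# a deterministic dictionary-lookup tagger is provided for reproducible
# pipelines and tests.

#' Default Polish surface forms of the possessive "MY"
#'
#' @return Character vector of word forms counted as the possessive
#'   adjective "MY".
#' @export
default_my_forms <- function() {
  c("mój", "moja", "moje", "mojego", "mojej", "mojemu", "moim",
    "moją", "moi", "moich", "moimi", "my", "mine")
}

#' Dictionary-lookup tagger
#'
#' Deterministic tagging contract: a table mapping surface word forms to a
#' part of speech (`adjective`, `verb`, or `other`), a lemma, and -- for
#' verbs -- a tense (`past`, `present`, `future`). Word forms absent from
#' the table tag as `other`.
#'
#' @param df Data frame with columns `wordform`, `pos`, `lemma`, `tense`
#'   (empty/NA tense for non-verbs).
#' @return A `dictionary_tagger`.
#' @export
dictionary_tagger <- function(df) {
  need <- c("wordform", "pos", "lemma", "tense")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tagger table missing column(s): ", paste(miss, collapse = ", "))
  df$wordform <- tolower(as.character(df$wordform))
  bad <- setdiff(unique(df$pos), c("adjective", "verb", "other", "possessive_my"))
  if (length(bad)) stop("unknown pos tag(s): ", paste(bad, collapse = ", "))
  df$tense[df$tense %in% c("", NA)] <- NA_character_
  badt <- setdiff(stats::na.omit(unique(df$tense)), c("past", "present", "future"))
  if (length(badt)) stop("unknown tense(s): ", paste(badt, collapse = ", "))
  df <- df[!duplicated(df$wordform), ]
  structure(list(table = df), class = "dictionary_tagger")
}

#' Read a dictionary tagger from TSV
#'
#' Dialect: `wordform<TAB>pos<TAB>lemma<TAB>tense`, UTF-8 with header.
#'
#' @param path TSV file.
#' @return A `dictionary_tagger`.
#' @export
read_tagger <- function(path) {
  dictionary_tagger(utils::read.delim(path, stringsAsFactors = FALSE,
                                      encoding = "UTF-8",
                                      na.strings = c("NA", "")))
}

#' Tag the tokens of one note
#'
#' Tokenizes the raw text (lowercase, non-letter boundaries) and tags each
#' token. The possessive "MY" is detected by surface-form lookup in
#' `my_forms` and overrides the tagger. Adjective polarity is assigned by
#' looking the lemma up in the polarity lexicon; adjectives absent from it
#' stay untyped (NA). Tense is retained for verbs only.
#'
#' @param note A [raw_note()].
#' @param tagger A `dictionary_tagger`.
#' @param polarity Optional `polarity_lexicon` for adjective polarity.
#' @param my_forms Surface forms of the possessive "MY";
#'   see [default_my_forms()].
#' @return Data frame of tagged tokens: `surface`, `lemma`, `pos`,
#'   `tense`, `polarity`.
#' @export
tag_tokens <- function(note, tagger, polarity = NULL,
                       my_forms = default_my_forms()) {
  stopifnot(inherits(note, "raw_note"), inherits(tagger, "dictionary_tagger"))
  toks <- tokenize_text(note$text)
  if (length(toks) == 0L) {
    return(data.frame(surface = character(), lemma = character(),
                      pos = character(), tense = character(),
                      polarity = character()))
  }
  idx <- match(toks, tagger$table$wordform)
  pos <- ifelse(is.na(idx), "other", tagger$table$pos[idx])
  lemma <- ifelse(is.na(idx), toks, tagger$table$lemma[idx])
  tense <- ifelse(pos == "verb" & !is.na(idx), tagger$table$tense[idx],
                  NA_character_)
  pos[toks %in% tolower(my_forms)] <- "possessive_my"
  tense[pos != "verb"] <- NA_character_
  pol <- rep(NA_character_, length(toks))
  if (!is.null(polarity)) {
    p <- unclass(polarity)[lemma]
    pol <- ifelse(pos == "adjective" & p %in% c("positive", "negative"),
                  p, NA_character_)
  }
  data.frame(surface = toks, lemma = lemma, pos = pos, tense = tense,
             polarity = pol, row.names = NULL)
}

#' Tag a note collection
#'
#' Notes on which the tagger fails are skipped with a warning.
#'
#' @inheritParams tag_tokens
#' @param notes List of [raw_note()] objects.
#' @return Named list of tagged-token data frames.
#' @export
tag_corpus <- function(notes, tagger, polarity = NULL,
                       my_forms = default_my_forms()) {
  out <- list()
  for (note in notes) {
    tt <- tryCatch(tag_tokens(note, tagger, polarity, my_forms),
                   error = function(e) {
                     warning("tagger failed on note '", note$id, "': ",
                             conditionMessage(e), "; note skipped")
                     NULL
                   })
    if (!is.null(tt)) out[[note$id]] <- tt
  }
  out
}

#' Part-of-speech statistics
#'
#' Corpus-level counts: total adjectives split into negative, positive and
#' untyped; total verbs split into the lemma "to be" versus other verbs,
#' each with past/present/future tense subcounts; and the possessive "MY"
#' count. The profile is a pure fold over tags: it is additive over notes
#' and invariant to note order.
#'
#' @param tagged One tagged-token data frame or a list of them
#'   ([tag_corpus()] output).
#' @param tobe_lemmas Lemmas identifying the verb "to be"
#'   (default Polish/English).
#' @return A named integer vector of class `pos_profile`.
#' @export
pos_statistics <- function(tagged, tobe_lemmas = c("być", "be")) {
  if (is.data.frame(tagged)) tagged <- list(tagged)
  tt <- if (length(tagged)) do.call(rbind, tagged) else
    data.frame(surface = character(), lemma = character(), pos = character(),
               tense = character(), polarity = character())
  adj <- tt[tt$pos == "adjective", , drop = FALSE]
  verb <- tt[tt$pos == "verb", , drop = FALSE]
  tobe <- verb[verb$lemma %in% tobe_lemmas, , drop = FALSE]
  other <- verb[!verb$lemma %in% tobe_lemmas, , drop = FALSE]
  cnt <- function(x) as.integer(nrow(x))
  tense_cnt <- function(x, tense) as.integer(sum(x$tense %in% tense))
  structure(c(
    adj_total = cnt(adj),
    adj_negative = as.integer(sum(adj$polarity %in% "negative")),
    adj_positive = as.integer(sum(adj$polarity %in% "positive")),
    verb_total = cnt(verb),
    verb_tobe_total = cnt(tobe),
    verb_tobe_past = tense_cnt(tobe, "past"),
    verb_tobe_present = tense_cnt(tobe, "present"),
    verb_tobe_future = tense_cnt(tobe, "future"),
    verb_other_total = cnt(other),
    verb_other_past = tense_cnt(other, "past"),
    verb_other_present = tense_cnt(other, "present"),
    verb_other_future = tense_cnt(other, "future"),
    my_count = as.integer(sum(tt$pos == "possessive_my"))
  ), class = "pos_profile")
}

#' Characteristic terms of the corpus
#'
#' Stop-word-filtered frequency ranking of the retained stems; ties in
#' frequency resolve lexicographically.
#'
#' @param pnotes List of `processed_note` objects.
#' @param stopwords Additional stop words to exclude from the ranking.
#' @param top_k Number of terms to return (>= 1); a `top_k` larger than
#'   the vocabulary returns the whole vocabulary.
#' @return Data frame `term`, `frequency`, ranked.
#' @export
characteristic_terms <- function(pnotes, stopwords = character(), top_k = 10L) {
  stopifnot(top_k >= 1)
  counts <- list()
  for (p in pnotes) {
    for (s in names(p$counts)) {
      counts[[s]] <- (counts[[s]] %||% 0L) + p$counts[[s]]
    }
  }
  if (length(counts) == 0L) {
    return(data.frame(term = character(), frequency = integer()))
  }
  df <- data.frame(term = names(counts),
                   frequency = as.integer(unlist(counts)),
                   row.names = NULL)
  df <- df[!df$term %in% tolower(stopwords), , drop = FALSE]
  df <- df[order(-df$frequency, df$term, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}
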