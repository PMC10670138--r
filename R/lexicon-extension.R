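# Extension of the affective lexicon to out-of-dictionary ("indefinite")
# words. Three stages: (I) emotion centers from the dominant emotions of
# words shared by the lexicon and the note corpus, (II) matching an
# indefinite word to a center by cosine similarity, (III) interpolating its
# intensities from the n nearest lexicon neighbours,
# intensity_e = sum_k s_k * w_k, with similarity-derived weights w_k
# normalized to sum to one.

unembeddable_error <- function(word) {
  stop(errorCondition(paste0("word '", word, "' has no embedding vector"),
                      class = c("notescope_unembeddable", "error", "condition")))
}

#' Emotion centers in embedding space
#'
#' For each emotion, the centroid (arithmetic mean vector) of the lexicon
#' words with that dominant emotion, restricted to words present both in
#' the embedding space and -- when `note_vocab` is given -- in the note
#' corpus. An emotion with no member word in that triple intersection falls
#' back, with a warning, to the lexicon-space intersection; if still empty
#' it is an error, as is a zero centroid (cosine undefined).
#'
#' @param lexicon Standardized `affective_lexicon`.
#' @param space An `embedding_space`.
#' @param note_vocab Optional character vector of corpus stems.
#' @return An `emotion_centers` object: named list with one
#'   `list(emotion, centroid, member_words)` per emotion.
#' @export
compute_emotion_centers <- function(lexicon, space, note_vocab = NULL) {
  stopifnot(inherits(lexicon, "affective_lexicon"),
            lexicon$scale == "standardized")
  in_space <- intersect(lexicon$entries$word, rownames(space))
  if (length(in_space) == 0L) stop("no lexicon word has an embedding vector")
  pool <- if (is.null(note_vocab)) in_space else intersect(in_space, note_vocab)
  dominant <- lexicon$entries$dominant[match(in_space, lexicon$entries$word)]
  names(dominant) <- in_space
  centers <- lapply(.emotions, function(e) {
    members <- intersect(pool, in_space[dominant == e])
    if (length(members) == 0L) {
      members <- in_space[dominant == e]
      if (length(members)) {
        warning("emotion '", e, "': no member word in the note corpus; ",
                "falling back to the full lexicon-embedding intersection")
      }
    }
    if (length(members) == 0L) {
      stop("emotion '", e, "' has no embeddable lexicon word")
    }
    centroid <- colMeans(space[members, , drop = FALSE])
    if (sqrt(sum(centroid^2)) == 0) {
      stop("emotion '", e, "': zero centroid (cosine undefined)")
    }
    list(emotion = e, centroid = centroid, member_words = members)
  })
  names(centers) <- .emotions
  structure(centers, class = "emotion_centers")
}

#' Match a word to its closest emotion center
#'
#' Stage II of the extension: cosine similarity between the word's vector
#' and each emotion centroid; ties resolve in canonical emotion order.
#'
#' @param word A stem present in `space` (otherwise a condition of class
#'   `notescope_unembeddable` is signalled).
#' @param space An `embedding_space`.
#' @param centers [compute_emotion_centers()] output.
#' @return The matched emotion label.
#' @export
match_word_to_center <- function(word, space, centers) {
  stopifnot(inherits(centers, "emotion_centers"))
  if (!word %in% rownames(space)) unembeddable_error(word)
  v <- space[word, ]
  sims <- vapply(.emotions,
                 function(e) cosine_similarity(v, centers[[e]]$centroid),
                 numeric(1))
  if (anyNA(sims)) stop("word '", word, "' has a zero vector (cosine undefined)")
  .emotions[which.max(sims)]
}

#' Interpolate intensities for one out-of-dictionary word
#'
#' Stage III: the neighbour pool is the set of lexicon words, present in
#' the embedding space, whose dominant emotion equals the Stage-II matched
#' emotion (falling back to the whole lexicon-space intersection, with a
#' warning, when that pool is empty). The `n` highest-cosine neighbours get
#' weights proportional to the shifted cosine (cos + 1)/2, normalized to
#' sum to one, and each of the five intensities is the weighted sum
#' `sum(s_k * w_k)` over neighbours -- a convex combination, so extended
#' intensities stay on the standardized scale.
#'
#' A word already in the lexicon is returned unchanged (identity).
#'
#' @param word Stem to extend.
#' @param lexicon Standardized `affective_lexicon`.
#' @param space An `embedding_space`.
#' @param centers [compute_emotion_centers()] output.
#' @param n Neighbour count (default 5).
#' @return An `affective_entry`: list with `word`, `intensities` (named,
#'   one per emotion), `dominant`, `origin`; for extended entries the
#'   attributes `matched_emotion` and `neighbors` (data frame with word,
#'   similarity, weight) record the interpolation.
#' @export
extend_word <- function(word, lexicon, space, centers, n = 5) {
  stopifnot(inherits(lexicon, "affective_lexicon"),
            lexicon$scale == "standardized", n >= 1)
  entries <- lexicon$entries
  hit <- match(word, entries$word)
  if (!is.na(hit)) {
    return(structure(list(
      word = word,
      intensities = stats::setNames(as.numeric(entries[hit, .emotions]), .emotions),
      dominant = entries$dominant[hit],
      origin = entries$origin[hit]
    ), class = "affective_entry"))
  }
  matched <- match_word_to_center(word, space, centers)
  in_space <- intersect(entries$word, rownames(space))
  pool <- in_space[entries$dominant[match(in_space, entries$word)] == matched]
  if (length(pool) == 0L) {
    warning("word '", word, "': no lexicon neighbour with dominant emotion '",
            matched, "'; using the whole embeddable lexicon as pool")
    pool <- in_space
  }
  sims <- cosine_to_rows(space[pool, , drop = FALSE], space[word, ])
  if (anyNA(sims)) stop("zero vector among neighbour candidates for '", word, "'")
  # deterministic: by similarity descending, then word for exact ties
  ord <- order(-sims, pool, method = "radix")
  k <- min(n, length(pool))
  sel <- ord[seq_len(k)]
  w <- (sims[sel] + 1) / 2
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
  s <- lexicon_intensities(lexicon, pool[sel])
  intens <- stats::setNames(as.numeric(crossprod(s, w)), .emotions)
  structure(list(
    word = word,
    intensities = intens,
    dominant = .emotions[which.max(intens[.emotions])],
    origin = "extended"
  ),
  matched_emotion = matched,
  neighbors = data.frame(word = pool[sel], similarity = sims[sel],
                         weight = w, row.names = NULL),
  class = "affective_entry")
}

#' Extend the lexicon over a corpus vocabulary
#'
#' Every vocabulary word that has an embedding vector and is not already in
#' the lexicon gains an `origin = "extended"` entry via [extend_word()].
#' Words without a vector are skipped and reported.
#'
#' @param vocab Character vector (typically [build_vocabulary()] output).
#' @param lexicon Standardized `affective_lexicon`.
#' @param space An `embedding_space`.
#' @param n Neighbour count passed to [extend_word()].
#' @param centers Optional precomputed [compute_emotion_centers()]; by
#'   default computed from `lexicon`, `space` and `vocab`.
#' @return The extended `affective_lexicon`; attribute `"skipped"` lists
#'   unembeddable vocabulary words.
#' @export
extend_lexicon <- function(vocab, lexicon, space, n = 5, centers = NULL) {
  stopifnot(inherits(lexicon, "affective_lexicon"),
            lexicon$scale == "standardized")
  vocab <- unique(vocab)
  new_words <- setdiff(vocab, lexicon$entries$word)
  embeddable <- new_words[new_words %in% rownames(space)]
  skipped <- setdiff(new_words, embeddable)
  if (length(embeddable) == 0L) {
    out <- lexicon
    attr(out, "skipped") <- skipped
    return(out)
  }
  if (is.null(centers)) {
    centers <- compute_emotion_centers(lexicon, space, note_vocab = vocab)
  }
  rows <- lapply(embeddable, function(w) {
    e <- extend_word(w, lexicon, space, centers, n = n)
    data.frame(word = e$word, t(e$intensities), dominant = e$dominant,
               origin = e$origin, check.names = FALSE)
  })
  entries <- rbind(lexicon$entries, do.call(rbind, rows))
  out <- new_affective_lexicon(entries, "standardized", ranges = lexicon$ranges)
  attr(out, "skipped") <- skipped
  out
}
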