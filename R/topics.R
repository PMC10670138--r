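# Difficulty-area detection: bag-of-words frequency matrix, truncated-SVD
# latent semantic analysis, fold-in of per-area positive/negative
# dictionaries, affiliation values W_P / W_N, and the relative-difference
# context classifier (negative / positive / mixed / not covered).

#' Term-by-document frequency matrix
#'
#' Rows are the corpus vocabulary in lexicographic order, columns the note
#' ids in input order; cell (t, d) is the multiplicity of term t in note d,
#' so each column sums to the note's length.
#'
#' @param pnotes List of `processed_note` objects; at least one must be
#'   non-empty.
#' @return Integer matrix with term rownames and note-id colnames.
#' @export
build_frequency_matrix <- function(pnotes) {
  vocab <- build_vocabulary(pnotes)
  if (length(vocab) == 0L) stop("all notes are empty")
  ids <- vapply(pnotes, `[[`, character(1), "id")
  m <- matrix(0L, nrow = length(vocab), ncol = length(pnotes),
              dimnames = list(vocab, ids))
  for (j in seq_along(pnotes)) {
    cts <- pnotes[[j]]$counts
    m[names(cts), j] <- as.integer(cts)
  }
  m
}

#' TF-IDF weighting of a frequency matrix
#'
#' Optional reweighting before LSA: tf * log(N / df), with df the number
#' of documents containing the term.
#'
#' @param m Frequency matrix from [build_frequency_matrix()].
#' @return Numeric matrix of the same shape.
#' @export
tfidf_weight <- function(m) {
  df <- rowSums(m > 0)
  m * log(ncol(m) / df)
}

#' Fit a latent semantic analysis model
#'
#' Truncated singular value decomposition X = U S V' of the term-document
#' matrix; term vectors are U_k S_k, document vectors V_k S_k.
#'
#' @param m Term-document matrix (raw counts or [tfidf_weight()] output).
#' @param k Retained dimensions, 1 <= k <= min(#terms, #documents).
#' @return An `lsa_model`: `k`, `u` (terms x k left singular vectors),
#'   `singular_values` (non-increasing), `term_vectors`, `doc_vectors`,
#'   plus the `terms` and `docs` name vectors.
#' @export
fit_lsa <- function(m, k) {
  if (k < 1 || k > min(dim(m))) {
    stop("k must be between 1 and min(#terms, #documents) = ", min(dim(m)))
  }
  sv <- svd(m, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  tv <- sweep(sv$u, 2L, d, `*`)
  dv <- sweep(sv$v, 2L, d, `*`)
  rownames(tv) <- rownames(sv$u) <- rownames(m)
  rownames(dv) <- colnames(m)
  structure(list(k = k, u = sv$u, singular_values = d,
                 term_vectors = tv, doc_vectors = dv,
                 terms = rownames(m), docs = colnames(m)),
            class = "lsa_model")
}

#' Fold a word set into LSA space
#'
#' A word set (e.g. an area dictionary) is treated as a pseudo-document: a
#' count vector q with one count per occurrence of each word present in
#' the model vocabulary, projected as q' U_k. Words absent from the
#' vocabulary are ignored and reported in the `"skipped"` attribute; if no
#' word is in the vocabulary the zero vector is returned (signalling zero
#' affiliation downstream).
#'
#' @param words Character vector (duplicates count as repeated
#'   occurrences).
#' @param model An `lsa_model`.
#' @return Numeric k-vector with attribute `"skipped"`.
#' @export
fold_in <- function(words, model) {
  stopifnot(inherits(model, "lsa_model"))
  idx <- match(words, model$terms)
  skipped <- unique(words[is.na(idx)])
  q <- tabulate(idx[!is.na(idx)], nbins = length(model$terms))
  v <- as.numeric(crossprod(model$u, q))
  attr(v, "skipped") <- skipped
  v
}

#' Affiliation of a note to one area's positive/negative vocabulary
#'
#' W_P is the cosine similarity, in LSA space, between the note's document
#' vector and the fold-in of the area's positive dictionary, clamped at 0;
#' W_N likewise for the negative dictionary. An undefined cosine (zero
#' vector on either side) yields 0.
#'
#' @param note_id A fitted document id.
#' @param model An `lsa_model`.
#' @param dict List with `positive` and `negative` word vectors.
#' @return Named numeric vector `c(W_P, W_N)`.
#' @export
area_affiliation <- function(note_id, model, dict) {
  if (!note_id %in% model$docs) stop("note '", note_id, "' is not a fitted document")
  d <- model$doc_vectors[note_id, ]
  c(W_P = affiliation_value(d, fold_in(dict$positive, model)),
    W_N = affiliation_value(d, fold_in(dict$negative, model)))
}

# clamped cosine; similarities below the tolerance count as exact zero so
# the "topic not covered" state survives floating-point noise
.affiliation_tol <- 1e-10
affiliation_value <- function(doc_vec, folded) {
  cs <- cosine_similarity(doc_vec, folded)
  if (is.na(cs) || cs < .affiliation_tol) 0 else cs
}

#' Relative difference between context affiliations
#'
#' relative difference (%) = (W_N - W_P) / max(W_N, W_P) * 100. Defined
#' only when max(W_N, W_P) > 0; bounded in \[-100, 100\] for nonnegative
#' inputs and antisymmetric under swapping W_N and W_P.
#'
#' @param W_N,W_P Nonnegative affiliation values, not both zero.
#' @return Percentage in \[-100, 100\].
#' @export
relative_difference <- function(W_N, W_P) {
  if (max(W_N, W_P) <= 0) stop("relative difference undefined when both affiliations are 0")
  (W_N - W_P) / max(W_N, W_P) * 100
}

#' Four-way context classification
#'
#' (0, 0) means the topic is not covered. Otherwise the relative
#' difference decides: above `threshold` the context is negative, below
#' `-threshold` positive, and within the band (ties at exactly the
#' threshold included, since the single-context rule is strict) mixed.
#'
#' @param W_N,W_P Nonnegative affiliation values.
#' @param threshold Percent threshold (default 20).
#' @return One of `"negative"`, `"positive"`, `"mixed"`, `"not_covered"`.
#' @export
classify_context <- function(W_N, W_P, threshold = 20) {
  if (W_N < 0 || W_P < 0) stop("affiliation values must be nonnegative")
  if (W_N == 0 && W_P == 0) {
    return("not_covered")
  }
  rd <- relative_difference(W_N, W_P)
  if (rd > threshold) {
    "negative"
  } else if (rd < -threshold) {
    "positive"
  } else {
    "mixed"
  }
}

#' Default choice of retained LSA dimensions
#'
#' The smallest k whose squared singular values capture at least
#' `var_explained` of the matrix's squared Frobenius norm -- a standard
#' variance-retention rule. The affiliation functional compares cosines
#' between folded-in dictionaries and document vectors, which needs enough
#' dimensions to separate the per-area, per-polarity vocabulary directions
#' from nuisance vocabulary; a too-aggressive truncation merges them and
#' blurs the positive/negative contrast.
#'
#' @param m Term-document matrix.
#' @param var_explained Fraction of squared Frobenius mass to retain
#'   (default 0.9).
#' @return Integer k in `[1, min(dim(m))]`.
#' @export
choose_lsa_k <- function(m, var_explained = 0.9) {
  d2 <- svd(m, nu = 0, nv = 0)$d^2
  unname(which(cumsum(d2) / sum(d2) >= var_explained)[1L])
}

#' Read area dictionaries from JSON
#'
#' Layout: `{area: {"positive": [...], "negative": [...]}}`. Both lists
#' must be non-empty and disjoint within one area.
#'
#' @param path JSON file.
#' @return Named list of per-area dictionaries.
#' @export
read_area_dictionaries <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_area_dictionaries(raw)
}

validate_area_dictionaries <- function(dicts) {
  for (a in names(dicts)) {
    d <- dicts[[a]]
    if (length(d$positive) == 0L || length(d$negative) == 0L) {
      stop("area '", a, "': both positive and negative dictionaries must be non-empty")
    }
    if (length(intersect(d$positive, d$negative))) {
      stop("area '", a, "': positive and negative dictionaries overlap")
    }
  }
  dicts
}

#' Topic analysis over a note collection
#'
#' Builds the frequency matrix, fits LSA, folds each area dictionary in
#' once, and classifies every note x area pair.
#'
#' @param pnotes List of `processed_note` objects.
#' @param area_dicts Named list of per-area dictionaries
#'   (see [read_area_dictionaries()]).
#' @param k Retained LSA dimensions; by default chosen with
#'   [choose_lsa_k()] (90% of squared singular mass).
#' @param threshold Percent threshold for [classify_context()].
#' @param tfidf Apply [tfidf_weight()] before the SVD (default raw counts).
#' @return Data frame: `note_id`, `area`, `W_P`, `W_N`, `rel_diff` (NA
#'   when the topic is not covered), `context`.
#' @export
analyze_topics <- function(pnotes, area_dicts, k = NULL, threshold = 20,
                           tfidf = FALSE) {
  area_dicts <- validate_area_dictionaries(area_dicts)
  m <- build_frequency_matrix(pnotes)
  if (tfidf) m <- tfidf_weight(m)
  if (is.null(k)) k <- choose_lsa_k(m)
  model <- fit_lsa(m, k)
  folded <- lapply(area_dicts, function(d) {
    list(positive = fold_in(d$positive, model),
         negative = fold_in(d$negative, model))
  })
  rows <- list()
  for (id in model$docs) {
    d <- model$doc_vectors[id, ]
    for (a in names(area_dicts)) {
      W_P <- affiliation_value(d, folded[[a]]$positive)
      W_N <- affiliation_value(d, folded[[a]]$negative)
      ctx <- classify_context(W_N, W_P, threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        note_id = id, area = a, W_P = W_P, W_N = W_N,
        rel_diff = if (ctx == "not_covered") NA_real_ else
          relative_difference(W_N, W_P),
        context = ctx)
    }
  }
  do.call(rbind, rows)
}
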