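# The affective lexicon: per-word intensities for the five basic emotions
# (happiness, sadness, anger, fear, disgust), modeled on normed affective
# word lists whose base weights range from 1 to 7.

new_affective_lexicon <- function(entries, scale, ranges = NULL) {
  stopifnot(is.data.frame(entries),
            all(c("word", .emotions, "dominant", "origin") %in% names(entries)),
            scale %in% c("base", "standardized"))
  rownames(entries) <- NULL
  structure(list(entries = entries, scale = scale, ranges = ranges),
            class = "affective_lexicon")
}

#' Build an affective lexicon from a data frame
#'
#' @param df Data frame with a `word` column and one numeric column per
#'   emotion (see [emotions()]); an optional `origin` column marks entries
#'   as `"original"` or `"extended"`.
#' @param scale `"base"` (intensities on the 1--7 scale) or
#'   `"standardized"` (min--max mapped to \[0, 1\]).
#' @param clamp When `TRUE`, out-of-range base values are clamped into
#'   \[1, 7\] with a warning instead of raising an error.
#' @return An `affective_lexicon`: entries plus scale; dominant emotions are
#'   computed as the per-word argmax with ties resolved in canonical
#'   emotion order.
#' @export
affective_lexicon <- function(df, scale = c("base", "standardized"),
                              clamp = FALSE) {
  scale <- match.arg(scale)
  miss <- setdiff(c("word", .emotions), names(df))
  if (length(miss)) stop("lexicon is missing column(s): ", paste(miss, collapse = ", "))
  df$word <- as.character(df$word)
  dup <- df$word[duplicated(df$word)]
  if (length(dup)) stop("duplicate lexicon word(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, .emotions])
  if (anyNA(m) || !is.numeric(m)) stop("non-numeric intensity values")
  lo <- if (scale == "base") 1 else 0
  hi <- if (scale == "base") 7 else 1
  if (any(m < lo | m > hi)) {
    if (clamp) {
      warning("intensities outside [", lo, ", ", hi, "] clamped")
      m[] <- pmin(pmax(m, lo), hi)
      df[, .emotions] <- m
    } else {
      stop("intensity outside [", lo, ", ", hi, "] on the ", scale, " scale")
    }
  }
  df$dominant <- dominant_from_intensities(m)
  if (is.null(df$origin)) df$origin <- "original"
  new_affective_lexicon(df[, c("word", .emotions, "dominant", "origin")], scale)
}

#' Read an affective lexicon from TSV
#'
#' Expected dialect: tab-separated, UTF-8, header
#' `word happiness sadness anger fear disgust` (an `origin` column is
#' accepted and preserved). Values must lie in the base range 1--7 unless
#' `clamp = TRUE`.
#'
#' @param path TSV file.
#' @inheritParams affective_lexicon
#' @return An `affective_lexicon` on the base scale.
#' @export
read_affective_lexicon <- function(path, clamp = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  affective_lexicon(df, scale = "base", clamp = clamp)
}

#' Write an affective lexicon to TSV
#'
#' Same dialect as [read_affective_lexicon()], with the `origin` column
#' appended so extended entries remain identifiable.
#'
#' @param lexicon An `affective_lexicon`.
#' @param path Output file.
#' @export
write_affective_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "affective_lexicon"))
  utils::write.table(lexicon$entries[, c("word", .emotions, "origin")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Min--max standardization of lexicon weights
#'
#' Applies f(x) = (x - min x) / (max x - min x) per emotion, where min and
#' max are observed over the lexicon's entries, so every emotion column
#' spans \[0, 1\] exactly (its minimum maps to 0 and maximum to 1 whenever
#' two distinct values exist). A constant column is degenerate: all its
#' values map to 0, with a warning. Dominant emotions are recomputed on the
#' standardized scale.
#'
#' @param lexicon An `affective_lexicon` on the base scale.
#' @return An `affective_lexicon` with `scale = "standardized"`; the
#'   observed per-emotion min/max used by the map are kept in `$ranges`.
#' @export
standardize_weights <- function(lexicon) {
  stopifnot(inherits(lexicon, "affective_lexicon"))
  if (lexicon$scale == "standardized") {
    return(lexicon)
  }
  entries <- lexicon$entries
  m <- as.matrix(entries[, .emotions])
  mins <- apply(m, 2L, min)
  maxs <- apply(m, 2L, max)
  for (j in seq_along(.emotions)) {
    rng <- maxs[j] - mins[j]
    if (rng == 0) {
      warning("emotion '", .emotions[j],
              "' has constant intensity; standardized values set to 0")
      m[, j] <- 0
    } else {
      m[, j] <- (m[, j] - mins[j]) / rng
    }
  }
  entries[, .emotions] <- m
  entries$dominant <- dominant_from_intensities(m)
  new_affective_lexicon(entries, "standardized",
                        ranges = data.frame(emotion = .emotions,
                                            min = unname(mins),
                                            max = unname(maxs)))
}

# intensity matrix for a subset of words (rows in given order)
lexicon_intensities <- function(lexicon, words) {
  idx <- match(words, lexicon$entries$word)
  if (anyNA(idx)) stop("word(s) not in lexicon: ",
                       paste(words[is.na(idx)], collapse = ", "))
  as.matrix(lexicon$entries[idx, .emotions, drop = FALSE])
}

#' @export
print.affective_lexicon <- function(x, ...) {
  cat("<affective_lexicon> ", nrow(x$entries), " words, scale=", x$scale,
      " (", sum(x$entries$origin == "extended"), " extended)\n", sep = "")
  invisible(x)
}
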