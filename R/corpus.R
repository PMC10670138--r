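# Reading free-text notes and turning them into the token/stem
# representation all downstream scoring consumes.

#' Construct a raw note
#'
#' A raw note is the unit of input: one short free-text paragraph elicited
#' from one patient, optionally carrying a disease-stage label and expert
#' flags (one per difficulty area, values 0/-1/1/2).
#'
#' @param id Unique note identifier.
#' @param text Non-empty free text.
#' @param stage One of [note_stages()]; defaults to `"unknown"`.
#' @param flags Optional named list/vector mapping difficulty areas to
#'   expert flags in `c(0, -1, 1, 2)`.
#' @return An object of class `raw_note`.
#' @export
raw_note <- function(id, text, stage = "unknown", flags = NULL) {
  id <- as.character(id)
  text <- as.character(text)
  if (length(id) != 1L || !nzchar(id)) stop("note id must be a non-empty string")
  if (length(text) != 1L || !nzchar(trimws(text))) {
    stop("note '", id, "': text is empty")
  }
  if (is.na(stage) || !nzchar(stage)) stage <- "unknown"
  stage <- match.arg(stage, .stages)
  if (!is.null(flags)) {
    flags <- as.list(flags)
    bad <- setdiff(names(flags), .areas)
    if (length(bad)) stop("unknown flag area(s): ", paste(bad, collapse = ", "))
    for (a in names(flags)) {
      if (!flags[[a]] %in% c(0, -1, 1, 2)) {
        stop("note '", id, "': flag for ", a, " must be one of 0, -1, 1, 2")
      }
    }
  }
  structure(list(id = id, text = text, stage = stage, flags = flags),
            class = "raw_note")
}

#' Read a collection of notes
#'
#' Supported containers: JSON Lines (one object per line with fields `id`,
#' `text`, optional `stage` and nested `flags`), CSV (columns `id`, `text`,
#' optional `stage` and one column per difficulty area holding expert
#' flags), or a directory of `.txt` files whose base names become ids.
#'
#' @param path File (jsonl/csv) or directory (txt_dir).
#' @param format `"auto"` (guess from the path), `"jsonl"`, `"csv"`, or
#'   `"txt_dir"`.
#' @return A list of [raw_note()] objects. Duplicate ids and empty inputs
#'   are hard errors.
#' @export
read_notes <- function(path, format = c("auto", "jsonl", "csv", "txt_dir")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "txt_dir"
    } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      "csv"
    } else {
      "jsonl"
    }
  }
  if (format != "txt_dir" && !file.exists(path)) stop("no such file: ", path)

  notes <- switch(format,
    jsonl = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      lapply(lines, function(l) {
        rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
        raw_note(rec$id, rec$text,
                 stage = rec$stage %||% "unknown",
                 flags = rec$flags)
      })
    },
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
      if (!all(c("id", "text") %in% names(df))) {
        stop("CSV notes need 'id' and 'text' columns")
      }
      lapply(seq_len(nrow(df)), function(i) {
        flags <- NULL
        present <- intersect(.areas, names(df))
        if (length(present)) {
          vals <- as.list(df[i, present, drop = FALSE])
          vals <- vals[!vapply(vals, function(x) is.na(x), logical(1))]
          if (length(vals)) flags <- vals
        }
        stage <- if ("stage" %in% names(df)) df$stage[i] else "unknown"
        if (is.na(stage) || !nzchar(stage)) stage <- "unknown"
        raw_note(df$id[i], df$text[i], stage = stage, flags = flags)
      })
    },
    txt_dir = {
      if (!dir.exists(path)) stop("no such directory: ", path)
      files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
      lapply(files, function(f) {
        raw_note(sub("\\.txt$", "", basename(f)),
                 paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                       collapse = " "))
      })
    }
  )
  if (length(notes) == 0L) stop("no notes found in ", path)
  ids <- vapply(notes, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate note id(s): ", paste(unique(dup), collapse = ", "))
  notes
}

#' Read a stop-word list
#'
#' One word per line, UTF-8; lowercased on read.
#'
#' @param path File path.
#' @return Character vector of stop words.
#' @export
read_stopwords <- function(path) {
  w <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  tolower(w[nzchar(w)])
}

#' Identity normalizer
#'
#' The token normalizer (stemmer/lemmatizer) is a pluggable contract: any
#' function mapping a character vector of tokens to same-length, non-empty
#' base forms. The core ships only this identity normalizer; a
#' language-specific stemmer can be supplied by the caller, and the same
#' normalizer should be used for the corpus and for every lexicon so that
#' vocabularies align.
#'
#' @param tokens Character vector.
#' @return `tokens`, unchanged.
#' @export
identity_normalizer <- function(tokens) tokens

# Lowercase and split on any non-letter character (Unicode letter class, so
# diacritics survive); tokens containing digits or punctuation cannot occur
# after the split.
tokenize_text <- function(text) {
  toks <- strsplit(tolower(text), "[^\\p{L}]+", perl = TRUE)[[1L]]
  toks[nzchar(toks)]
}

#' Preprocess one note
#'
#' Fixed pipeline: lowercase, tokenize on non-letter boundaries (which
#' removes numbers and punctuation), drop stop-words, then normalize each
#' remaining token to its stem. Counts aggregate identical stems.
#'
#' @param note A [raw_note()].
#' @param stopwords Character vector of stop words (compared before
#'   stemming, case-insensitively).
#' @param normalizer Stemming contract, see [identity_normalizer()].
#' @return An object of class `processed_note` with fields `id`, `tokens`
#'   (ordered retained stems), `counts` (named integer vector), and
#'   `length_N` (number of retained tokens). A note whose every token is
#'   removed yields `length_N = 0`; callers decide whether that is an error.
#' @export
preprocess_note <- function(note, stopwords = character(),
                            normalizer = identity_normalizer) {
  stopifnot(inherits(note, "raw_note"), is.function(normalizer))
  toks <- tokenize_text(note$text)
  toks <- toks[!toks %in% tolower(stopwords)]
  if (length(toks)) {
    stems <- normalizer(toks)
    if (length(stems) != length(toks) || any(!nzchar(stems))) {
      stop("normalizer must map every token to a non-empty stem")
    }
  } else {
    stems <- character()
  }
  counts <- if (length(stems)) {
    tab <- table(stems)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(), character())
  }
  structure(list(id = note$id, tokens = stems, counts = counts,
                 length_N = length(stems)),
            class = "processed_note")
}

#' Preprocess a note collection
#'
#' @inheritParams preprocess_note
#' @param notes List of [raw_note()] objects.
#' @return List of `processed_note` objects, in input order.
#' @export
preprocess_notes <- function(notes, stopwords = character(),
                             normalizer = identity_normalizer) {
  lapply(notes, preprocess_note, stopwords = stopwords,
         normalizer = normalizer)
}

#' Corpus vocabulary
#'
#' Sorted, deduplicated union of the stems of all processed notes. The
#' lexicographic order (C collation) makes the result deterministic across
#' platforms.
#'
#' @param pnotes Non-empty list of `processed_note` objects.
#' @return Character vector (possibly empty when all notes are empty).
#' @export
build_vocabulary <- function(pnotes) {
  if (length(pnotes) == 0L) stop("empty note collection")
  stems <- unlist(lapply(pnotes, `[[`, "tokens"), use.names = FALSE)
  sort(unique(stems), method = "radix")
}

#' @export
print.processed_note <- function(x, ...) {
  cat("<processed_note> id=", x$id, " N=", x$length_N,
      " distinct=", length(x$counts), "\n", sep = "")
  invisible(x)
}
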