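# Per-note and per-group emotion intensity profiles.

#' Emotion profile of one note
#'
#' For each emotion e, the intensity is the count-weighted mean over the
#' note's stems: I_e = sum_s count(s) * intensity_e(s) / N, where N is the
#' note length in retained tokens. Stems absent from the (extended) lexicon
#' contribute zero intensity but still count in N -- the denominator is the
#' note length, not the number of lexicon hits.
#'
#' @param pnote A `processed_note` with `length_N > 0`.
#' @param lexicon Standardized (optionally extended) `affective_lexicon`.
#' @return List with `note_id` and `intensity`, a named numeric vector with
#'   one entry per emotion, each in \[0, 1\].
#' @export
note_emotion_profile <- function(pnote, lexicon) {
  stopifnot(inherits(pnote, "processed_note"),
            inherits(lexicon, "affective_lexicon"),
            lexicon$scale == "standardized")
  if (pnote$length_N == 0L) stop("empty note '", pnote$id, "'")
  stems <- names(pnote$counts)
  idx <- match(stems, lexicon$entries$word)
  s <- matrix(0, nrow = length(stems), ncol = length(.emotions),
              dimnames = list(NULL, .emotions))
  hit <- !is.na(idx)
  if (any(hit)) {
    s[hit, ] <- as.matrix(lexicon$entries[idx[hit], .emotions])
  }
  intensity <- as.numeric(crossprod(s, pnote$counts)) / pnote$length_N
  list(note_id = pnote$id,
       intensity = stats::setNames(intensity, .emotions))
}

#' Emotion profiles for a note collection
#'
#' @param pnotes List of `processed_note` objects (all non-empty).
#' @param lexicon Standardized `affective_lexicon`.
#' @return Data frame: `note_id` plus one column per emotion.
#' @export
note_emotion_profiles <- function(pnotes, lexicon) {
  rows <- lapply(pnotes, function(p) {
    pr <- note_emotion_profile(p, lexicon)
    data.frame(note_id = pr$note_id, t(pr$intensity), check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean emotion profile per disease-stage group
#'
#' Arithmetic mean of member notes' profiles, per stage, with group sizes
#' reported. Stages declared (as factor levels of `stages`) but empty are
#' omitted with a warning.
#'
#' @param profiles Data frame from [note_emotion_profiles()].
#' @param stages Named character vector or factor mapping `note_id` to a
#'   stage label; every profiled note must be covered.
#' @return Data frame: `stage`, `n`, and one mean-intensity column per
#'   emotion.
#' @export
group_emotion_profile <- function(profiles, stages) {
  st <- stages[profiles$note_id]
  if (anyNA(st) || is.null(names(stages))) {
    missing_ids <- profiles$note_id[is.na(st)]
    stop("no stage for note(s): ", paste(missing_ids, collapse = ", "))
  }
  declared <- if (is.factor(stages)) levels(stages) else unique(as.character(stages))
  st <- as.character(st)
  empty <- setdiff(declared, unique(st))
  if (length(empty)) {
    warning("empty stage group(s) omitted: ", paste(empty, collapse = ", "))
  }
  groups <- declared[declared %in% unique(st)]
  rows <- lapply(groups, function(g) {
    sub <- profiles[st == g, .emotions, drop = FALSE]
    data.frame(stage = g, n = nrow(sub), t(colMeans(sub)), check.names = FALSE)
  })
  do.call(rbind, rows)
}
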