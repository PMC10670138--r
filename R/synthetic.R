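# Seeded synthetic fixtures with known ground truth: an affective lexicon,
# cluster-structured embeddings, polarity and area dictionaries, and note
# collections with planted sentiment, per-area context, and stage labels.
# Tokens are synthetic letter-only strings (emohapxaa, bodyimgnegc, ...)
# that survive the corpus tokenizer, so no language resources are needed;
# every pipeline stage can be validated against the planted truth.

#' Synthetic-generator configuration
#'
#' Defaults mirror the study conditions the pipeline targets: 50 notes in
#' stage groups of 11 (diagnosis), 32 (treatment) and 7 (palliative care);
#' planted sentiments 29 negative / 10 positive / 11 neutral;
#' 100-dimensional embeddings with five emotion clusters separated by ten
#' times the within-cluster noise.
#'
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the configuration.
#' @param n_lexicon_words Affective-lexicon size (>= 5).
#' @param n_notes Number of notes; `stage_sizes` and `sentiment_sizes`
#'   must sum to it.
#' @param embed_dim Embedding dimension (>= 5, default 100).
#' @param cluster_separation Mutual distance between emotion cluster
#'   centers in embedding space.
#' @param noise_sigma Per-coordinate Gaussian noise around each center.
#' @param stage_sizes Named counts over stage labels.
#' @param sentiment_sizes Named counts over negative/positive/neutral.
#' @param planted_context Optional notes x areas matrix with values in
#'   `c(0, -1, 1, 2)`; by default every note raises every area with a
#'   context drawn uniformly from -1/1/2.
#' @param n_area_tokens Tokens drawn from an area dictionary per covered
#'   area (split evenly between polarities for mixed contexts).
#' @param n_sentiment_tokens Polarity-lexicon tokens planted per
#'   negative/positive note (neutral notes get half as many
#'   neutral-labelled tokens).
#' @param n_emotion_tokens Affective-lexicon tokens per note.
#' @param n_filler_tokens Filler tokens per note.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_lexicon_words = 250L,
                             n_notes = 50L,
                             embed_dim = 100L,
                             cluster_separation = 10,
                             noise_sigma = 1,
                             stage_sizes = c(I = 11L, II = 32L, palliative = 7L),
                             sentiment_sizes = c(negative = 29L, positive = 10L,
                                                 neutral = 11L),
                             planted_context = NULL,
                             n_area_tokens = 8L,
                             n_sentiment_tokens = 4L,
                             n_emotion_tokens = 3L,
                             n_filler_tokens = 2L) {
  stopifnot(n_lexicon_words >= 5L, embed_dim >= 5L,
            cluster_separation > 0, noise_sigma >= 0,
            n_area_tokens >= 2L)
  if (sum(stage_sizes) != n_notes) {
    stop("stage_sizes must sum to n_notes (", sum(stage_sizes), " != ", n_notes, ")")
  }
  if (sum(sentiment_sizes) != n_notes) {
    stop("sentiment_sizes must sum to n_notes")
  }
  bad <- setdiff(names(stage_sizes), .stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(planted_context)) {
    stopifnot(is.matrix(planted_context),
              nrow(planted_context) == n_notes,
              identical(colnames(planted_context), .areas),
              all(planted_context %in% c(0, -1, 1, 2)))
  }
  structure(list(seed = as.integer(seed),
                 n_lexicon_words = as.integer(n_lexicon_words),
                 n_notes = as.integer(n_notes),
                 embed_dim = as.integer(embed_dim),
                 cluster_separation = cluster_separation,
                 noise_sigma = noise_sigma,
                 stage_sizes = stage_sizes,
                 sentiment_sizes = sentiment_sizes,
                 planted_context = planted_context,
                 n_area_tokens = as.integer(n_area_tokens),
                 n_sentiment_tokens = as.integer(n_sentiment_tokens),
                 n_emotion_tokens = as.integer(n_emotion_tokens),
                 n_filler_tokens = as.integer(n_filler_tokens)),
            class = "generator_config")
}

# letter-only token ids so generated words survive the corpus tokenizer
# (which splits on any non-letter character): 1 -> "a", 27 -> "aa", ...
letter_id <- function(i) {
  vapply(i, function(x) {
    out <- character()
    while (x > 0) {
      r <- (x - 1) %% 26
      out <- c(letters[r + 1], out)
      x <- (x - 1) %/% 26
    }
    paste(out, collapse = "")
  }, character(1))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic affective lexicon (base scale)
#'
#' Words are assigned the five emotions cyclically (so `n = 5` gives one
#' word per emotion); each word's dominant-emotion intensity is drawn
#' uniformly from \[5, 7\] and the remaining four from \[1, 3\], on the
#' base 1--7 scale. Deterministic under the configuration seed.
#'
#' @param config A [generator_config()].
#' @return An `affective_lexicon` with `scale = "base"`.
#' @export
generate_affective_lexicon <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_lexicon_words
  dom_idx <- rep(seq_along(.emotions), length.out = n)
  words <- paste0("emo", substr(.emotions, 1, 3)[dom_idx], "x", letter_id(seq_len(n)))
  with_seed(config$seed, {
    m <- matrix(stats::runif(n * 5L, 1, 3), nrow = n,
                dimnames = list(NULL, .emotions))
    m[cbind(seq_len(n), dom_idx)] <- stats::runif(n, 5, 7)
    affective_lexicon(data.frame(word = words, m, check.names = FALSE),
                      scale = "base")
  })
}

#' Generate cluster-structured synthetic embeddings
#'
#' Five cluster centers sit on orthogonal axes, scaled so any two are at
#' mutual Euclidean distance `cluster_separation`; each lexicon word's
#' vector is its dominant emotion's center plus isotropic Gaussian noise
#' of `noise_sigma` per coordinate. Extra (non-lexicon) words receive
#' unstructured Gaussian vectors around the origin.
#'
#' @param lexicon An `affective_lexicon` (any scale).
#' @param config A [generator_config()].
#' @param extra_words Optional character vector of additional words to
#'   embed (area/polarity/filler tokens of generated notes).
#' @return An `embedding_space`.
#' @export
generate_embeddings <- function(lexicon, config, extra_words = NULL) {
  stopifnot(inherits(lexicon, "affective_lexicon"),
            inherits(config, "generator_config"))
  d <- config$embed_dim
  centers <- matrix(0, nrow = 5L, ncol = d, dimnames = list(.emotions, NULL))
  # orthogonal placement: pairwise distance sep requires axis scale sep/sqrt(2)
  for (j in 1:5) centers[j, j] <- config$cluster_separation / sqrt(2)
  words <- lexicon$entries$word
  dom <- lexicon$entries$dominant
  with_seed(config$seed + 1L, {
    m <- centers[dom, , drop = FALSE] +
      matrix(stats::rnorm(length(words) * d, 0, config$noise_sigma),
             ncol = d)
    rownames(m) <- words
    if (length(extra_words)) {
      extra_words <- setdiff(unique(extra_words), words)
      e <- matrix(stats::rnorm(length(extra_words) * d, 0,
                               max(config$noise_sigma, 0.1)),
                  ncol = d, dimnames = list(extra_words, NULL))
      m <- rbind(m, e)
    }
    embedding_space(m)
  })
}

#' Generate synthetic area dictionaries
#'
#' Disjoint positive/negative vocabularies per difficulty area, named
#' `<area>_pos_w01` etc. Deterministic (no randomness involved).
#'
#' @param n_words Words per area per polarity (default 12).
#' @return Named list of per-area dictionaries.
#' @export
generate_area_dictionaries <- function(n_words = 12L) {
  codes <- c(body_image = "bodyimg", environment_acceptance = "envacc",
             self_esteem = "selfest")
  out <- lapply(.areas, function(a) {
    list(positive = paste0(codes[[a]], "pos", letter_id(seq_len(n_words))),
         negative = paste0(codes[[a]], "neg", letter_id(seq_len(n_words))))
  })
  names(out) <- .areas
  validate_area_dictionaries(out)
}

#' Generate a synthetic polarity lexicon
#'
#' @param n_per_class Words per polarity class (default 20).
#' @return A `polarity_lexicon` over `pol_pos_*`, `pol_neg_*`,
#'   `pol_neu_*` words.
#' @export
generate_polarity_lexicon <- function(n_per_class = 20L) {
  words <- c(paste0("polpos", letter_id(seq_len(n_per_class))),
             paste0("polneg", letter_id(seq_len(n_per_class))),
             paste0("polneu", letter_id(seq_len(n_per_class))))
  polarity_lexicon(words, rep(c("positive", "negative", "neutral"),
                              each = n_per_class))
}

filler_vocabulary <- function(n = 30L) paste0("fill", letter_id(seq_len(n)))

#' Generate synthetic notes with planted ground truth
#'
#' Each note's tokens are sampled from (a) the polarity lexicon according
#' to its planted sentiment, (b) each covered area's dictionary according
#' to its planted context (single-polarity draws for -1/1, an even
#' positive/negative split for mixed), (c) the affective lexicon, and (d)
#' a filler vocabulary; the token order is shuffled. Stage labels follow
#' `stage_sizes`; expert flags equal the planted contexts; everything is
#' deterministic under the configuration seed.
#'
#' @param config A [generator_config()].
#' @param area_dicts Area dictionaries
#'   (default [generate_area_dictionaries()]).
#' @param polarity_lex A `polarity_lexicon`
#'   (default [generate_polarity_lexicon()]).
#' @param lexicon Optional `affective_lexicon` supplying emotion tokens.
#' @return List with `notes` (list of [raw_note()], flags attached),
#'   `flags` (long data frame `note_id`, `area`, `flag`), and `truth`
#'   (planted `sentiment`, `context` matrix, `stage`).
#' @export
generate_notes <- function(config,
                           area_dicts = generate_area_dictionaries(),
                           polarity_lex = generate_polarity_lexicon(),
                           lexicon = NULL) {
  stopifnot(inherits(config, "generator_config"))
  area_dicts <- validate_area_dictionaries(area_dicts)
  n <- config$n_notes
  ids <- sprintf("note%03d", seq_len(n))
  stages <- rep(names(config$stage_sizes), config$stage_sizes)
  pol_words <- split(names(unclass(polarity_lex)), unclass(polarity_lex))
  for (cl in c("positive", "negative", "neutral")) {
    if (length(pol_words[[cl]] %||% character()) == 0L) {
      stop("polarity lexicon has no ", cl, " word")
    }
  }
  with_seed(config$seed + 2L, {
    sentiments <- sample(rep(names(config$sentiment_sizes),
                             config$sentiment_sizes))
    context <- config$planted_context
    if (is.null(context)) {
      context <- matrix(sample(c(-1, 1, 2), n * length(.areas), replace = TRUE),
                        nrow = n, dimnames = list(ids, .areas))
    } else {
      rownames(context) <- ids
    }
    notes <- vector("list", n)
    for (i in seq_len(n)) {
      toks <- character()
      for (a in .areas) {
        ctx <- context[i, a]
        d <- area_dicts[[a]]
        na <- config$n_area_tokens
        toks <- c(toks, switch(as.character(ctx),
          `-1` = sample(d$negative, na, replace = TRUE),
          `1` = sample(d$positive, na, replace = TRUE),
          `2` = c(sample(d$positive, ceiling(na / 2), replace = TRUE),
                  sample(d$negative, ceiling(na / 2), replace = TRUE)),
          `0` = character()))
      }
      toks <- c(toks, switch(sentiments[i],
        negative = sample(pol_words$negative, config$n_sentiment_tokens,
                          replace = TRUE),
        positive = sample(pol_words$positive, config$n_sentiment_tokens,
                          replace = TRUE),
        neutral = sample(pol_words$neutral,
                         max(1L, config$n_sentiment_tokens %/% 2L),
                         replace = TRUE)))
      if (!is.null(lexicon) && config$n_emotion_tokens > 0L) {
        toks <- c(toks, sample(lexicon$entries$word, config$n_emotion_tokens,
                               replace = TRUE))
      }
      if (config$n_filler_tokens > 0L) {
        toks <- c(toks, sample(filler_vocabulary(), config$n_filler_tokens,
                               replace = TRUE))
      }
      toks <- sample(toks)
      flags <- as.list(context[i, ])
      notes[[i]] <- raw_note(ids[i], paste(toks, collapse = " "),
                             stage = stages[i], flags = flags)
    }
    flags_df <- data.frame(
      note_id = rep(ids, each = length(.areas)),
      area = rep(.areas, times = n),
      flag = as.integer(t(context)))
    list(notes = notes,
         flags = flags_df,
         truth = list(sentiment = stats::setNames(sentiments, ids),
                      context = context,
                      stage = stats::setNames(stages, ids)))
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits `notes.jsonl`, `lexicon.tsv` (base scale), `embeddings.vec`,
#' `polarity.tsv`, `areas.json`, `flags.csv`, and `truth.json` under
#' `dir`, all derived from one configuration.
#'
#' @param dir Output directory (created if missing).
#' @param config A [generator_config()].
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_fixture <- function(dir, config = generator_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lexicon <- generate_affective_lexicon(config)
  areas <- generate_area_dictionaries()
  pol <- generate_polarity_lexicon()
  gen <- generate_notes(config, areas, pol, lexicon = lexicon)
  extra <- unique(unlist(lapply(gen$notes, function(n) tokenize_text(n$text))))
  space <- generate_embeddings(lexicon, config, extra_words = extra)

  paths <- c(notes = file.path(dir, "notes.jsonl"),
             lexicon = file.path(dir, "lexicon.tsv"),
             embeddings = file.path(dir, "embeddings.vec"),
             polarity = file.path(dir, "polarity.tsv"),
             areas = file.path(dir, "areas.json"),
             flags = file.path(dir, "flags.csv"),
             truth = file.path(dir, "truth.json"))

  con <- file(paths[["notes"]], "w", encoding = "UTF-8")
  for (note in gen$notes) {
    writeLines(jsonlite::toJSON(list(id = note$id, text = note$text,
                                     stage = note$stage, flags = note$flags),
                                auto_unbox = TRUE), con)
  }
  close(con)
  write_affective_lexicon(lexicon, paths[["lexicon"]])
  write_embeddings(space, paths[["embeddings"]])
  utils::write.table(data.frame(word = names(unclass(pol)),
                                polarity = as.character(unclass(pol))),
                     paths[["polarity"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(areas, paths[["areas"]])
  utils::write.csv(gen$flags, paths[["flags"]], row.names = FALSE)
  jsonlite::write_json(list(sentiment = as.list(gen$truth$sentiment),
                            stage = as.list(gen$truth$stage),
                            context = as.data.frame(gen$truth$context)),
                       paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}
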