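# One entry point orchestrating the four analysis arms and writing a
# consolidated per-patient report.

#' Pipeline run configuration
#'
#' @param notes Path to the note collection (jsonl/csv/txt directory).
#' @param lexicon Path to the base-scale affective lexicon TSV (optional;
#'   emotion profiling is skipped without it).
#' @param embeddings Path to word2vec-text embeddings (optional; without
#'   it the lexicon is used as-is, unextended).
#' @param polarity Path to the polarity lexicon TSV (optional; sentiment
#'   and adjective polarity are skipped without it).
#' @param tagger Path to a dictionary-tagger TSV (optional; the POS
#'   profile is skipped without it).
#' @param areas Path to the area-dictionaries JSON (optional; topic
#'   analysis is skipped without it).
#' @param flags Path to an expert-flag CSV (optional; agreement scoring is
#'   skipped without it; flags embedded in the notes are used when no file
#'   is given).
#' @param stopwords Path to a stop-word list (optional).
#' @param n_neighbors Neighbour count for lexicon extension.
#' @param alpha Hybrid sentiment mixing weight in \[0, 1\].
#' @param lsa_k Retained LSA dimensions (`NULL` = default heuristic).
#' @param threshold Context-classifier threshold in percent, in (0, 100).
#' @param top_k Characteristic-term count.
#' @param seed Integer seed for any stochastic component.
#' @param outdir Optional output directory for `report.json` and
#'   `report.md`.
#' @return A `run_config` list.
#' @export
run_config <- function(notes,
                       lexicon = NULL, embeddings = NULL, polarity = NULL,
                       tagger = NULL, areas = NULL, flags = NULL,
                       stopwords = NULL,
                       n_neighbors = 5L, alpha = 0.5, lsa_k = NULL,
                       threshold = 20, top_k = 10L, seed = 1L,
                       outdir = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, threshold > 0, threshold < 100)
  structure(list(notes = notes, lexicon = lexicon, embeddings = embeddings,
                 polarity = polarity, tagger = tagger, areas = areas,
                 flags = flags, stopwords = stopwords,
                 n_neighbors = as.integer(n_neighbors), alpha = alpha,
                 lsa_k = lsa_k, threshold = threshold,
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocessing, lexicon extension, emotion profiling,
#' hybrid sentiment, the POS profile, topic detection, and agreement
#' scoring. Optional inputs that are absent skip only their dependent
#' sections (with a logged notice); the run is deterministic given the
#' configuration.
#'
#' @param config A [run_config()].
#' @param model Optional sentiment classifier honouring the
#'   [sentiment_probs()] contract.
#' @param quiet Suppress progress messages.
#' @return A `pipeline_report` list with sections `notes` (per-note table:
#'   emotion intensities, sentiment, area contexts), `group_profiles`,
#'   `sentiment_counts`, `pos_profile`, `characteristic_terms`, `topics`,
#'   `agreement`, and `skipped_words`.
#' @export
run_pipeline <- function(config, model = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  set.seed(config$seed)

  say("reading notes from ", config$notes)
  notes <- read_notes(config$notes)
  stopwords <- if (!is.null(config$stopwords)) {
    read_stopwords(config$stopwords)
  } else {
    character()
  }
  pnotes <- preprocess_notes(notes, stopwords = stopwords)
  nonempty <- vapply(pnotes, function(p) p$length_N > 0L, logical(1))
  if (any(!nonempty)) {
    warning("empty after preprocessing, excluded: ",
            paste(vapply(pnotes[!nonempty], `[[`, character(1), "id"),
                  collapse = ", "))
    pnotes <- pnotes[nonempty]
    notes <- notes[nonempty]
  }
  if (length(pnotes) == 0L) stop("corpus stage: no non-empty notes")
  vocab <- build_vocabulary(pnotes)
  ids <- vapply(pnotes, `[[`, character(1), "id")
  report <- list(notes = data.frame(note_id = ids))
  skipped <- character()

  # emotion arm
  if (!is.null(config$lexicon)) {
    say("emotion profiling (lexicon: ", config$lexicon, ")")
    lexicon <- standardize_weights(read_affective_lexicon(config$lexicon))
    if (!is.null(config$embeddings)) {
      space <- read_embeddings(config$embeddings)
      lexicon <- extend_lexicon(vocab, lexicon, space,
                                n = config$n_neighbors)
      skipped <- attr(lexicon, "skipped") %||% character()
    } else {
      say("no embeddings supplied; lexicon used unextended")
    }
    profiles <- note_emotion_profiles(pnotes, lexicon)
    report$notes <- merge(report$notes, profiles, by = "note_id", sort = FALSE)
    stages <- stats::setNames(vapply(notes, `[[`, character(1), "stage"), ids)
    report$group_profiles <- group_emotion_profile(profiles, stages)
  } else {
    say("no affective lexicon supplied; emotion arm skipped")
  }

  # sentiment arm
  if (!is.null(config$polarity)) {
    say("sentiment analysis (alpha = ", config$alpha, ")")
    pol <- read_polarity_lexicon(config$polarity)
    sent <- analyze_sentiment(pnotes, pol, model = model,
                              alpha = config$alpha)
    report$notes <- merge(report$notes,
                          sent[, c("note_id", "dict_score", "label")],
                          by = "note_id", sort = FALSE)
    names(report$notes)[names(report$notes) == "label"] <- "sentiment"
    report$sentiment <- sent
    report$sentiment_counts <- sentiment_summary(sent)
  } else {
    pol <- NULL
    say("no polarity lexicon supplied; sentiment arm skipped")
  }

  # POS arm
  if (!is.null(config$tagger)) {
    say("part-of-speech profiling")
    tagger <- read_tagger(config$tagger)
    tagged <- tag_corpus(notes, tagger, polarity = pol)
    report$pos_profile <- pos_statistics(tagged)
  } else {
    say("no tagger supplied; POS arm skipped")
  }
  report$characteristic_terms <- characteristic_terms(pnotes, stopwords,
                                                      top_k = config$top_k)

  # topics arm
  if (!is.null(config$areas)) {
    say("topic analysis (threshold ", config$threshold, "%)")
    dicts <- read_area_dictionaries(config$areas)
    topics <- analyze_topics(pnotes, dicts, k = config$lsa_k,
                             threshold = config$threshold)
    report$topics <- topics
    wide <- stats::reshape(topics[, c("note_id", "area", "context")],
                           idvar = "note_id", timevar = "area",
                           direction = "wide")
    names(wide) <- sub("^context\\.", "context_", names(wide))
    report$notes <- merge(report$notes, wide, by = "note_id", sort = FALSE)
    flags <- if (!is.null(config$flags)) {
      read_expert_flags(config$flags)
    } else {
      notes_expert_flags(notes)
    }
    if (nrow(flags) > 0L) {
      report$agreement <- evaluate_agreement(topics, flags)
    } else {
      say("no expert flags available; agreement section skipped")
    }
  } else {
    say("no area dictionaries supplied; topics arm skipped")
  }

  report$skipped_words <- skipped
  class(report) <- "pipeline_report"
  if (!is.null(config$outdir)) write_pipeline_report(report, config$outdir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (machine-readable, full content) and `report.md`
#' (human-readable summary) under `dir`.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the report paths.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  out <- report
  class(out) <- NULL
  if (!is.null(out$agreement)) {
    out$agreement <- list(per_area = out$agreement$per_area,
                          expert_shares = out$agreement$expert_shares)
  }
  if (!is.null(out$pos_profile)) out$pos_profile <- as.list(out$pos_profile)
  if (!is.null(out$sentiment_counts)) {
    out$sentiment_counts <- as.list(out$sentiment_counts)
  }
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  md <- c("# Note analysis report", "",
          paste0("Notes analysed: ", nrow(report$notes)), "")
  if (!is.null(report$sentiment_counts)) {
    md <- c(md, "## Sentiment",
            paste0("- ", names(report$sentiment_counts), ": ",
                   report$sentiment_counts), "")
  }
  if (!is.null(report$group_profiles)) {
    md <- c(md, "## Mean emotion intensity by stage group", "",
            utils::capture.output(print(report$group_profiles,
                                        row.names = FALSE)), "")
  }
  if (!is.null(report$pos_profile)) {
    md <- c(md, "## Part-of-speech profile",
            paste0("- ", names(report$pos_profile), ": ",
                   as.integer(report$pos_profile)), "")
  }
  if (!is.null(report$agreement)) {
    md <- c(md, "## Agreement with expert flags", "",
            utils::capture.output(print(report$agreement$per_area,
                                        row.names = FALSE)), "")
  }
  writeLines(md, md_path)
  invisible(c(json = json_path, md = md_path))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", nrow(x$notes), " notes; sections: ",
      paste(setdiff(names(x), "notes"), collapse = ", "), "\n", sep = "")
  invisible(x)
}
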