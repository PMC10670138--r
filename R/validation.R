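# Packaged validation experiments on synthetic data with known ground
# truth: held-out lexicon-extension recovery and end-to-end context
# recovery. Both are deterministic functions of a generator configuration.

#' Held-out lexicon-extension recovery experiment
#'
#' Generates a synthetic lexicon and cluster-structured embeddings,
#' removes a fraction of the lexicon words, re-derives their entries with
#' [extend_word()] from the retained words, and compares against the
#' planted truth. Two quantities are reported: the share of held-out words
#' whose interpolated dominant emotion equals the planted one, and the
#' root-mean-square error of the interpolated standardized intensities
#' over all held-out words and all five emotions.
#'
#' The interpolated value for a held-out word is essentially a
#' similarity-weighted within-cluster mean, so its error floor is the
#' within-cluster intensity spread; a neighbour count a good deal larger
#' than the default extension setting (here sized to roughly a quarter of
#' a cluster) averages that estimator noise away without leaving the
#' cluster.
#'
#' @param config A [generator_config()]; the lexicon size should be large
#'   enough that each emotion keeps a sensible neighbour pool after the
#'   hold-out split.
#' @param holdout_frac Fraction of lexicon words held out (default 0.2).
#' @param n_neighbors Neighbour count used for the interpolation.
#' @return List with `n_heldout`, `dominant_recovery_pct`,
#'   `intensity_rmse`, and the per-word `detail` data frame.
#' @export
evaluate_extension_recovery <- function(config, holdout_frac = 0.2,
                                        n_neighbors = 50L) {
  stopifnot(inherits(config, "generator_config"),
            holdout_frac > 0, holdout_frac < 1)
  lexicon <- standardize_weights(generate_affective_lexicon(config))
  space <- generate_embeddings(lexicon, config)
  words <- lexicon$entries$word
  n_hold <- max(5L, floor(length(words) * holdout_frac))
  held <- with_seed(config$seed + 3L, sample(words, n_hold))
  retained <- affective_lexicon(
    lexicon$entries[!words %in% held, c("word", .emotions, "origin")],
    scale = "standardized")
  centers <- compute_emotion_centers(retained, space)
  truth <- lexicon$entries[match(held, lexicon$entries$word), ]
  rows <- lapply(held, function(w) {
    e <- extend_word(w, retained, space, centers, n = n_neighbors)
    data.frame(word = w, predicted_dominant = e$dominant,
               true_dominant = truth$dominant[truth$word == w],
               sq_err = sum((e$intensities -
                               as.numeric(truth[truth$word == w, .emotions]))^2))
  })
  detail <- do.call(rbind, rows)
  list(n_heldout = n_hold,
       dominant_recovery_pct =
         100 * mean(detail$predicted_dominant == detail$true_dominant),
       intensity_rmse = sqrt(sum(detail$sq_err) / (n_hold * length(.emotions))),
       detail = detail)
}

#' End-to-end context-recovery experiment
#'
#' Generates a synthetic note collection with planted per-area contexts,
#' runs the full topic pipeline (preprocessing, frequency matrix, LSA,
#' dictionary fold-in, four-way classification), and scores the predicted
#' contexts against the planted ones over all note x area pairs. The
#' agreement report against the emitted expert flags is returned as well.
#'
#' @param config A [generator_config()].
#' @param k,threshold,tfidf Passed to [analyze_topics()].
#' @return List with `n_pairs`, `recovery_pct`, the `predicted` data
#'   frame, and the `agreement` report.
#' @export
evaluate_context_recovery <- function(config, k = NULL, threshold = 20,
                                      tfidf = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  lexicon <- generate_affective_lexicon(config)
  gen <- generate_notes(config, lexicon = lexicon)
  pnotes <- preprocess_notes(gen$notes)
  predicted <- analyze_topics(pnotes, generate_area_dictionaries(),
                              k = k, threshold = threshold, tfidf = tfidf)
  truth_label <- flag_to_label(
    gen$truth$context[cbind(predicted$note_id, predicted$area)])
  agreement <- evaluate_agreement(predicted, gen$flags)
  list(n_pairs = nrow(predicted),
       recovery_pct = 100 * mean(predicted$context == truth_label),
       predicted = predicted,
       agreement = agreement)
}
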