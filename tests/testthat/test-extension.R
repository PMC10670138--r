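test_that("a centroid over a single member equals that member's vector", {
  lex <- toy_lexicon(paste0("w", 1:5), emotions())
  vecs <- diag(5) + 0.1
  sp <- toy_space(paste0("w", 1:5), asplit(vecs, 1))
  centers <- compute_emotion_centers(lex, sp)
  for (i in 1:5) {
    expect_equal(unname(centers[[emotions()[i]]]$centroid), vecs[i, ])
  }
})

test_that("centers fall back to the lexicon-space pool when the corpus lacks an emotion", {
  lex <- toy_lexicon(paste0("w", 1:5), emotions())
  sp <- toy_space(paste0("w", 1:5), asplit(diag(5) + 0.1, 1))
  expect_warning(
    centers <- compute_emotion_centers(lex, sp,
                                       note_vocab = c("w1", "w2", "w3", "w4")),
    "falling back")
  expect_identical(centers$disgust$member_words, "w5")
})

test_that("matching picks the most similar center, ties in canonical order", {
  lex <- toy_lexicon(paste0("w", 1:5), emotions())
  sp <- toy_space(c(paste0("w", 1:5), "q", "tie"),
                  c(asplit(diag(5), 1), list(c(0, 0, 0.9, 0, 0)),
                    list(rep(1, 5))))
  centers <- compute_emotion_centers(lex, sp)
  expect_identical(match_word_to_center("q", sp, centers), "anger")
  # equidistant to all five centers -> happiness by tie order
  expect_identical(match_word_to_center("tie", sp, centers), "happiness")
  expect_error(match_word_to_center("absent", sp, centers),
               class = "notescope_unembeddable")
})

test_that("extending an in-lexicon word is the identity", {
  lex <- toy_lexicon(paste0("w", 1:5), emotions())
  sp <- toy_space(paste0("w", 1:5), asplit(diag(5), 1))
  centers <- compute_emotion_centers(lex, sp)
  e <- extend_word("w2", lex, sp, centers, n = 3)
  expect_identical(e$origin, "original")
  expect_equal(unname(e$intensities["sadness"]), 0.8)
})

test_that("equal-similarity neighbours average their intensities", {
  # two fear-dominant words symmetric about the query, plus one word for
  # each other emotion far away
  words <- c("f1", "f2", "h", "s", "a", "d", "q")
  vecs <- list(c(10, 1, 0, 0), c(10, -1, 0, 0), c(-10, 0, 1, 0),
               c(-10, 0, -1, 0), c(0, 10, 0, 1), c(0, -10, 0, 1),
               c(10, 0, 0, 0))
  sp <- toy_space(words, vecs)
  df <- data.frame(word = words[1:6],
                   happiness = c(0.1, 0.1, 0.9, 0.1, 0.1, 0.1),
                   sadness = c(0.1, 0.1, 0.1, 0.9, 0.1, 0.1),
                   anger = c(0.1, 0.1, 0.1, 0.1, 0.9, 0.1),
                   fear = c(0.2, 0.8, 0.1, 0.1, 0.1, 0.1),
                   disgust = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.9))
  lex <- affective_lexicon(df, scale = "standardized")
  centers <- compute_emotion_centers(lex, sp)
  e <- extend_word("q", lex, sp, centers, n = 2)
  expect_identical(attr(e, "matched_emotion"), "fear")
  expect_equal(unname(e$intensities["fear"]), 0.5)
  expect_identical(e$origin, "extended")
})

test_that("identical neighbour intensities are a fixed point regardless of distance", {
  lex <- toy_lexicon(c("f1", "f2", "f3", "h", "s", "a", "d"),
                     c("fear", "fear", "fear", "happiness", "sadness",
                       "anger", "disgust"), dom_value = 0.6,
                     other_value = 0.15)
  set.seed(1)
  sp <- toy_space(c("f1", "f2", "f3", "h", "s", "a", "d", "q"),
                  c(lapply(1:3, function(i) c(5, 0, 0) + rnorm(3, 0, 0.5)),
                    list(c(-5, 1, 0), c(-5, -1, 0), c(0, -5, 1), c(0, -5, -1),
                         c(5, 0.2, 0.1))))
  centers <- compute_emotion_centers(lex, sp)
  e <- extend_word("q", lex, sp, centers, n = 3)
  expect_equal(unname(e$intensities["fear"]), 0.6, tolerance = 1e-12)
})

test_that("weights sum to one and extension matches the brute-force oracle", {
  set.seed(2024)
  for (rep in 1:40) {
    inst <- random_extension_instance()
    centers <- compute_emotion_centers(inst$lexicon, inst$space)
    got <- extend_word("query", inst$lexicon, inst$space, centers, n = inst$n)
    want <- oracle_extend("query", inst$lexicon_df, inst$space, inst$n)
    expect_identical(attr(got, "matched_emotion"), want$matched)
    expect_equal(got$intensities, want$intensities, tolerance = 1e-12)
    expect_equal(sum(attr(got, "neighbors")$weight), 1, tolerance = 1e-12)
    # convex combination: inside the neighbours' hull, per emotion
    for (e in emotions()) {
      expect_gte(got$intensities[[e]], min(want$neighbor_intensities[[e]]) - 1e-12)
      expect_lte(got$intensities[[e]], max(want$neighbor_intensities[[e]]) + 1e-12)
    }
  }
})

test_that("n covering the whole pool gives the similarity-weighted pool mean", {
  set.seed(7)
  inst <- random_extension_instance()
  centers <- compute_emotion_centers(inst$lexicon, inst$space)
  got <- extend_word("query", inst$lexicon, inst$space, centers, n = 1000L)
  matched <- attr(got, "matched_emotion")
  doms <- inst$lexicon$entries$dominant
  pool <- inst$lexicon$entries$word[doms == matched]
  sims <- vapply(pool, function(w)
    cosine_similarity(inst$space[w, ], inst$space["query", ]), numeric(1))
  w <- (sims + 1) / 2
  w <- w / sum(w)
  s <- as.matrix(inst$lexicon$entries[match(pool, inst$lexicon$entries$word),
                                      emotions()])
  expect_equal(unname(got$intensities), as.numeric(crossprod(s, w)),
               tolerance = 1e-12)
})

test_that("extend_lexicon adds entries only for new embeddable words", {
  lex <- toy_lexicon(paste0("w", 1:5), emotions())
  sp <- toy_space(c(paste0("w", 1:5), "nowy"),
                  c(asplit(diag(5), 1), list(c(0.9, 0, 0, 0, 0.1))))
  centers <- compute_emotion_centers(lex, sp)
  # vocab fully inside the lexicon -> identity
  same <- extend_lexicon(paste0("w", 1:5), lex, sp, centers = centers)
  expect_identical(same$entries, lex$entries)
  # one new embeddable word, one unembeddable
  ext <- extend_lexicon(c("w1", "nowy", "brak"), lex, sp, centers = centers)
  expect_identical(sum(ext$entries$origin == "extended"), 1L)
  expect_identical(attr(ext, "skipped"), "brak")
  expect_true("nowy" %in% ext$entries$word)
})
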