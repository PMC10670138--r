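tagger_fixture <- function() {
  dictionary_tagger(data.frame(
    wordform = c("brzydki", "suchy", "piekny", "jest", "byl", "bedzie",
                 "boli", "bolal", "wyglada"),
    pos = c("adjective", "adjective", "adjective", "verb", "verb", "verb",
            "verb", "verb", "verb"),
    lemma = c("brzydki", "suchy", "piekny", "być", "być", "być",
              "boleć", "boleć", "wyglądać"),
    tense = c(NA, NA, NA, "present", "past", "future", "present", "past",
              "present")))
}

pos_polarity <- function() {
  polarity_lexicon(c("brzydki", "suchy", "piekny"),
                   c("negative", "negative", "positive"))
}

test_that("tagging is a deterministic lookup with MY detection", {
  tt <- tag_tokens(raw_note("n1", "Moje cialo jest brzydkie!"),
                   tagger_fixture(), pos_polarity())
  expect_identical(tt$pos, c("possessive_my", "other", "verb", "other"))
  expect_identical(tt$tense[3], "present")
  # adjective absent from the polarity lexicon stays untyped
  tagger2 <- dictionary_tagger(data.frame(wordform = "nieznany",
                                          pos = "adjective",
                                          lemma = "nieznany", tense = NA))
  tt2 <- tag_tokens(raw_note("n2", "nieznany"), tagger2, pos_polarity())
  expect_identical(tt2$pos, "adjective")
  expect_true(is.na(tt2$polarity))
})

test_that("the corpus profile matches a hand count", {
  # 3 adjectives (2 neg, 1 pos), "to be" x2 (1 past, 1 present),
  # other verbs x2 (present), 1 MY
  note <- raw_note("n1", "moje brzydki suchy piekny jest byl boli wyglada")
  prof <- pos_statistics(tag_corpus(list(note), tagger_fixture(),
                                    pos_polarity()))
  expect_identical(unclass(prof)[c(
    "adj_total", "adj_negative", "adj_positive",
    "verb_total", "verb_tobe_total", "verb_tobe_past", "verb_tobe_present",
    "verb_tobe_future", "verb_other_total", "verb_other_past",
    "verb_other_present", "my_count")],
    c(adj_total = 3L, adj_negative = 2L, adj_positive = 1L,
      verb_total = 4L, verb_tobe_total = 2L, verb_tobe_past = 1L,
      verb_tobe_present = 1L, verb_tobe_future = 0L,
      verb_other_total = 2L, verb_other_past = 0L,
      verb_other_present = 2L, my_count = 1L))
})

test_that("an empty corpus yields an all-zero profile", {
  prof <- pos_statistics(list())
  expect_true(all(unclass(prof) == 0L))
})

test_that("the profile is additive over notes and order-invariant", {
  notes <- list(raw_note("a", "brzydki jest moje"),
                raw_note("b", "piekny boli"),
                raw_note("c", "byl suchy bedzie"))
  tg <- tagger_fixture()
  pol <- pos_polarity()
  whole <- pos_statistics(tag_corpus(notes, tg, pol))
  parts <- lapply(notes, function(n) pos_statistics(tag_tokens(n, tg, pol)))
  summed <- Reduce(`+`, lapply(parts, unclass))
  expect_identical(unclass(whole), summed)
  permuted <- pos_statistics(tag_corpus(notes[c(3, 1, 2)], tg, pol))
  expect_identical(unclass(whole), unclass(permuted))
})

test_that("a corpus planted with the published totals is recovered", {
  # adjectives 191 (138 negative, 53 positive); verbs 270 of which 105
  # "to be" (7 past, 89 present, 9 future) and 165 others (25 past,
  # 140 present); possessive MY 36
  toks <- c(rep("brzydki", 138), rep("piekny", 53),
            rep("byl", 7), rep("jest", 89), rep("bedzie", 9),
            rep("bolal", 25), rep("boli", 140), rep("moje", 36))
  notes <- list(raw_note("n1", paste(toks[1:300], collapse = " ")),
                raw_note("n2", paste(toks[301:length(toks)], collapse = " ")))
  prof <- pos_statistics(tag_corpus(notes, tagger_fixture(), pos_polarity()))
  expect_identical(unname(unclass(prof)[c("adj_total", "adj_negative",
                                          "adj_positive")]),
                   c(191L, 138L, 53L))
  expect_identical(unname(unclass(prof)["verb_total"]), 270L)
  expect_identical(unname(unclass(prof)[c("verb_tobe_total", "verb_tobe_past",
                                          "verb_tobe_present",
                                          "verb_tobe_future")]),
                   c(105L, 7L, 89L, 9L))
  expect_identical(unname(unclass(prof)["my_count"]), 36L)
})

test_that("characteristic terms rank by frequency with lexicographic ties", {
  pns <- list(pnote("d1", c(rep("skora", 5), rep("wlosy", 3))),
              pnote("d2", rep("blady", 3)))
  top <- characteristic_terms(pns, top_k = 2)
  expect_identical(top$term, c("skora", "blady"))
  expect_identical(top$frequency, c(5L, 3L))
  # top_k beyond the vocabulary returns everything
  expect_identical(nrow(characteristic_terms(pns, top_k = 99)), 3L)
  # stop-words are excluded; all-stop-word corpora give an empty ranking
  expect_identical(nrow(characteristic_terms(pns,
                                             stopwords = c("skora", "wlosy",
                                                           "blady"),
                                             top_k = 5)), 0L)
})
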