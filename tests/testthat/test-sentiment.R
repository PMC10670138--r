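polarity_fixture <- function() {
  polarity_lexicon(c("dobry", "piekny", "zly", "brzydki", "zwykly"),
                   c("positive", "positive", "negative", "negative",
                     "neutral"))
}

test_that("polarity lexicon reading validates labels and duplicates", {
  path <- write_tsv(data.frame(word = c("dobry", "zły", "dobry"),
                               polarity = c("positive", "negative",
                                            "positive")))
  lex <- read_polarity_lexicon(path)
  expect_length(unclass(lex), 2L)
  bad <- write_tsv(data.frame(word = "x", polarity = "meh"))
  expect_error(read_polarity_lexicon(bad), "unknown polarity")
  conflict <- write_tsv(data.frame(word = c("a", "a"),
                                   polarity = c("positive", "negative")))
  expect_error(read_polarity_lexicon(conflict), "conflicting")
})

test_that("dictionary score is the normalized count difference", {
  lex <- polarity_fixture()
  expect_equal(dictionary_polarity_score(
    pnote("n", c("dobry", "piekny", "dobry")), lex), 1)
  expect_equal(dictionary_polarity_score(pnote("n", c("obcy", "inny")), lex), 0)
  # pos=1, neg=3 -> (1-3)/4
  expect_equal(dictionary_polarity_score(
    pnote("n", c("dobry", "zly", "zly", "brzydki")), lex), -0.5)
  # neutral tokens enter the denominator only
  expect_equal(dictionary_polarity_score(
    pnote("n", c("dobry", "zwykly")), lex), 0.5)
})

test_that("swapping positive and negative entries flips score and label", {
  lex <- polarity_fixture()
  pol <- unclass(lex)
  swapped <- polarity_lexicon(names(pol),
                              c(positive = "negative", negative = "positive",
                                neutral = "neutral")[pol])
  set.seed(3)
  vocab <- c(names(pol), "obcy", "inny")
  for (i in 1:20) {
    p <- pnote("n", sample(vocab, 8, replace = TRUE))
    s1 <- dictionary_polarity_score(p, lex)
    s2 <- dictionary_polarity_score(p, swapped)
    expect_equal(s2, -s1)
    l1 <- hybrid_label(s1)
    l2 <- hybrid_label(s2)
    flip <- c(negative = "positive", neutral = "neutral",
              positive = "negative")
    expect_identical(l2, unname(flip[l1]))
  }
})

test_that("hybrid blending follows the stated pseudo-probability rule", {
  expect_identical(hybrid_label(1), "positive")
  expect_identical(hybrid_label(0, c(negative = 0.2, neutral = 0.2,
                                     positive = 0.6), alpha = 0), "positive")
  h <- hybrid_sentiment(-0.5, c(negative = 0.6, neutral = 0.3,
                                positive = 0.1), alpha = 0.5)
  expect_identical(h$label, "negative")
  expect_equal(unname(h$probs["negative"]), 0.55)
  # exact ties go to neutral
  expect_identical(hybrid_label(0), "neutral")
  expect_identical(
    hybrid_label(1, c(negative = 1, neutral = 0, positive = 0), alpha = 0.5),
    "neutral")
})

test_that("blended probabilities are affine in alpha with the stated limits", {
  ml <- c(negative = 0.5, neutral = 0.3, positive = 0.2)
  s <- 0.4
  dict <- c(negative = 0, neutral = 0.6, positive = 0.4)
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    h <- hybrid_sentiment(s, ml, alpha = a)
    expect_equal(h$probs, a * dict + (1 - a) * ml)
  }
  expect_equal(hybrid_sentiment(s, ml, alpha = 1)$probs, dict)
  expect_equal(hybrid_sentiment(s, NULL, alpha = 0.3)$probs, dict)
  expect_equal(hybrid_sentiment(s, NULL, alpha = 0.3)$alpha, 1)
})

test_that("the classifier contract is validated", {
  p <- pnote("n", "cokolwiek")
  expect_equal(unname(classifier_probabilities(p, uniform_sentiment_classifier())),
               rep(1 / 3, 3))
  expect_null(classifier_probabilities(p, NULL))
  registerS3method("sentiment_probs", "broken_classifier",
                   function(model, pnote) c(negative = 0.5, neutral = 0.3,
                                            positive = 0.1),
                   envir = asNamespace("notescope"))
  broken <- structure(list(), class = "broken_classifier")
  expect_error(classifier_probabilities(p, broken), "contract violation")
})

test_that("the reference classifier beats the majority baseline on its training set", {
  cfg <- generator_config(seed = 11)
  lex <- generate_affective_lexicon(cfg)
  gen <- generate_notes(cfg, lexicon = lex)
  pn <- preprocess_notes(gen$notes)
  toks <- unique(unlist(lapply(gen$notes,
                               function(n) notescope:::tokenize_text(n$text))))
  space <- generate_embeddings(lex, cfg, extra_words = toks)
  labels <- unname(gen$truth$sentiment)
  model <- train_sentiment_classifier(pn, labels, space)
  preds <- vapply(pn, function(p) {
    names(which.max(classifier_probabilities(p, model)))
  }, character(1))
  majority <- max(table(labels)) / length(labels)
  expect_gt(mean(preds == labels), majority)
})

test_that("summary counts are conserved", {
  expect_identical(sentiment_summary(c("negative", "negative", "positive")),
                   c(negative = 2L, neutral = 0L, positive = 1L))
  expect_identical(sum(sentiment_summary(character())), 0L)
  res <- analyze_sentiment(list(pnote("a", "dobry"), pnote("b", "zly")),
                           polarity_fixture(), alpha = 1)
  expect_identical(sum(sentiment_summary(res)), nrow(res))
})
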