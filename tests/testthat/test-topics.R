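test_that("the frequency matrix counts term multiplicities per document", {
  pns <- list(pnote("d1", c("a", "a", "b")), pnote("d2", c("b", "b", "b")))
  m <- build_frequency_matrix(pns)
  expect_identical(rownames(m), c("a", "b"))
  expect_identical(colnames(m), c("d1", "d2"))
  expect_equal(unname(m), rbind(c(2, 0), c(1, 3)))
  # column sums equal each note's length
  expect_equal(unname(colSums(m)),
               vapply(pns, `[[`, integer(1), "length_N"),
               ignore_attr = TRUE)
  m1 <- build_frequency_matrix(list(pnote("d", "x")))
  expect_equal(unname(m1), matrix(1))
  expect_error(build_frequency_matrix(list(
    preprocess_note(raw_note("e", "123")))), "empty")
})

test_that("full-rank LSA reconstructs the matrix and orders singular values", {
  set.seed(9)
  m <- matrix(rpois(20 * 10, 2), nrow = 20,
              dimnames = list(paste0("t", 1:20), paste0("d", 1:10)))
  model <- fit_lsa(m, k = 10)
  recon <- model$u %*% t(model$doc_vectors)
  expect_lt(max(abs(recon - m)), 1e-8)
  expect_true(all(diff(model$singular_values) <= 1e-12))
  expect_error(fit_lsa(m, 0), "between")
  expect_error(fit_lsa(m, 11), "between")
})

test_that("a rank-one matrix is reconstructed exactly at k = 1", {
  m <- outer(c(1, 2, 3), c(2, 0, 1))
  dimnames(m) <- list(paste0("t", 1:3), paste0("d", 1:3))
  model <- fit_lsa(m, k = 1)
  expect_lt(max(abs(model$u %*% t(model$doc_vectors) - m)), 1e-8)
})

test_that("fold-in is consistent with fitted document vectors at full rank", {
  set.seed(10)
  m <- matrix(rpois(12 * 6, 3), nrow = 12,
              dimnames = list(paste0("t", 1:12), paste0("d", 1:6)))
  model <- fit_lsa(m, k = 6)
  bag <- rep(rownames(m), m[, "d3"])
  v <- fold_in(bag, model)
  expect_equal(as.numeric(v), unname(model$doc_vectors["d3", ]),
               tolerance = 1e-8)
  # singleton fold-in is the word's row of U
  v1 <- fold_in("t5", model)
  expect_equal(as.numeric(v1), unname(model$u["t5", ]), tolerance = 1e-12)
  # no overlap with the vocabulary -> zero vector, words reported
  v0 <- fold_in(c("zzz", "qqq"), model)
  expect_equal(as.numeric(v0), rep(0, 6))
  expect_identical(sort(attr(v0, "skipped")), c("qqq", "zzz"))
})

test_that("affiliation separates disjoint positive and negative vocabularies", {
  pns <- list(pnote("neg1", c("zle", "okropne", "zle")),
              pnote("neg2", c("okropne", "zle")),
              pnote("pos1", c("dobre", "piekne", "dobre")),
              pnote("pos2", c("piekne", "dobre")))
  dict <- list(positive = c("dobre", "piekne"),
               negative = c("zle", "okropne"))
  m <- build_frequency_matrix(pns)
  model <- fit_lsa(m, k = 4)
  w_neg <- area_affiliation("neg1", model, dict)
  expect_gt(w_neg[["W_N"]], w_neg[["W_P"]])
  w_pos <- area_affiliation("pos1", model, dict)
  expect_gt(w_pos[["W_P"]], w_pos[["W_N"]])
  # note identical to the positive pseudo-document at full rank
  pns2 <- c(pns, list(pnote("same", c("dobre", "piekne"))))
  model2 <- fit_lsa(build_frequency_matrix(pns2), k = 4)
  w_same <- area_affiliation("same", model2, dict)
  expect_equal(w_same[["W_P"]], 1, tolerance = 1e-8)
})

test_that("the relative difference follows its closed form", {
  expect_equal(relative_difference(0.5, 0), 100)
  expect_equal(relative_difference(0, 0.5), -100)
  expect_equal(relative_difference(0.6, 0.5), 100 / 6, tolerance = 1e-12)
  expect_equal(relative_difference(0.3, 0.3), 0)
  expect_error(relative_difference(0, 0), "undefined")
})

test_that("relative difference is bounded and antisymmetric", {
  set.seed(12)
  for (i in 1:200) {
    a <- runif(1)
    b <- runif(1)
    if (max(a, b) == 0) next
    rd <- relative_difference(a, b)
    expect_gte(rd, -100)
    expect_lte(rd, 100)
    expect_equal(relative_difference(b, a), -rd)
  }
})

test_that("context classification is total, four-valued and scale-free", {
  expect_identical(classify_context(0, 0), "not_covered")
  expect_identical(classify_context(0.6, 0.1), "negative")
  expect_identical(classify_context(0.1, 0.6), "positive")
  expect_identical(classify_context(0.5, 0.5), "mixed")
  # ties at exactly the threshold are mixed (strict "greater than")
  expect_identical(classify_context(1, 0.8), "mixed")
  expect_identical(classify_context(0.8, 1), "mixed")
  expect_error(classify_context(-0.1, 0.5), "nonnegative")
  grid <- expand.grid(W_N = seq(0, 1, 0.1), W_P = seq(0, 1, 0.1))
  labels <- mapply(classify_context, grid$W_N, grid$W_P)
  expect_setequal(unique(labels),
                  c("negative", "positive", "mixed", "not_covered"))
  # scale invariance
  set.seed(13)
  for (i in 1:100) {
    a <- runif(1)
    b <- runif(1)
    cc <- runif(1, 0.01, 50)
    expect_identical(classify_context(cc * a, cc * b),
                     classify_context(a, b))
  }
})

test_that("analyze_topics classifies every note x area pair once", {
  cfg <- generator_config(seed = 21, n_notes = 12,
                          stage_sizes = c(I = 4, II = 4, palliative = 4),
                          sentiment_sizes = c(negative = 4, positive = 4,
                                              neutral = 4))
  gen <- generate_notes(cfg)
  res <- analyze_topics(preprocess_notes(gen$notes),
                        generate_area_dictionaries())
  expect_identical(nrow(res), 12L * 3L)
  expect_true(all(res$W_P >= 0 & res$W_N >= 0))
  expect_true(all(res$context %in% c("negative", "positive", "mixed",
                                     "not_covered")))
  covered <- !is.na(res$rel_diff)
  expect_true(all(abs(res$rel_diff[covered]) <= 100))
})
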