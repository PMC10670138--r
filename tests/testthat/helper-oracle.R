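# Independent brute-force oracle for the neighbour-interpolation formula
# intensity_e = sum_k s_k * w_k. Written as plain loops, sharing no code
# with the package implementation.

oracle_cosine <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))

oracle_dominant <- function(intens) {
  best <- emotions()[1]
  for (e in emotions()) {
    if (intens[[e]] > intens[[best]]) best <- e
  }
  best
}

# lexicon: data frame word + emotion columns (standardized); space: matrix
oracle_extend <- function(word, lexicon, space, n) {
  doms <- character(nrow(lexicon))
  for (i in seq_len(nrow(lexicon))) {
    doms[i] <- oracle_dominant(lexicon[i, emotions()])
  }
  # Stage I: centers over lexicon words in space
  centroids <- list()
  for (e in emotions()) {
    members <- lexicon$word[doms == e & lexicon$word %in% rownames(space)]
    vs <- space[members, , drop = FALSE]
    centroids[[e]] <- colSums(vs) / nrow(vs)
  }
  # Stage II: matched emotion by cosine, first-win ties in canonical order
  best_e <- NULL
  best_s <- -Inf
  for (e in emotions()) {
    s <- oracle_cosine(space[word, ], centroids[[e]])
    if (s > best_s) {
      best_s <- s
      best_e <- e
    }
  }
  # Stage III: n closest same-dominant neighbours, shifted-cosine weights
  pool <- lexicon$word[doms == best_e & lexicon$word %in% rownames(space)]
  sims <- numeric(length(pool))
  for (i in seq_along(pool)) {
    sims[i] <- oracle_cosine(space[pool[i], ], space[word, ])
  }
  ord <- order(-sims, pool, method = "radix")
  keep <- ord[seq_len(min(n, length(pool)))]
  w <- (sims[keep] + 1) / 2
  w <- w / sum(w)
  out <- stats::setNames(numeric(5), emotions())
  for (e in emotions()) {
    acc <- 0
    for (i in seq_along(keep)) {
      s_k <- lexicon[lexicon$word == pool[keep[i]], e]
      acc <- acc + s_k * w[i]
    }
    out[[e]] <- acc
  }
  list(matched = best_e, intensities = out,
       neighbor_intensities = lexicon[match(pool[keep], lexicon$word),
                                      emotions(), drop = FALSE])
}

# random small instance: >=1 word per emotion so centers exist
random_extension_instance <- function(dim = 6) {
  nw <- sample(5:10, 1)
  dom <- c(seq_len(5), sample(5, nw - 5, replace = TRUE))
  m <- matrix(runif(nw * 5, 0, 0.4), nrow = nw,
              dimnames = list(NULL, emotions()))
  m[cbind(seq_len(nw), dom)] <- runif(nw, 0.6, 1)
  words <- paste0("w", letters[seq_len(nw)])
  lex_df <- data.frame(word = words, m, check.names = FALSE)
  vecs <- matrix(rnorm((nw + 1) * dim), ncol = dim)
  rownames(vecs) <- c(words, "query")
  list(lexicon_df = lex_df,
       lexicon = affective_lexicon(lex_df, scale = "standardized"),
       space = embedding_space(vecs),
       n = sample(1:5, 1))
}
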