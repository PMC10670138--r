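# Small in-code fixtures shared across test files.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

write_jsonl_notes <- function(records, path = tempfile(fileext = ".jsonl")) {
  con <- file(path, "w", encoding = "UTF-8")
  for (r in records) writeLines(jsonlite::toJSON(r, auto_unbox = TRUE), con)
  close(con)
  path
}

# tiny standardized lexicon with one clearly dominant emotion per word
toy_lexicon <- function(words, dominants, dom_value = 0.8, other_value = 0.2) {
  m <- matrix(other_value, nrow = length(words), ncol = 5,
              dimnames = list(NULL, emotions()))
  m[cbind(seq_along(words), match(dominants, emotions()))] <- dom_value
  affective_lexicon(data.frame(word = words, m, check.names = FALSE),
                    scale = "standardized")
}

toy_space <- function(words, vectors) {
  m <- do.call(rbind, vectors)
  rownames(m) <- words
  embedding_space(m)
}

pnote <- function(id, tokens) {
  preprocess_note(raw_note(id, paste(tokens, collapse = " ")))
}
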