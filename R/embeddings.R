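# Word-embedding spaces in word2vec text format. Vectors supply the
# "spatial position" used to interpolate emotion intensities for words
# missing from the affective lexicon.

#' Build an embedding space from a matrix
#'
#' @param vectors Numeric matrix, one row per word, rownames = words.
#' @return An `embedding_space` (the matrix with a class attribute; the
#'   embedding dimension is `ncol`).
#' @export
embedding_space <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (is.null(rownames(vectors))) stop("vectors must have word rownames")
  dup <- rownames(vectors)[duplicated(rownames(vectors))]
  if (length(dup)) stop("duplicate word(s) in embedding space: ",
                        paste(unique(dup), collapse = ", "))
  class(vectors) <- c("embedding_space", class(vectors))
  vectors
}

#' Read embeddings in word2vec text format
#'
#' Each line is `word v1 v2 ... vd`; an optional leading header line
#' `count dim` is tolerated. All rows must share one dimension. A duplicate
#' word keeps its first occurrence, with a warning.
#'
#' @param path File path.
#' @return An `embedding_space`.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  # header: exactly two fields, both numeric
  if (length(parts[[1L]]) == 2L &&
      !anyNA(suppressWarnings(as.numeric(parts[[1L]])))) {
    parts <- parts[-1L]
    if (length(parts) == 0L) stop("embedding file has a header but no vectors")
  }
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L) {
    stop("inconsistent embedding dimensions: ",
         paste(sort(unique(dims)), collapse = ", "))
  }
  if (dims[1L] < 1L) stop("embedding rows carry no values")
  words <- vapply(parts, `[[`, character(1), 1L)
  vals <- vapply(parts, function(p) as.numeric(p[-1L]), numeric(dims[1L]))
  if (anyNA(vals)) stop("non-numeric embedding value")
  m <- t(matrix(vals, nrow = dims[1L]))
  rownames(m) <- words
  if (anyDuplicated(words)) {
    warning("duplicate word(s) in embedding file; keeping first occurrence")
    m <- m[!duplicated(words), , drop = FALSE]
  }
  embedding_space(m)
}

#' Write embeddings in word2vec text format
#'
#' @param space An `embedding_space`.
#' @param path Output file.
#' @param header Emit the `count dim` header line (default `TRUE`).
#' @export
write_embeddings <- function(space, path, header = TRUE) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (header) writeLines(paste(nrow(space), ncol(space)), con)
  for (i in seq_len(nrow(space))) {
    writeLines(paste(rownames(space)[i],
                     paste(formatC(space[i, ], format = "g", digits = 17),
                           collapse = " ")), con)
  }
  invisible(path)
}

# cosine of one query vector against each row of a matrix; zero-norm rows
# or query give NA
cosine_to_rows <- function(m, v) {
  nv <- sqrt(sum(v^2))
  nr <- sqrt(rowSums(m^2))
  sims <- as.vector(m %*% v) / (nr * nv)
  sims[nr == 0 | nv == 0] <- NA_real_
  sims
}
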