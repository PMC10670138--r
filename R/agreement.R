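# Scoring predicted note x area contexts against expert flags
# (0 topic not raised, -1 negative, 1 positive, 2 mixed context).

flag_to_label <- function(flag) {
  lab <- c(`0` = "not_covered", `-1` = "negative", `1` = "positive",
           `2` = "mixed")[as.character(flag)]
  if (anyNA(lab)) stop("expert flags must be in {0, -1, 1, 2}")
  unname(lab)
}

#' Read expert flags from CSV
#'
#' Columns `note_id`, `area`, `flag` with flag in 0/-1/1/2.
#'
#' @param path CSV file.
#' @return Data frame of flags.
#' @export
read_expert_flags <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("note_id", "area", "flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("flag file missing column(s): ", paste(miss, collapse = ", "))
  flag_to_label(df$flag) # validates values
  df[, need]
}

#' Expert flags of a note collection
#'
#' Collects the per-note flag maps carried by [raw_note()] objects into
#' the long format used by [evaluate_agreement()].
#'
#' @param notes List of [raw_note()] objects.
#' @return Data frame `note_id`, `area`, `flag` (notes without flags are
#'   omitted).
#' @export
notes_expert_flags <- function(notes) {
  rows <- list()
  for (n in notes) {
    for (a in names(n$flags)) {
      rows[[length(rows) + 1L]] <-
        data.frame(note_id = n$id, area = a, flag = as.integer(n$flags[[a]]))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(note_id = character(), area = character(),
                      flag = integer()))
  }
  do.call(rbind, rows)
}

#' Agreement between predicted contexts and expert flags
#'
#' Every prediction is placed in exactly one of four categories:
#' `consistent` (label match after mapping flags to labels),
#' `mixed_detected_as_single` (expert says mixed, method says negative or
#' positive), `single_detected_as_mixed` (expert says negative or
#' positive, method says mixed), and `error` (every remaining mismatch).
#' Percentages are over the notes of each area and sum to 100. The report
#' also gives the expert's context shares among flagged notes (flag != 0).
#'
#' @param predicted Data frame with `note_id`, `area`, `context`
#'   ([analyze_topics()] output).
#' @param flags Data frame with `note_id`, `area`, `flag`; a flag must
#'   exist for every predicted pair.
#' @return An `agreement_report`: list with `per_area` (data frame of n
#'   and the four percentages), `expert_shares` (per-area shares of
#'   negative/positive/mixed among flagged notes), and `detail` (row-level
#'   categories).
#' @export
evaluate_agreement <- function(predicted, flags) {
  key_p <- paste(predicted$note_id, predicted$area, sep = "\r")
  key_f <- paste(flags$note_id, flags$area, sep = "\r")
  idx <- match(key_p, key_f)
  if (anyNA(idx)) {
    miss <- predicted[is.na(idx), c("note_id", "area")]
    stop("missing expert flag for: ",
         paste(paste0(miss$note_id, "/", miss$area), collapse = ", "))
  }
  expert <- flag_to_label(flags$flag[idx])
  pred <- predicted$context
  category <- ifelse(pred == expert, "consistent",
              ifelse(expert == "mixed" & pred %in% c("negative", "positive"),
                     "mixed_detected_as_single",
              ifelse(expert %in% c("negative", "positive") & pred == "mixed",
                     "single_detected_as_mixed", "error")))
  detail <- data.frame(note_id = predicted$note_id, area = predicted$area,
                       predicted = pred, expert = expert, category = category)
  cats <- c("consistent", "error", "mixed_detected_as_single",
            "single_detected_as_mixed")
  per_area <- do.call(rbind, lapply(split(detail, detail$area), function(d) {
    tab <- table(factor(d$category, levels = cats))
    data.frame(area = d$area[1L], n_notes = nrow(d),
               pct_consistent = 100 * tab[["consistent"]] / nrow(d),
               pct_error = 100 * tab[["error"]] / nrow(d),
               pct_mixed_detected_as_single =
                 100 * tab[["mixed_detected_as_single"]] / nrow(d),
               pct_single_detected_as_mixed =
                 100 * tab[["single_detected_as_mixed"]] / nrow(d),
               row.names = NULL)
  }))
  rownames(per_area) <- NULL
  shares <- do.call(rbind, lapply(split(detail, detail$area), function(d) {
    flagged <- d$expert[d$expert != "not_covered"]
    tab <- table(factor(flagged, levels = c("negative", "positive", "mixed")))
    n <- length(flagged)
    data.frame(area = d$area[1L], n_flagged = n,
               pct_negative = if (n) 100 * tab[["negative"]] / n else NA_real_,
               pct_positive = if (n) 100 * tab[["positive"]] / n else NA_real_,
               pct_mixed = if (n) 100 * tab[["mixed"]] / n else NA_real_,
               row.names = NULL)
  }))
  rownames(shares) <- NULL
  structure(list(per_area = per_area, expert_shares = shares, detail = detail),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  print(x$per_area, ...)
  invisible(x)
}
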