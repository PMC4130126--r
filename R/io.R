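# Flat-file interfaces. All writers prepend a '#' comment line flagging the
# content as synthetic and non-clinical; readers skip '#' lines.

#' Read and write the package's CSV interchange files
#'
#' Weights: `participant_id, attribute_id, points`. Ratings:
#' `participant_id, option_id, attribute_id, rating`. Questionnaire:
#' `participant_id, instrument, item_index, value`. Fixations:
#' `participant_id, page_id, start_ms, duration_ms, x, y` (extra columns
#' such as `participant_id`/`page_id` are optional on input). Raw gaze:
#' `participant_id, page_id, t_ms, x, y, valid`. Lines starting with `#` are
#' treated as comments.
#'
#' @param path File path.
#' @param data Data frame to write.
#' @param header_note Comment written as the first line.
#' @return `read_dcida_csv()` returns a data frame; `write_dcida_csv()`
#'   returns `path` invisibly.
#' @export
read_dcida_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_dcida_csv
#' @export
write_dcida_csv <- function(data, path,
                            header_note = "synthetic, non-clinical example data") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_note), con)
  utils::write.csv(data, con, row.names = FALSE)
  invisible(path)
}

#' Rebuild elicitation objects from interchange tables
#'
#' `allocation_from_table()` turns one participant's rows of a weights table
#' into a [weight_allocation()]; `sheet_from_table()` turns rating rows into
#' a [rating_sheet()]; `questionnaire_scores()` scores every participant's
#' SUS and DCS-uncertainty items in a questionnaire table.
#'
#' @param problem A [decision_problem()].
#' @param weights_table,ratings_table,questionnaire_table Data frames in the
#'   formats of [read_dcida_csv()].
#' @param participant_id Participant to extract; default the first present.
#' @param integer Integer-mode flag passed to [weight_allocation()].
#' @return An allocation, a rating sheet, or a data frame
#'   `participant_id, instrument, score`.
#' @export
allocation_from_table <- function(problem, weights_table,
                                  participant_id = weights_table$participant_id[1],
                                  integer = TRUE) {
  rows <- weights_table[weights_table$participant_id == participant_id, ]
  w <- stats::setNames(rows$points, rows$attribute_id)
  weight_allocation(problem, w, budget = sum(w), integer = integer)
}

#' @rdname allocation_from_table
#' @export
sheet_from_table <- function(problem, ratings_table,
                             participant_id = ratings_table$participant_id[1]) {
  rows <- ratings_table[ratings_table$participant_id == participant_id, ]
  rating_sheet(problem, rows[, c("option_id", "attribute_id", "rating")])
}

#' @rdname allocation_from_table
#' @export
questionnaire_scores <- function(questionnaire_table) {
  out <- list()
  for (pid in unique(questionnaire_table$participant_id)) {
    rows <- questionnaire_table[questionnaire_table$participant_id == pid, ]
    for (inst in unique(rows$instrument)) {
      items <- rows[rows$instrument == inst, ]
      items <- items$value[order(items$item_index)]
      score <- switch(inst,
        sus = sus_score(items),
        dcs_uncertainty = dcs_uncertainty(items),
        stop("unknown instrument: ", inst, call. = FALSE))
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, instrument = inst, score = score,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
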