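#' Construct an attribute of a decision problem
#'
#' An attribute is one consequence of a treatment choice (a benefit, harm,
#' inconvenience, cost, ...) on which every option is scored. `direction`
#' records whether higher underlying outcomes are desirable (`"benefit"`) or
#' undesirable (`"harm"`); it is authored metadata, never inferred, so the
#' scoring direction is always unambiguous. Risk-type attributes may carry a
#' per-option `event_probability` (probability of the adverse or beneficial
#' event occurring), which the bias simulator distorts through the
#' probability-weighting function.
#'
#' @param id Short unique string key.
#' @param label Display text.
#' @param direction `"benefit"` or `"harm"`.
#' @param description Text shown in the detail step.
#' @param event_probability Optional named numeric vector (names are option
#'   ids) of event probabilities in `[0, 1]`.
#' @param document_order Integer position of the attribute in the authored
#'   (conventional) decision aid. Defaults to the authoring sequence when the
#'   problem is assembled.
#' @return A list of class `"dcida_attribute"`.
#' @seealso [decision_problem()]
#' @export
attribute <- function(id, label, direction = c("benefit", "harm"),
                      description = "", event_probability = NULL,
                      document_order = NA_integer_) {
  direction <- match.arg(direction)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.null(event_probability)) {
    stopifnot(is.numeric(event_probability), !is.null(names(event_probability)))
  }
  structure(
    list(id = id, label = as.character(label), direction = direction,
         description = as.character(description),
         event_probability = event_probability,
         document_order = as.integer(document_order)),
    class = "dcida_attribute")
}

#' Construct a decision problem
#'
#' A decision problem is the substrate of every computation in the package:
#' two or more medically appropriate options crossed with the attributes on
#' which they differ, plus a free-text narrative describing the condition.
#'
#' @param title Problem title.
#' @param options A data frame with columns `id` and `label`, one row per
#'   treatment option, or a list of `list(id=, label=)` entries.
#' @param attributes A list of [attribute()] objects.
#' @param narrative Free-text condition description.
#' @return A list of class `"decision_problem"`. Construction validates all
#'   invariants and stops on violation; use [validate_problem()] to collect
#'   findings without stopping.
#' @examples
#' p <- decision_problem(
#'   "Example",
#'   options = data.frame(id = c("a", "b"), label = c("A", "B")),
#'   attributes = list(attribute("x", "X", "benefit"),
#'                     attribute("y", "Y", "harm")))
#' option_ids(p)
#' @export
decision_problem <- function(title, options, attributes, narrative = "") {
  if (is.data.frame(options)) {
    opts <- data.frame(id = as.character(options$id),
                       label = as.character(options$label),
                       stringsAsFactors = FALSE)
  } else {
    opts <- data.frame(id = vapply(options, function(o) o$id, ""),
                       label = vapply(options, function(o) o$label, ""),
                       stringsAsFactors = FALSE)
  }
  attrs <- lapply(attributes, function(a) {
    if (!inherits(a, "dcida_attribute")) {
      a <- attribute(a$id, a$label, a$direction,
                     description = if (is.null(a$description)) "" else a$description,
                     event_probability = a$event_probability,
                     document_order = if (is.null(a$document_order)) NA_integer_ else a$document_order)
    }
    a
  })
  # document_order defaults to authoring sequence
  ord <- vapply(attrs, function(a) a$document_order, integer(1))
  if (all(is.na(ord))) {
    for (i in seq_along(attrs)) attrs[[i]]$document_order <- i
  }
  problem <- structure(
    list(title = as.character(title), options = opts, attributes = attrs,
         narrative = as.character(narrative)),
    class = "decision_problem")
  rep_ <- validate_problem(problem)
  if (nrow(rep_) > 0L) {
    stop("invalid decision problem:\n  ",
         paste(rep_$message, collapse = "\n  "), call. = FALSE)
  }
  problem
}

#' @export
print.decision_problem <- function(x, ...) {
  cat("Decision problem: ", x$title, "\n", sep = "")
  cat("  options:    ", paste(x$options$label, collapse = ", "), "\n", sep = "")
  cat("  attributes: ", paste(attribute_ids(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Accessors for decision problems
#'
#' `option_ids()` and `attribute_ids()` return the id keys; `document_order()`
#' returns the authored position of each attribute, named by attribute id.
#'
#' @param problem A [decision_problem()].
#' @return Character or named integer vector.
#' @export
option_ids <- function(problem) problem$options$id

#' @rdname option_ids
#' @export
attribute_ids <- function(problem) {
  vapply(problem$attributes, function(a) a$id, "")
}

#' @rdname option_ids
#' @export
document_order <- function(problem) {
  stats::setNames(vapply(problem$attributes, function(a) a$document_order,
                         integer(1)),
                  attribute_ids(problem))
}

#' Validate a decision problem
#'
#' Checks every structural invariant and returns the findings as data rather
#' than raising: at least two options and one attribute, unique ids, valid
#' directions, event probabilities in `[0, 1]` referring to existing options,
#' and `document_order` forming a permutation of `1..n_attributes`. The input
#' is never mutated and repeated calls yield identical reports.
#'
#' @param problem A candidate decision problem (need not be valid).
#' @return A data frame of class `"validation_report"` with columns `code` and
#'   `message`; zero rows iff all invariants hold.
#' @export
validate_problem <- function(problem) {
  findings <- list()
  add <- function(code, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      code = code, message = message, stringsAsFactors = FALSE)
  }

  opts <- problem$options
  if (is.null(opts) || nrow(opts) == 0L) {
    add("no_options", "problem has no options")
  } else {
    if (nrow(opts) < 2L)
      add("too_few_options", "at least two options are required")
    dup <- unique(opts$id[duplicated(opts$id)])
    for (d in dup) add("duplicate_option_id", paste0("duplicate option id: ", d))
  }

  attrs <- problem$attributes
  if (is.null(attrs) || length(attrs) == 0L) {
    add("no_attributes", "problem has no attributes")
  } else {
    ids <- vapply(attrs, function(a) a$id, "")
    dup <- unique(ids[duplicated(ids)])
    for (d in dup) add("duplicate_attribute_id", paste0("duplicate attribute id: ", d))
    for (a in attrs) {
      if (!a$direction %in% c("benefit", "harm"))
        add("bad_direction", paste0("attribute ", a$id, ": direction must be benefit or harm"))
      if (!is.null(a$event_probability)) {
        p <- a$event_probability
        if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
          add("probability_out_of_range",
              paste0("attribute ", a$id, ": event probability out of range [0,1]"))
        bad <- setdiff(names(p), opts$id)
        for (b in bad)
          add("unknown_option_ref",
              paste0("attribute ", a$id, ": event probability refers to unknown option ", b))
      }
    }
    ord <- vapply(attrs, function(a) a$document_order, integer(1))
    if (anyNA(ord) || !identical(sort(ord), seq_along(attrs)))
      add("document_order_not_permutation",
          paste0("document_order (", paste(ord, collapse = ","),
                 ") is not a permutation of 1..", length(attrs)))
  }

  rep_ <- if (length(findings)) do.call(rbind, findings) else
    data.frame(code = character(), message = character(), stringsAsFactors = FALSE)
  class(rep_) <- c("validation_report", "data.frame")
  rep_
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("validation: ok (no findings)\n")
  else {
    cat("validation: ", nrow(x), " finding(s)\n", sep = "")
    for (i in seq_len(nrow(x))) cat("  - ", x$message[i], "\n", sep = "")
  }
  invisible(x)
}

# serializable list form of a problem (canonical key order, snake_case)
problem_to_list <- function(problem) {
  list(
    dcida_spec_version = "1.0",
    title = problem$title,
    narrative = problem$narrative,
    options = lapply(seq_len(nrow(problem$options)), function(i)
      list(id = problem$options$id[i], label = problem$options$label[i])),
    attributes = lapply(problem$attributes, function(a) {
      out <- list(id = a$id, label = a$label, direction = a$direction,
                  description = a$description,
                  document_order = a$document_order)
      if (!is.null(a$event_probability))
        out$event_probability <- as.list(a$event_probability)
      out
    }))
}

problem_from_list <- function(x) {
  if (is.null(x$options) || is.null(x$attributes))
    stop("problem file must contain 'options' and 'attributes'", call. = FALSE)
  attrs <- lapply(x$attributes, function(a) {
    ep <- NULL
    if (!is.null(a$event_probability))
      ep <- unlist(a$event_probability)
    attribute(a$id, a$label, a$direction,
              description = if (is.null(a$description)) "" else a$description,
              event_probability = ep,
              document_order = if (is.null(a$document_order)) NA_integer_
                               else as.integer(a$document_order))
  })
  decision_problem(
    title = if (is.null(x$title)) "" else x$title,
    options = x$options,
    attributes = attrs,
    narrative = if (is.null(x$narrative)) "" else x$narrative)
}

#' Read and write decision-problem files
#'
#' The canonical file dialect is JSON with snake_case keys and a top-level
#' `dcida_spec_version`; YAML files with the same structure are accepted on
#' input (chosen by file extension `.yaml`/`.yml`). A JSON Schema for the
#' dialect ships in `system.file("schema", "decision_problem.schema.json",
#' package = "dcida")`. `load_problem()` followed by `save_problem()` is the
#' identity on the canonical dialect.
#'
#' @param path File path.
#' @param problem A [decision_problem()].
#' @return `load_problem()` returns a validated [decision_problem()];
#'   `save_problem()` returns `path` invisibly.
#' @export
load_problem <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  is_yaml <- grepl("\\.ya?ml$", path, ignore.case = TRUE)
  x <- tryCatch(
    if (is_yaml) yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!is_yaml && !is.null(x$options) && is.data.frame(x$options)) {
    # not reachable with simplifyVector = FALSE; defensive
    x$options <- split(x$options, seq_len(nrow(x$options)))
  }
  prob <- tryCatch(problem_from_list(x), error = function(e)
    stop("invalid problem in ", path, ": ", conditionMessage(e), call. = FALSE))
  prob
}

#' @rdname load_problem
#' @export
save_problem <- function(problem, path) {
  stopifnot(inherits(problem, "decision_problem"))
  jsonlite::write_json(problem_to_list(problem), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
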