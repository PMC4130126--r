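# Largest-remainder apportionment of `total` integer points proportional to
# `raw` (non-negative, may be fractional). Ties on fractional part go to the
# earliest entry, keeping the operation deterministic.
largest_remainder <- function(raw, total) {
  if (length(raw) == 0L) return(raw)
  stopifnot(all(raw >= -1e-12), abs(total - round(total)) < 1e-9)
  total <- round(total)
  s <- sum(raw)
  share <- if (s > 0) raw / s * total else rep(total / length(raw), length(raw))
  base <- floor(share + 1e-9)
  left <- total - sum(base)
  if (left > 0) {
    frac <- share - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  base
}

#' Create a budget-pie weight allocation
#'
#' The value-clarification step asks the user to allocate a fixed budget of
#' points (typically 100) across the problem's attributes in proportion to
#' their importance, via sliders linked to a constrained pie chart. A
#' `weight_allocation` holds that state. Entries are stored in the problem's
#' `document_order` sequence, which also serves as the deterministic tie-break
#' for [rank_attributes()]. Allocations are immutable: [set_weight()] returns
#' a new allocation, so a session can keep a revision history.
#'
#' @param problem A [decision_problem()].
#' @param weights Optional named numeric vector of initial points (must cover
#'   every attribute and sum to `budget`); default is a uniform split.
#' @param budget Total points to allocate (default 100).
#' @param integer If `TRUE` (default) weights are whole points and every
#'   redistribution uses largest-remainder rounding so the sum stays exact;
#'   if `FALSE` weights are fractional and conservation holds to 1e-9.
#' @return A list of class `"weight_allocation"` with fields `budget`,
#'   `weights` (named, in document order) and `integer`.
#' @export
weight_allocation <- function(problem, weights = NULL, budget = 100,
                              integer = TRUE) {
  stopifnot(inherits(problem, "decision_problem"), budget > 0)
  ids <- attribute_ids(problem)[order(document_order(problem))]
  if (is.null(weights)) {
    w <- if (integer) largest_remainder(rep(1, length(ids)), budget)
         else rep(budget / length(ids), length(ids))
    weights <- stats::setNames(w, ids)
  } else {
    missing_ids <- setdiff(ids, names(weights))
    if (length(missing_ids))
      stop("weights missing for attribute(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    weights <- weights[ids]
  }
  alloc <- structure(list(budget = budget,
                          weights = stats::setNames(as.numeric(weights), ids),
                          integer = isTRUE(integer)),
                     class = "weight_allocation")
  check_allocation(alloc)
  alloc
}

check_allocation <- function(allocation) {
  w <- allocation$weights
  if (any(w < -1e-12)) stop("weights must be non-negative", call. = FALSE)
  tol <- if (allocation$integer) 1e-9 else 1e-9
  if (abs(sum(w) - allocation$budget) > tol)
    stop("weights must sum to the budget (", allocation$budget,
         "), got ", sum(w), call. = FALSE)
  if (allocation$integer && any(abs(w - round(w)) > 1e-9))
    stop("integer-mode weights must be whole points", call. = FALSE)
  invisible(allocation)
}

#' @export
print.weight_allocation <- function(x, ...) {
  cat("Weight allocation (budget ", x$budget,
      if (x$integer) ", integer points" else ", fractional", "):\n", sep = "")
  print(x$weights)
  invisible(x)
}

#' Move one slider of the budget pie
#'
#' Sets one attribute's weight and redistributes the remaining budget over the
#' other attributes in proportion to their prior weights, mirroring the linked
#' sliders of the constrained pie chart: relative judgments among untouched
#' attributes are preserved. When the untouched attributes all hold zero
#' points, the pool is split uniformly among them. In integer mode the
#' redistribution is rounded by the largest-remainder method so the budget is
#' conserved exactly.
#'
#' @param allocation A [weight_allocation()]; not modified.
#' @param attribute Attribute id whose slider moved.
#' @param new_value New point value in `[0, budget]` (whole number in integer
#'   mode).
#' @return A new `weight_allocation` with the budget conserved.
#' @examples
#' p <- decision_problem("ex",
#'   data.frame(id = c("a", "b"), label = c("A", "B")),
#'   list(attribute("x", "X", "benefit"), attribute("y", "Y", "harm"),
#'        attribute("z", "Z", "harm")))
#' a <- weight_allocation(p, c(x = 50, y = 30, z = 20))
#' set_weight(a, "x", 20)$weights  # pool 80 split 30:20 -> 48, 32
#' @export
set_weight <- function(allocation, attribute, new_value) {
  stopifnot(inherits(allocation, "weight_allocation"))
  w <- allocation$weights
  if (!attribute %in% names(w))
    stop("unknown attribute: ", attribute, call. = FALSE)
  if (!is.finite(new_value) || new_value < 0 || new_value > allocation$budget)
    stop("new value must lie in [0, ", allocation$budget, "]", call. = FALSE)
  if (allocation$integer && abs(new_value - round(new_value)) > 1e-9)
    stop("integer-mode allocation requires whole points", call. = FALSE)

  others <- setdiff(names(w), attribute)
  pool <- allocation$budget - new_value
  prior <- w[others]
  raw <- if (length(others) == 0L) numeric(0)
         else if (sum(prior) > 0) pool * prior / sum(prior)
         else rep(pool / length(others), length(others))
  if (allocation$integer) raw <- largest_remainder(raw, pool)
  w[attribute] <- new_value
  w[others] <- raw
  out <- allocation
  out$weights <- w
  check_allocation(out)
  out
}

#' Rank attributes by allocated weight
#'
#' Orders attribute ids by descending weight; ties are broken by ascending
#' `document_order` (the order in which the allocation stores its entries),
#' so the result is stable and deterministic.
#'
#' @param allocation A [weight_allocation()].
#' @return Character vector of attribute ids, most important first.
#' @export
rank_attributes <- function(allocation) {
  stopifnot(inherits(allocation, "weight_allocation"))
  w <- allocation$weights
  names(w)[order(-w, seq_along(w))]
}

#' Map a 5-point rating to a 0-100 score
#'
#' The detail step collects a rating on a simple 5-point scale for each
#' option-attribute pair; the MCDA engine works on 0-100 scores. The map is
#' linear with anchors 1 -> 0 and 5 -> 100 (so 2 -> 25, 3 -> 50, 4 -> 75),
#' the minimal assumption given only the two scales; it is isolated here so
#' an alternative map can be swapped in.
#'
#' @param rating Integer(s) in `{1, ..., 5}`.
#' @return Numeric score(s) in `[0, 100]`.
#' @export
rating_to_score <- function(rating) {
  if (any(!is.finite(rating)) || any(!rating %in% 1:5))
    stop("ratings must be integers in 1..5", call. = FALSE)
  (as.numeric(rating) - 1) * 25
}

#' Assemble a rating sheet
#'
#' A rating sheet is the complete set of step-2 responses: one integer in
#' 1..5 per (option, attribute) pair. For harm attributes the rating wording
#' asks for the desirability of that option's harm profile (higher = more
#' preferred), so no sign flip is applied downstream; direction handling
#' lives in the data-entry contract.
#'
#' @param problem A [decision_problem()].
#' @param ratings Either a numeric matrix with rownames = option ids and
#'   colnames = attribute ids, or a data frame with columns `option_id`,
#'   `attribute_id`, `rating`.
#' @return A matrix of class `"rating_sheet"` (options x attributes).
#' @export
rating_sheet <- function(problem, ratings) {
  opts <- option_ids(problem)
  attrs <- attribute_ids(problem)
  m <- matrix(NA_real_, nrow = length(opts), ncol = length(attrs),
              dimnames = list(opts, attrs))
  if (is.data.frame(ratings)) {
    for (i in seq_len(nrow(ratings))) {
      o <- as.character(ratings$option_id[i])
      a <- as.character(ratings$attribute_id[i])
      if (!o %in% opts || !a %in% attrs)
        stop("rating refers to unknown pair (", o, ", ", a, ")", call. = FALSE)
      m[o, a] <- ratings$rating[i]
    }
  } else {
    ratings <- as.matrix(ratings)
    m[rownames(ratings), colnames(ratings)] <- ratings
  }
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss) > 0L)
    stop("missing rating for (", opts[miss[1, 1]], ", ", attrs[miss[1, 2]], ")",
         call. = FALSE)
  if (any(!m %in% 1:5))
    stop("ratings must be integers in 1..5", call. = FALSE)
  structure(m, class = c("rating_sheet", class(m)))
}

#' Build the 0-100 score matrix from a rating sheet
#'
#' Applies [rating_to_score()] cell-wise to a complete rating sheet.
#'
#' @param problem A [decision_problem()].
#' @param sheet A [rating_sheet()] (or matrix acceptable to it).
#' @return A numeric options x attributes matrix of class `"score_matrix"`
#'   with values in `[0, 100]`.
#' @export
build_score_matrix <- function(problem, sheet) {
  if (!inherits(sheet, "rating_sheet")) sheet <- rating_sheet(problem, sheet)
  s <- matrix(rating_to_score(as.vector(sheet)),
              nrow = nrow(sheet), dimnames = dimnames(sheet))
  structure(s, class = c("score_matrix", class(s)))
}
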