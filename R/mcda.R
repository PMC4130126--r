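#' Weighted-additive option totals and the default option
#'
#' The core of the tool: each option's total is the weight-weighted sum of its
#' attribute scores, `total(o) = sum_a w_a * s[o, a] / budget`, which places
#' totals on the same 0-100 scale as the scores (the raw weighted sum, up to
#' budget x 100, is recovered by multiplying by the budget). The option with
#' the highest total becomes the pre-selected default shown in the summary.
#' Ties are resolved to the option appearing earliest in the problem's option
#' order and flagged in the result so a front-end can disclose them.
#'
#' @param allocation A [weight_allocation()].
#' @param matrix A [build_score_matrix()] result (options x attributes, values
#'   in `[0, 100]`).
#' @return A list of class `"option_totals"`: `totals` (named numeric, in
#'   `[0, 100]`), `default_option`, `tie` (logical).
#' @examples
#' p <- decision_problem("ex",
#'   data.frame(id = c("o1", "o2"), label = c("O1", "O2")),
#'   list(attribute("a", "A", "benefit"), attribute("b", "B", "harm")))
#' w <- weight_allocation(p, c(a = 60, b = 40))
#' s <- matrix(c(100, 50, 0, 100), 2, dimnames = list(c("o1", "o2"), c("a", "b")))
#' total_scores(w, s)$totals  # o1 60, o2 70
#' @export
total_scores <- function(allocation, matrix) {
  stopifnot(inherits(allocation, "weight_allocation"))
  w <- allocation$weights
  if (!setequal(colnames(matrix), names(w)))
    stop("attribute sets of allocation and score matrix differ", call. = FALSE)
  s <- matrix[, names(w), drop = FALSE]
  if (any(s < -1e-9) || any(s > 100 + 1e-9))
    stop("scores must lie in [0, 100]", call. = FALSE)
  totals <- as.vector(s %*% w) / allocation$budget
  names(totals) <- rownames(matrix)
  best <- max(totals)
  maximizers <- which(totals >= best - 1e-9)
  structure(list(totals = totals,
                 default_option = names(totals)[maximizers[1L]],
                 tie = length(maximizers) > 1L),
            class = "option_totals")
}

#' @export
print.option_totals <- function(x, ...) {
  cat("Option totals (0-100):\n")
  print(round(x$totals, 2))
  cat("default option: ", x$default_option,
      if (x$tie) " (tie)" else "", "\n", sep = "")
  invisible(x)
}

#' Serialize option totals to JSON
#'
#' @param totals An `"option_totals"` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON text (invisibly, when writing to a file).
#' @export
totals_to_json <- function(totals, path = NULL) {
  x <- list(totals = as.list(totals$totals),
            default_option = totals$default_option, tie = totals$tie)
  if (is.null(path)) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  else invisible(jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA))
}

#' Minimal weight shift that flips the default option
#'
#' For each attribute, finds the smallest change of that attribute's slider
#' (with the freed or consumed budget redistributed proportionally over the
#' other attributes, exactly as [set_weight()] does in fractional mode) that
#' changes the default option, or `NA` when no value in `[0, budget]` flips
#' it. Because every option's total is linear in the moved weight under
#' proportional redistribution, the flip points are found analytically as
#' pairwise crossings with the incumbent default.
#'
#' Used to probe how stable the pre-selected default is to the user revising
#' one judgment.
#'
#' @inheritParams total_scores
#' @return Named numeric vector (one entry per attribute): minimal
#'   perturbation in points, or `NA` if the default can never flip by moving
#'   that slider alone.
#' @export
sensitivity_to_default <- function(allocation, matrix) {
  stopifnot(inherits(allocation, "weight_allocation"))
  w0 <- allocation$weights
  budget <- allocation$budget
  s <- matrix[rownames(matrix), names(w0), drop = FALSE]
  if (nrow(s) < 2L) stop("at least two options required", call. = FALSE)
  incumbent <- total_scores(allocation, matrix)$default_option

  out <- stats::setNames(rep(NA_real_, length(w0)), names(w0))
  for (a in names(w0)) {
    others <- setdiff(names(w0), a)
    W <- sum(w0[others])
    # total_o(v) = (v * s[o,a] + (budget - v) * M_o) / budget, linear in v,
    # where M_o is the proportionally-redistributed mean of the other scores
    # (uniform fallback when the others hold zero weight).
    M <- if (W > 0) as.vector(s[, others, drop = FALSE] %*% w0[others]) / W
         else rowMeans(s[, others, drop = FALSE])
    slope <- (s[, a] - M) / budget
    intercept <- M
    names(slope) <- names(intercept) <- rownames(s)

    v0 <- w0[[a]]
    best <- NA_real_
    for (o in setdiff(rownames(s), incumbent)) {
      dslope <- slope[[o]] - slope[[incumbent]]
      dint <- intercept[[o]] - intercept[[incumbent]]
      if (abs(dslope) < 1e-15) next  # parallel: never crosses (or always tied)
      cross <- -dint / dslope
      if (cross < -1e-9 || cross > budget + 1e-9) next
      # the challenger overtakes just past the crossing; feasibility of the
      # overtaking side within [0, budget]:
      side_up <- dslope > 0   # o beats incumbent for v > cross
      feasible <- if (side_up) cross < budget - 1e-12 else cross > 1e-12
      if (!feasible) next
      dist <- abs(cross - v0)
      if (is.na(best) || dist < best) best <- dist
    }
    out[[a]] <- best
  }
  out
}
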