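#' Map a 0-100 score to a greyscale luminance
#'
#' Summary cells are shaded so that a lighter grey marks a more preferred
#' option. The map is linear, `luminance = 0.25 + score/100 * 0.70`, with
#' anchors 0.25 (darkest) and 0.95 (lightest) chosen so cell text stays
#' legible at both extremes.
#'
#' @param score Numeric score(s) in `[0, 100]`.
#' @return Luminance value(s) in `[0.25, 0.95]`.
#' @export
score_to_shade <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 100))
    stop("scores must lie in [0, 100]", call. = FALSE)
  0.25 + (score / 100) * 0.70
}

# Water-filling height normalization: raw proportions below `floor` are fixed
# at the floor and the remaining rows are renormalized proportionally; the
# fixed set grows until no free row falls below the floor.
floor_heights <- function(raw, floor) {
  n <- length(raw)
  if (floor * n > 1 + 1e-12)
    stop("height floor ", floor, " infeasible for ", n, " rows", call. = FALSE)
  raw <- raw / sum(raw)
  fixed <- rep(FALSE, n)
  h <- raw
  repeat {
    low <- !fixed & h < floor - 1e-12
    if (!any(low)) break
    fixed <- fixed | low
    h[fixed] <- floor
    free <- !fixed
    if (!any(free)) break
    h[free] <- raw[free] / sum(raw[free]) * (1 - floor * sum(fixed))
  }
  h
}

#' Compose the summary-screen layout
#'
#' The step-3 summary applies three weight-driven transformations to the
#' option x attribute grid: rows are ordered by the rank of the user's
#' weights, sized in proportion to the weights (with a legibility floor), and
#' each cell is shaded by its score via [score_to_shade()]; the MCDA-optimal
#' option is carried through as the pre-selected default. In
#' `mode = "conventional"` the same data render as a plain decision-aid
#' summary: rows in authored `document_order`, uniform heights, no shading
#' and no default — the paired control for the nudged display.
#'
#' Rows below the floor are raised to it and the remaining rows renormalized
#' iteratively (water-filling) so the height fractions always sum to 1.
#' Each row's area-of-interest (AOI) box spans the full width (including the
#' attribute label) and the rows tile the summary region, which occupies the
#' page below a fixed header band (`region_top`), in normalized page
#' coordinates.
#'
#' @param allocation A [weight_allocation()].
#' @param matrix A score matrix (options x attributes, `[0, 100]`).
#' @param totals An `"option_totals"` from [total_scores()]; recomputed when
#'   omitted.
#' @param mode `"dcida"` (nudged) or `"conventional"`.
#' @param floor Minimum height fraction per row (default 0.05).
#' @param region_top Top of the attribute region in normalized page
#'   coordinates (default 0.2; the band above it is header/instructions).
#' @return A list of class `"summary_layout"`: `rows` (data frame with
#'   `attribute_id`, `rank`, `height_fraction`), `scores` and `shades`
#'   matrices in row order, `default_option` (`NA` in conventional mode),
#'   `tie`, `aoi_boxes` (data frame `attribute_id`, `x0`, `x1`, `y0`, `y1`),
#'   `mode`, `region_top`.
#' @export
compute_layout <- function(allocation, matrix, totals = NULL,
                           mode = c("dcida", "conventional"),
                           floor = 0.05, region_top = 0.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(allocation, "weight_allocation"))
  if (is.null(totals)) totals <- total_scores(allocation, matrix)
  w <- allocation$weights
  if (!setequal(colnames(matrix), names(w)))
    stop("attribute sets of allocation and score matrix differ", call. = FALSE)

  if (mode == "dcida") {
    ord <- rank_attributes(allocation)
    h <- floor_heights(w[ord] / allocation$budget, floor)
    default_option <- totals$default_option
    tie <- totals$tie
    shades <- matrix(score_to_shade(as.vector(matrix[, ord, drop = FALSE])),
                     nrow = nrow(matrix),
                     dimnames = list(rownames(matrix), ord))
  } else {
    ord <- names(w)  # allocation stores entries in document order
    h <- rep(1 / length(ord), length(ord))
    default_option <- NA_character_
    tie <- FALSE
    shades <- matrix(NA_real_, nrow = nrow(matrix), ncol = length(ord),
                     dimnames = list(rownames(matrix), ord))
  }

  y0 <- region_top + cumsum(c(0, h[-length(h)])) * (1 - region_top)
  aoi <- data.frame(attribute_id = ord,
                    x0 = 0, x1 = 1,
                    y0 = y0, y1 = y0 + h * (1 - region_top),
                    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(
    rows = data.frame(attribute_id = ord, rank = seq_along(ord),
                      height_fraction = as.numeric(h),
                      stringsAsFactors = FALSE, row.names = NULL),
    scores = matrix[, ord, drop = FALSE],
    shades = shades,
    default_option = default_option, tie = tie,
    aoi_boxes = aoi, mode = mode, region_top = region_top),
    class = "summary_layout")
}

#' @export
print.summary_layout <- function(x, ...) {
  cat("Summary layout (", x$mode, " mode)\n", sep = "")
  print(x$rows)
  if (!is.na(x$default_option))
    cat("default option: ", x$default_option, "\n", sep = "")
  invisible(x)
}

grey_css <- function(luminance) {
  v <- as.integer(round(luminance * 255))
  sprintf("rgb(%d,%d,%d)", v, v, v)
}

#' Render a summary layout as a deterministic HTML document
#'
#' Produces a self-contained HTML page: one table row per attribute with its
#' height as a CSS percentage, greyscale cell backgrounds from the layout's
#' shades (white in conventional mode), and — in nudged mode — the default
#' option both marked visually and pre-selected via a checked radio control,
#' while every option remains selectable. A machine-readable copy of the AOI
#' boxes is embedded as a JSON `<script>` block so gaze analysis can recover
#' the geometry from the page itself. Output is byte-identical across runs
#' for identical inputs.
#'
#' @param layout A [compute_layout()] result.
#' @param problem The matching [decision_problem()].
#' @return A single character string of HTML.
#' @export
render_html <- function(layout, problem) {
  stopifnot(inherits(layout, "summary_layout"),
            inherits(problem, "decision_problem"))
  opts <- problem$options
  labels <- stats::setNames(
    vapply(problem$attributes, function(a) a$label, ""),
    attribute_ids(problem))

  head_cells <- paste0(
    vapply(seq_len(nrow(opts)), function(i) {
      id <- opts$id[i]
      checked <- if (!is.na(layout$default_option) &&
                     identical(id, layout$default_option)) " checked" else ""
      mark <- if (nzchar(checked)) " &#10003; (default)" else ""
      sprintf(paste0("<th><label><input type=\"radio\" name=\"choice\"",
                     " value=\"%s\"%s> %s%s</label></th>"),
              id, checked, opts$label[i], mark)
    }, ""), collapse = "")

  body_rows <- vapply(seq_len(nrow(layout$rows)), function(r) {
    aid <- layout$rows$attribute_id[r]
    hpct <- sprintf("%.4f%%", layout$rows$height_fraction[r] * 100)
    cells <- vapply(opts$id, function(o) {
      sc <- layout$scores[o, aid]
      bg <- if (layout$mode == "dcida") grey_css(layout$shades[o, aid])
            else "rgb(255,255,255)"
      sprintf("<td style=\"background:%s\" data-score=\"%s\">%s</td>",
              bg, format(sc), format(sc))
    }, "")
    sprintf("<tr style=\"height:%s\" data-attribute=\"%s\"><th>%s</th>%s</tr>",
            hpct, aid, labels[[aid]], paste0(cells, collapse = ""))
  }, "")

  aoi_json <- jsonlite::toJSON(layout$aoi_boxes, dataframe = "rows",
                               digits = NA)

  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n<title>",
    problem$title, "</title>\n</head>\n<body>\n",
    "<h1>", problem$title, "</h1>\n",
    "<table style=\"width:100%;height:80%\" data-mode=\"", layout$mode,
    "\">\n<thead><tr><th></th>", head_cells, "</tr></thead>\n<tbody>\n",
    paste0(body_rows, collapse = "\n"), "\n</tbody>\n</table>\n",
    "<script type=\"application/json\" id=\"aoi-boxes\">", aoi_json,
    "</script>\n</body>\n</html>\n")
}
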