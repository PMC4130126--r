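#' Detect fixations from raw gaze samples (I-DT)
#'
#' Dispersion-threshold identification: within each run of valid samples,
#' maximal windows whose dispersion (x-range + y-range) stays within
#' `dispersion_threshold` and whose time span reaches `min_duration_ms`
#' become fixations, reported at the window centroid. During a fixation the
#' eyes remain relatively still for a few hundred milliseconds, which is when
#' information is actually processed; samples between fixations (saccades)
#' are discarded. Invalid samples break windows. Fixation-level logs exported
#' by an eye tracker are the primary input path for the analytics; this
#' detector is a convenience for raw gaze logs.
#'
#' @param samples Data frame with columns `t_ms` (strictly increasing), `x`,
#'   `y` (normalized page coordinates in `[0, 1]`) and optionally `valid`
#'   (logical, default all valid).
#' @param dispersion_threshold Maximum x-range + y-range of a fixation window
#'   in normalized units (default 0.02).
#' @param min_duration_ms Minimum fixation duration (default 100).
#' @return Data frame with columns `start_ms`, `duration_ms`, `x`, `y`, `aoi`
#'   (`NA` until [assign_aoi()] labels it). Empty input gives an empty frame.
#' @export
detect_fixations <- function(samples, dispersion_threshold = 0.02,
                             min_duration_ms = 100) {
  stopifnot(dispersion_threshold > 0, min_duration_ms > 0)
  empty <- data.frame(start_ms = numeric(), duration_ms = numeric(),
                      x = numeric(), y = numeric(), aoi = character(),
                      stringsAsFactors = FALSE)
  if (is.null(samples) || nrow(samples) == 0L) return(empty)
  if (is.null(samples$valid)) samples$valid <- TRUE
  if (any(diff(samples$t_ms) <= 0))
    stop("sample timestamps must be strictly increasing", call. = FALSE)

  out <- list()
  runs <- split(seq_len(nrow(samples)),
                cumsum(c(TRUE, diff(as.integer(samples$valid)) != 0)))
  for (run in runs) {
    if (!samples$valid[run[1L]]) next
    t <- samples$t_ms[run]; x <- samples$x[run]; y <- samples$y[run]
    n <- length(run); i <- 1L
    while (i <= n) {
      j <- i
      xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
      while (j < n) {
        nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
        nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
        if ((nxmax - nxmin) + (nymax - nymin) > dispersion_threshold) break
        j <- j + 1L
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      }
      if (t[j] - t[i] >= min_duration_ms) {
        idx <- i:j
        out[[length(out) + 1L]] <- data.frame(
          start_ms = t[i], duration_ms = t[j] - t[i],
          x = mean(x[idx]), y = mean(y[idx]), aoi = NA_character_,
          stringsAsFactors = FALSE)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Label fixations with the area of interest they fall in
#'
#' Assigns each fixation centroid to an attribute row by point-in-rectangle
#' against the layout's AOI boxes. Rectangles are half-open,
#' `[x0, x1) x [y0, y1)`, so a fixation exactly on a shared row boundary
#' belongs unambiguously to the lower (later) row. Fixations outside every
#' box (e.g. on the page header) are labelled `"other_screen"`.
#'
#' @param fixations Data frame with columns `x`, `y` (and typically
#'   `duration_ms`).
#' @param layout A [compute_layout()] result, or any data frame of boxes with
#'   columns `attribute_id`, `x0`, `x1`, `y0`, `y1`.
#' @return The fixation data frame with its `aoi` column filled.
#' @export
assign_aoi <- function(fixations, layout) {
  boxes <- if (inherits(layout, "summary_layout")) layout$aoi_boxes else layout
  # reject overlapping geometry (shared edges are fine under half-open boxes)
  if (nrow(boxes) > 1L) {
    for (i in seq_len(nrow(boxes) - 1L)) for (j in (i + 1L):nrow(boxes)) {
      eps <- 1e-9
      if (boxes$x0[i] < boxes$x1[j] - eps && boxes$x0[j] < boxes$x1[i] - eps &&
          boxes$y0[i] < boxes$y1[j] - eps && boxes$y0[j] < boxes$y1[i] - eps)
        stop("AOI boxes ", boxes$attribute_id[i], " and ",
             boxes$attribute_id[j], " overlap", call. = FALSE)
    }
  }
  aoi <- rep("other_screen", nrow(fixations))
  for (b in seq_len(nrow(boxes))) {
    hit <- fixations$x >= boxes$x0[b] & fixations$x < boxes$x1[b] &
           fixations$y >= boxes$y0[b] & fixations$y < boxes$y1[b]
    aoi[hit] <- boxes$attribute_id[b]
  }
  fixations$aoi <- aoi
  fixations
}

#' Relative fixation duration by importance rank
#'
#' Summarizes labelled fixations into the four importance buckets used to
#' report deliberation: the most important attribute, the second most
#' important, the least important, and all remaining ("other") attributes,
#' plus time on other areas of the screen. The share of each bucket is its
#' fixation time divided by the total time on attribute rows (time on other
#' areas of the screen is excluded from the denominator), reported to the
#' nearest percent; raw durations are reported in seconds alongside the
#' total including other screen areas.
#'
#' @param fixations Data frame with `duration_ms` and `aoi` filled (see
#'   [assign_aoi()]).
#' @param ranking Attribute ids ordered most important first, covering every
#'   attribute AOI (see [rank_attributes()]).
#' @return A list of class `"relative_fixation_summary"`: `durations_s`
#'   (named: `most_important`, `second`, `least`, `other_attributes`,
#'   `other_screen`), `shares_pct` (named, attribute buckets only),
#'   `total_on_screen_s`, and `undefined` (`TRUE` when there is no
#'   on-attribute time, in which case shares are `NA`).
#' @export
relative_fixation <- function(fixations, ranking) {
  stopifnot(length(ranking) >= 1L)
  on_attr <- setdiff(unique(fixations$aoi), c("other_screen", NA))
  unknown <- setdiff(on_attr, ranking)
  if (length(unknown))
    stop("fixations carry AOI labels outside the ranking: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(ranking)
  bucket_of <- stats::setNames(rep("other_attributes", n), ranking)
  bucket_of[ranking[1L]] <- "most_important"
  if (n >= 2L) bucket_of[ranking[2L]] <- "second"
  if (n >= 3L) bucket_of[ranking[n]] <- "least"

  dur_ms <- function(keys) sum(fixations$duration_ms[fixations$aoi %in% keys])
  buckets <- c("most_important", "second", "least", "other_attributes")
  durations <- vapply(buckets, function(b)
    dur_ms(names(bucket_of)[bucket_of == b]), numeric(1)) / 1000
  other_screen <- dur_ms("other_screen") / 1000
  denom <- sum(durations)

  undefined <- denom <= 0
  if (undefined) {
    shares <- stats::setNames(rep(NA_real_, length(buckets)), buckets)
    warning("no on-attribute fixation time; shares undefined", call. = FALSE)
  } else {
    shares <- round(durations / denom * 100)
  }
  structure(list(
    durations_s = c(durations, other_screen = other_screen),
    shares_pct = shares,
    total_on_screen_s = denom + other_screen,
    undefined = undefined),
    class = "relative_fixation_summary")
}

#' @export
print.relative_fixation_summary <- function(x, ...) {
  cat("Relative fixation (shares over on-attribute time):\n")
  for (b in names(x$shares_pct))
    cat(sprintf("  %-17s %5.1f s  %s\n", b, x$durations_s[[b]],
                if (is.na(x$shares_pct[[b]])) "NA"
                else paste0(x$shares_pct[[b]], "%")))
  cat(sprintf("  %-17s %5.1f s\n", "other_screen", x$durations_s[["other_screen"]]))
  cat(sprintf("  total on screen   %5.1f s\n", x$total_on_screen_s))
  invisible(x)
}

#' Aggregate fixation time on a page into a heatmap grid
#'
#' Divides the unit page into `n_rows` x `n_cols` cells and returns, per
#' cell, the proportion of total fixation time whose centroid falls in the
#' cell — the numeric form of a gaze heatmap. Cells sum to 1 whenever any
#' fixation time exists; with no fixations an all-zero matrix is returned
#' with attribute `empty = TRUE`.
#'
#' @param fixations Data frame with `x`, `y`, `duration_ms`.
#' @param n_rows,n_cols Grid dimensions (>= 1). Rows index `y` from the top
#'   of the page, columns index `x` from the left.
#' @return Numeric `n_rows` x `n_cols` matrix of time proportions.
#' @export
heatmap_grid <- function(fixations, n_rows, n_cols) {
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  m <- matrix(0, n_rows, n_cols)
  total <- sum(fixations$duration_ms)
  if (is.null(fixations) || nrow(fixations) == 0L || total <= 0) {
    attr(m, "empty") <- TRUE
    return(m)
  }
  row <- pmin(pmax(floor(fixations$y * n_rows) + 1L, 1L), n_rows)
  col <- pmin(pmax(floor(fixations$x * n_cols) + 1L, 1L), n_cols)
  for (i in seq_len(nrow(fixations)))
    m[row[i], col[i]] <- m[row[i], col[i]] + fixations$duration_ms[i]
  m <- m / total
  attr(m, "empty") <- FALSE
  m
}

#' Score a System Usability Scale response
#'
#' Standard SUS arithmetic over the 10 items on 1..5: odd items contribute
#' `item - 1`, even items `5 - item`, and the sum is scaled by 2.5, giving a
#' score between 0 and 100 (higher = more usable).
#'
#' @param items Integer vector of length 10, each in 1..5.
#' @return SUS score in `[0, 100]`.
#' @export
sus_score <- function(items) {
  if (length(items) != 10L || any(!items %in% 1:5))
    stop("SUS requires exactly 10 items, each an integer in 1..5",
         call. = FALSE)
  odd <- items[seq(1, 9, by = 2)]
  even <- items[seq(2, 10, by = 2)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

#' Score the Decisional Conflict Scale uncertainty subscale
#'
#' The uncertainty subscale has three items (clear about the best choice,
#' sure about the choice, choice easy to make) on a 1..5 Likert coding. The
#' aggregate score is `(mean(items) - 1) * 25`, placing it on 0-100 with
#' lower scores indicating less decisional conflict; it is reported to one
#' decimal. Item means (fractional values in `[1, 5]`) are accepted so group
#' summaries can be scored directly.
#'
#' @param items Numeric vector of length 3, each in `[1, 5]`.
#' @return Subscale score in `[0, 100]`, rounded to 1 decimal.
#' @export
dcs_uncertainty <- function(items) {
  if (length(items) != 3L || any(!is.finite(items)) ||
      any(items < 1) || any(items > 5))
    stop("DCS uncertainty subscale requires 3 items in [1, 5]", call. = FALSE)
  round((mean(items) - 1) * 25, 1)
}

#' Summarize a cohort of per-participant measures
#'
#' Computes the arithmetic mean and min-max range of each measure, optionally
#' split by presentation mode; with a `mode` column of exactly two levels and
#' participants observed under both, the paired per-participant difference
#' (second level minus first) is summarized too.
#'
#' @param data Long-format data frame with columns `participant_id`,
#'   `measure`, `value` and optionally `mode`.
#' @return A list with `summary` (data frame: measure, mode if present, mean,
#'   min, max, n) and, when paired, `paired_diff` (data frame: measure,
#'   mean_diff, n_pairs).
#' @export
cohort_summary <- function(data) {
  stopifnot(nrow(data) >= 1L,
            all(c("participant_id", "measure", "value") %in% names(data)))
  keys <- if ("mode" %in% names(data)) c("measure", "mode") else "measure"
  agg <- stats::aggregate(data["value"], data[keys], function(v)
    c(mean = mean(v), min = min(v), max = max(v), n = length(v)))
  summary <- cbind(agg[keys], as.data.frame(agg$value))

  out <- list(summary = summary)
  if ("mode" %in% names(data) && length(unique(data$mode)) == 2L) {
    lev <- sort(unique(data$mode))
    wide <- merge(
      data[data$mode == lev[1L], c("participant_id", "measure", "value")],
      data[data$mode == lev[2L], c("participant_id", "measure", "value")],
      by = c("participant_id", "measure"), suffixes = c("_a", "_b"))
    if (nrow(wide) > 0L) {
      wide$diff <- wide$value_b - wide$value_a
      pd <- stats::aggregate(wide["diff"], wide["measure"], function(v)
        c(mean_diff = mean(v), n_pairs = length(v)))
      out$paired_diff <- cbind(pd["measure"], as.data.frame(pd$diff))
      attr(out$paired_diff, "direction") <- paste(lev[2L], "-", lev[1L])
    }
  }
  out
}
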