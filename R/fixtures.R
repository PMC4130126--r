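#' Example decision-aid problems (synthetic content)
#'
#' Three worked decision problems spanning the situations a nudged decision
#' aid must handle: over-the-counter treatment of knee osteoarthritis (no
#' treatment vs acetaminophen vs NSAIDs: more benefit traded against more
#' side effects), obstructive sleep apnea (CPAP vs an oral appliance vs no
#' treatment: effectiveness traded against inconvenience), and chemotherapy
#' for late-stage non-small cell lung cancer (higher efficacy traded against
#' more frequent and severe side effects). Each carries five attributes
#' including at least one rare-event risk attribute (event probability at or
#' below 2%) so the probability-weighting bias has something to act on.
#'
#' All clinical numbers are illustrative, synthetic content for testing and
#' simulation — not clinical information; generated output files repeat this
#' in their headers.
#'
#' @return Named list of three [decision_problem()] objects:
#'   `osteoarthritis`, `osa`, `nsclc`.
#' @export
fixture_problems <- function() {
  oa <- decision_problem(
    "Knee osteoarthritis: over-the-counter treatment (synthetic example)",
    options = data.frame(
      id = c("none", "acetaminophen", "nsaid"),
      label = c("No treatment", "Acetaminophen", "NSAIDs")),
    attributes = list(
      attribute("pain_relief", "Pain relief", "benefit",
                "How much day-to-day knee pain improves."),
      attribute("function", "Daily functioning", "benefit",
                "Ability to walk, climb stairs and stay active."),
      attribute("stomach_upset", "Stomach upset", "harm",
                "Chance of nausea or indigestion while on treatment.",
                event_probability = c(none = 0, acetaminophen = 0.05,
                                      nsaid = 0.15)),
      attribute("gi_bleed", "Serious stomach bleeding", "harm",
                "Rare but serious gastrointestinal bleeding.",
                event_probability = c(none = 0.001, acetaminophen = 0.002,
                                      nsaid = 0.01)),
      attribute("cost", "Out-of-pocket cost", "harm",
                "Monthly cost of the medication.")),
    narrative = paste("Synthetic example content, not clinical advice.",
                      "Wear of the knee cartilage causes pain and stiffness;",
                      "medication choices trade benefit against side effects."))

  osa <- decision_problem(
    "Obstructive sleep apnea: treatment choice (synthetic example)",
    options = data.frame(
      id = c("cpap", "oral_appliance", "none"),
      label = c("CPAP", "Oral appliance", "No treatment")),
    attributes = list(
      attribute("symptom_relief", "Daytime sleepiness relief", "benefit",
                "How much daytime sleepiness and snoring improve."),
      attribute("convenience", "Ease of nightly use", "benefit",
                "Comfort and convenience of using the device every night."),
      attribute("jaw_discomfort", "Jaw or mask discomfort", "harm",
                "Chance of jaw soreness or mask irritation.",
                event_probability = c(cpap = 0.20, oral_appliance = 0.25,
                                      none = 0)),
      attribute("cardio_risk", "Serious heart complication", "harm",
                "Rare cardiovascular complication of untreated apnea.",
                event_probability = c(cpap = 0.005, oral_appliance = 0.01,
                                      none = 0.02)),
      attribute("cost", "Out-of-pocket cost", "harm",
                "Upfront and ongoing cost of the device.")),
    narrative = paste("Synthetic example content, not clinical advice.",
                      "Breathing repeatedly stops during sleep; the main",
                      "treatment (CPAP) is effective but inconvenient, with",
                      "less invasive alternatives available."))

  nsclc <- decision_problem(
    "Advanced non-small cell lung cancer: chemotherapy choice (synthetic example)",
    options = data.frame(
      id = c("doublet", "single_agent", "supportive"),
      label = c("Combination chemotherapy", "Single-agent chemotherapy",
                "Supportive care only")),
    attributes = list(
      attribute("survival", "Chance of living longer", "benefit",
                "Chance that treatment extends survival.",
                event_probability = c(doublet = 0.35, single_agent = 0.25,
                                      supportive = 0.10)),
      attribute("symptom_control", "Symptom control", "benefit",
                "Relief of cough, pain and breathlessness."),
      attribute("fatigue", "Severe fatigue and nausea", "harm",
                "Chance of severe treatment-related fatigue or nausea.",
                event_probability = c(doublet = 0.40, single_agent = 0.25,
                                      supportive = 0.05)),
      attribute("neutropenia", "Life-threatening infection", "harm",
                "Rare life-threatening infection from low blood counts.",
                event_probability = c(doublet = 0.02, single_agent = 0.008,
                                      supportive = 0)),
      attribute("hospital_time", "Time spent at the clinic", "harm",
                "Hours per month spent on infusions and monitoring.")),
    narrative = paste("Synthetic example content, not clinical advice.",
                      "More intensive chemotherapy offers higher efficacy but",
                      "more frequent and severe side effects."))

  list(osteoarthritis = oa, osa = osa, nsclc = nsclc)
}

#' Describe the positional attention profile of a synthetic gaze log
#'
#' A gaze profile states, per display position, the share of total viewing
#' time spent on that row, with the remainder going to other areas of the
#' screen; fixation durations are log-normal. The default emulates the
#' positional gradient seen in summary screens: about 23% of time on the
#' first row declining linearly to about 13% on the last, regardless of
#' content.
#'
#' @param position_shares Non-negative shares per display position (sum <= 1).
#' @param other_share Share for other areas of the screen; defaults to the
#'   complement of `position_shares`.
#' @param meanlog,sdlog Log-normal fixation-duration parameters, in seconds
#'   (defaults 250 ms typical duration).
#' @param n_fixations Number of fixations to generate (default 200).
#' @return A list of class `"gaze_profile"`.
#' @export
gaze_profile <- function(position_shares,
                         other_share = 1 - sum(position_shares),
                         meanlog = log(0.25), sdlog = 0.5,
                         n_fixations = 200) {
  stopifnot(all(position_shares >= 0), other_share >= -1e-9,
            abs(sum(position_shares) + other_share - 1) < 1e-9,
            n_fixations >= 0)
  structure(list(position_shares = position_shares,
                 other_share = max(other_share, 0),
                 meanlog = meanlog, sdlog = sdlog,
                 n_fixations = n_fixations),
            class = "gaze_profile")
}

#' @rdname gaze_profile
#' @param n_rows Number of displayed attribute rows.
#' @param first,last Time share of the first and last row (default 0.23 and
#'   0.13, interpolated linearly in between).
#' @param ... Passed on to [gaze_profile()].
#' @export
linear_gaze_profile <- function(n_rows, first = 0.23, last = 0.13, ...) {
  shares <- if (n_rows == 1L) first else seq(first, last, length.out = n_rows)
  gaze_profile(shares, ...)
}

#' Generate a synthetic fixation log over a summary layout
#'
#' Draws each fixation's target (a display row or other areas of the screen)
#' from the profile's time shares, places it uniformly inside the target's
#' AOI box (or inside the header band for other-screen fixations), and draws
#' log-normal durations; as the number of fixations grows the realized AOI
#' time shares converge to the profile. A stand-in for an eye tracker's
#' fixation export.
#'
#' @param layout A [compute_layout()] result.
#' @param profile A [gaze_profile()] with one share per layout row.
#' @param seed Integer seed.
#' @return Fixation data frame (`start_ms`, `duration_ms`, `x`, `y`, `aoi`
#'   unset) in the format [detect_fixations()] produces.
#' @export
generate_gaze_log <- function(layout, profile, seed) {
  stopifnot(inherits(layout, "summary_layout"), inherits(profile, "gaze_profile"))
  boxes <- layout$aoi_boxes
  if (length(profile$position_shares) != nrow(boxes))
    stop("profile has ", length(profile$position_shares),
         " position shares for ", nrow(boxes), " layout rows", call. = FALSE)
  set.seed(seed)
  n <- profile$n_fixations
  empty <- data.frame(start_ms = numeric(), duration_ms = numeric(),
                      x = numeric(), y = numeric(), aoi = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  probs <- c(profile$position_shares, profile$other_share)
  target <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  dur_s <- stats::rlnorm(n, profile$meanlog, profile$sdlog)
  x <- stats::runif(n)
  y <- numeric(n)
  for (i in seq_len(n)) {
    if (target[i] <= nrow(boxes)) {
      b <- target[i]
      x[i] <- stats::runif(1, boxes$x0[b], boxes$x1[b])
      y[i] <- stats::runif(1, boxes$y0[b], boxes$y1[b])
    } else {
      y[i] <- stats::runif(1, 0, layout$region_top)  # header band
    }
  }
  dur_ms <- dur_s * 1000
  gap_ms <- stats::runif(n, 20, 80)  # saccade gaps
  start_ms <- cumsum(c(0, (dur_ms + gap_ms)[-n]))
  data.frame(start_ms = start_ms, duration_ms = dur_ms, x = x, y = y,
             aoi = NA_character_, stringsAsFactors = FALSE)
}

#' Generate synthetic participant responses
#'
#' Produces the full response set of one participant — budget-pie weights,
#' 5-point ratings, SUS items and DCS uncertainty items — around a persona,
#' with optional jitter. Jittered weights are projected back onto the budget
#' (largest-remainder in integer mode) so they always validate; ratings and
#' questionnaire items take integer steps and are clamped to range.
#'
#' @param problem A [decision_problem()].
#' @param persona List with `weights` (named, summing to the budget),
#'   `ratings` (options x attributes matrix in 1..5), `sus` (10 items 1..5),
#'   `dcs` (3 items 1..5).
#' @param jitter Standard deviation of the perturbations (0 = echo the
#'   persona exactly).
#' @param seed Integer seed.
#' @param participant_id Id written into the output tables.
#' @return List of data frames: `weights` (participant_id, attribute_id,
#'   points), `ratings` (participant_id, option_id, attribute_id, rating),
#'   `questionnaire` (participant_id, instrument, item_index, value).
#' @export
generate_responses <- function(problem, persona, jitter = 0, seed = 1,
                               participant_id = "p1") {
  set.seed(seed)
  budget <- sum(persona$weights)
  w <- persona$weights
  if (jitter > 0) {
    w <- project_to_budget(w + stats::rnorm(length(w), 0, jitter), budget)
    w <- stats::setNames(largest_remainder(w, budget), names(w))
  }
  jitter_items <- function(v, lo, hi) {
    if (jitter > 0) v <- v + round(stats::rnorm(length(v), 0, jitter))
    pmin(pmax(v, lo), hi)
  }
  ratings <- persona$ratings
  ratings[] <- jitter_items(as.vector(ratings), 1, 5)
  sus <- jitter_items(persona$sus, 1, 5)
  dcs <- jitter_items(persona$dcs, 1, 5)

  ridx <- expand.grid(option_id = rownames(ratings),
                      attribute_id = colnames(ratings),
                      stringsAsFactors = FALSE)
  list(
    weights = data.frame(participant_id = participant_id,
                         attribute_id = names(w), points = as.numeric(w),
                         stringsAsFactors = FALSE),
    ratings = data.frame(participant_id = participant_id, ridx,
                         rating = as.integer(ratings[cbind(ridx$option_id,
                                                           ridx$attribute_id)]),
                         stringsAsFactors = FALSE),
    questionnaire = data.frame(
      participant_id = participant_id,
      instrument = rep(c("sus", "dcs_uncertainty"), c(10L, 3L)),
      item_index = c(1:10, 1:3),
      value = as.integer(c(sus, dcs)),
      stringsAsFactors = FALSE))
}

#' Draw a random persona for a problem
#'
#' Uniform-simplex weights (largest-remainder rounded to whole points),
#' uniform ratings in 1..5 and uniform questionnaire items; useful as input
#' to [generate_responses()] and for end-to-end smoke runs.
#'
#' @param problem A [decision_problem()].
#' @param seed Integer seed.
#' @param budget Weight budget (default 100).
#' @return A persona list (see [generate_responses()]).
#' @export
random_persona <- function(problem, seed = 1, budget = 100) {
  set.seed(seed)
  attrs <- attribute_ids(problem)[order(document_order(problem))]
  opts <- option_ids(problem)
  w <- stats::rexp(length(attrs))
  w <- stats::setNames(largest_remainder(w / sum(w) * budget, budget), attrs)
  ratings <- matrix(sample(1:5, length(opts) * length(attrs), replace = TRUE),
                    nrow = length(opts), dimnames = list(opts, attrs))
  list(weights = w, ratings = ratings,
       sus = sample(1:5, 10, replace = TRUE),
       dcs = sample(1:5, 3, replace = TRUE))
}
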