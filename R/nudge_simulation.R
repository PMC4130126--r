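#' Prospect-theory probability weighting
#'
#' Inverse-S probability weighting in the Tversky-Kahneman (1992) form,
#' `pi(p) = p^gamma / (p^gamma + (1-p)^gamma)^(1/gamma)`. For `gamma < 1`
#' small probabilities are overweighted and large ones underweighted — the
#' distortion that can scare decision makers away from options carrying
#' several rare side effects. `gamma = 1` is the undistorted identity; the
#' endpoints 0 and 1 are fixed points for every `gamma`.
#'
#' @param p Probability (or vector) in `[0, 1]`.
#' @param gamma Curvature in `(0, 1]`.
#' @return Perceived probability in `[0, 1]`.
#' @examples
#' prob_weight(0.01, 0.61)  # ~ 0.055: a 1% risk felt as 5.5%
#' @export
prob_weight <- function(p, gamma) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]", call. = FALSE)
  if (gamma == 1) return(as.numeric(p))
  pg <- p^gamma
  qg <- (1 - p)^gamma
  out <- pg / (pg + qg)^(1 / gamma)
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

#' Construct the parameters of a simulated decision maker
#'
#' An agent holds true underlying values (weights over attributes and scores
#' per option-attribute) plus one parameter for each of the four decision
#' biases the nudged presentation targets:
#' \describe{
#'   \item{`weight_noise_sd`}{unstable values — the elicited weights are the
#'     true weights plus Gaussian noise, projected back onto the budget.}
#'   \item{`primacy_decay`}{order effects — the effective weight of the row
#'     shown at display position `j` is multiplied by `d^(j-1)`.}
#'   \item{`prob_weight_gamma`}{overweighting of rare events — scores of
#'     risk attributes are recomputed from [prob_weight()] of the event
#'     probability.}
#'   \item{`attention_capacity`}{information overload — rows beyond position
#'     `k` receive zero effective weight.}
#' }
#' `default_adherence` is the probability of accepting a presented default
#' when the perceived totals of the top two options are within the
#' indifference margin.
#'
#' @param true_weights Named numeric vector over attributes; its sum defines
#'   the budget.
#' @param true_scores Options x attributes matrix in `[0, 100]`. For risk
#'   attributes concordance is judged against scores implied by the true
#'   event probabilities, so supply `100 * (1 - p)` there (the
#'   [sample_agents()] sampler does).
#' @param weight_noise_sd Standard deviation of elicitation noise in points
#'   (>= 0).
#' @param primacy_decay Geometric position decay `d` in `(0, 1]`.
#' @param prob_weight_gamma Curvature in `(0, 1]`.
#' @param attention_capacity Number of displayed rows processed (>= 1; `Inf`
#'   for no truncation).
#' @param default_adherence Probability in `[0, 1]`.
#' @return A list of class `"agent_params"`.
#' @export
agent_params <- function(true_weights, true_scores, weight_noise_sd = 0,
                         primacy_decay = 1, prob_weight_gamma = 1,
                         attention_capacity = Inf, default_adherence = 0) {
  stopifnot(is.numeric(true_weights), !is.null(names(true_weights)),
            all(true_weights >= 0), sum(true_weights) > 0,
            is.matrix(true_scores),
            all(true_scores >= 0), all(true_scores <= 100),
            weight_noise_sd >= 0,
            primacy_decay > 0, primacy_decay <= 1,
            prob_weight_gamma > 0, prob_weight_gamma <= 1,
            attention_capacity >= 1,
            default_adherence >= 0, default_adherence <= 1)
  structure(list(true_weights = true_weights,
                 true_scores = true_scores[, names(true_weights), drop = FALSE],
                 budget = sum(true_weights),
                 weight_noise_sd = weight_noise_sd,
                 primacy_decay = primacy_decay,
                 prob_weight_gamma = prob_weight_gamma,
                 attention_capacity = attention_capacity,
                 default_adherence = default_adherence),
            class = "agent_params")
}

# Clamp to >= 0 and rescale so the weights conserve the budget; uniform
# fallback when noise wipes everything out.
project_to_budget <- function(w, budget) {
  w <- pmax(w, 0)
  if (sum(w) <= 0) w <- rep(1, length(w))
  w / sum(w) * budget
}

# event-probability-implied scores: 100*(1-p) for harms (less likely harm is
# better), 100*p for benefits, with probabilities optionally distorted.
risk_scores <- function(problem, gamma = 1) {
  out <- list()
  for (a in problem$attributes) {
    if (is.null(a$event_probability)) next
    p <- prob_weight(a$event_probability, gamma)
    s <- if (a$direction == "harm") 100 * (1 - p) else 100 * p
    out[[a$id]] <- s
  }
  out
}

#' Simulate how an agent perceives a decision problem
#'
#' Applies the value-instability and risk-perception biases (the two that act
#' before any display is seen): elicited weights are the true weights plus
#' seeded Gaussian noise projected back onto the budget, and scores of risk
#' attributes are recomputed from the probability-weighted event probability
#' in place of the true one. Order and capacity effects depend on the display
#' and are applied in [choose()]. Perception is drawn once per (agent, seed),
#' so the same agent sees the same perceived problem under both presentation
#' modes.
#'
#' @param problem A [decision_problem()].
#' @param agent An [agent_params()].
#' @param seed Integer seed.
#' @return A list with `weights` (elicited, budget-conserving) and `scores`
#'   (perceived options x attributes matrix).
#' @export
perceive <- function(problem, agent, seed) {
  stopifnot(inherits(agent, "agent_params"))
  set.seed(seed)
  w <- agent$true_weights
  if (agent$weight_noise_sd > 0)
    w <- project_to_budget(w + stats::rnorm(length(w), 0, agent$weight_noise_sd),
                           agent$budget)
  s <- agent$true_scores
  for (a in names(rs <- risk_scores(problem, agent$prob_weight_gamma))) {
    s[names(rs[[a]]), a] <- rs[[a]]
  }
  list(weights = w, scores = s)
}

# Effective weights after display-dependent biases: geometric primacy decay
# over display positions and hard truncation beyond the attention capacity.
effective_weights <- function(weights, display_order, d, k) {
  mult <- stats::setNames(d^(seq_along(display_order) - 1), display_order)
  if (is.finite(k) && k < length(display_order))
    mult[display_order[seq.int(k + 1L, length(display_order))]] <- 0
  weights * mult[names(weights)]
}

# Decision rule shared by choose() and run_experiment(): perceived MCDA
# totals under the display, with default adherence in nudged mode when the
# top two totals are within the indifference margin.
decide <- function(problem, mode, perception, agent, u_default,
                   indifference_margin = 5) {
  w <- perception$weights
  s <- perception$scores[, names(w), drop = FALSE]
  budget <- agent$budget

  if (mode == "dcida") {
    display_order <- names(w)[order(-w, seq_along(w))]
    tool_totals <- as.vector(s %*% w) / budget  # what the tool computes
    names(tool_totals) <- rownames(s)
    default_option <- names(tool_totals)[which.max(tool_totals)]
  } else {
    display_order <- names(w)  # authored document order
    default_option <- NA_character_
  }

  ew <- effective_weights(w, display_order, agent$primacy_decay,
                          agent$attention_capacity)
  totals <- as.vector(s %*% ew) / budget
  names(totals) <- rownames(s)
  ranked <- sort(totals, decreasing = TRUE)
  chosen <- names(ranked)[1L]
  if (mode == "dcida" && length(ranked) >= 2L &&
      (ranked[1L] - ranked[2L]) < indifference_margin &&
      u_default < agent$default_adherence) {
    chosen <- default_option
  }
  chosen
}

#' Choose an option as a biased agent under a given presentation
#'
#' Computes the agent's perceived weighted-additive totals under the display
#' (conventional: rows in authored document order; nudged: rows in elicited
#' weight order with the MCDA default pre-selected) and returns the chosen
#' option. In nudged mode, when the perceived totals of the top two options
#' fall within the indifference margin, the agent adopts the presented
#' default with probability `default_adherence`. Fully deterministic given
#' `(problem, mode, agent, seed)`.
#'
#' @param problem A [decision_problem()].
#' @param mode `"conventional"` or `"dcida"`.
#' @param agent An [agent_params()].
#' @param seed Integer seed.
#' @param indifference_margin Width, on the 0-100 total scale, of the
#'   near-indifference band in which a default can sway the choice
#'   (default 5).
#' @return The chosen option id.
#' @export
choose <- function(problem, mode = c("dcida", "conventional"), agent, seed,
                   indifference_margin = 5) {
  mode <- match.arg(mode)
  perception <- perceive(problem, agent, seed)
  u <- stats::runif(1)  # adherence draw, continuing the seeded stream
  decide(problem, mode, perception, agent, u, indifference_margin)
}

# The option a bias-free agent should pick: argmax of true weights x true
# scores (risk attributes at their undistorted probability-implied scores).
value_optimal_option <- function(problem, agent) {
  s <- agent$true_scores
  for (a in names(rs <- risk_scores(problem, gamma = 1)))
    s[names(rs[[a]]), a] <- rs[[a]]
  totals <- as.vector(s[, names(agent$true_weights), drop = FALSE] %*%
                        agent$true_weights)
  rownames(s)[which.max(totals)]
}

#' Sample a population of agents for a decision problem
#'
#' True weights are drawn uniformly from the simplex (normalized exponential
#' spacings) and scaled to the budget; true scores are uniform on `[0, 100]`
#' except for risk attributes, whose true scores are tied to the event
#' probabilities (`100 (1 - p)` for harms, `100 p` for benefits) so that the
#' undistorted perception reproduces them exactly. Bias parameters are shared
#' across the population.
#'
#' @param problem A [decision_problem()].
#' @param n Number of agents.
#' @param budget Weight budget (default 100).
#' @param weight_noise_sd,primacy_decay,prob_weight_gamma,attention_capacity,default_adherence
#'   Population bias parameters, as in [agent_params()].
#' @return List of [agent_params()].
#' @export
sample_agents <- function(problem, n, budget = 100, weight_noise_sd = 0,
                          primacy_decay = 1, prob_weight_gamma = 1,
                          attention_capacity = Inf, default_adherence = 0) {
  attrs <- attribute_ids(problem)[order(document_order(problem))]
  opts <- option_ids(problem)
  rs <- risk_scores(problem, gamma = 1)
  lapply(seq_len(n), function(i) {
    w <- stats::rexp(length(attrs))
    w <- stats::setNames(w / sum(w) * budget, attrs)
    s <- matrix(stats::runif(length(opts) * length(attrs), 0, 100),
                nrow = length(opts), dimnames = list(opts, attrs))
    for (a in names(rs)) s[names(rs[[a]]), a] <- rs[[a]]
    agent_params(w, s, weight_noise_sd = weight_noise_sd,
                 primacy_decay = primacy_decay,
                 prob_weight_gamma = prob_weight_gamma,
                 attention_capacity = attention_capacity,
                 default_adherence = default_adherence)
  })
}

#' Run a paired conventional-vs-nudged simulation experiment
#'
#' Samples a population of biased agents, lets each one face the same
#' decision problem under both the conventional and the nudged presentation
#' (a paired, within-agent design), and measures value concordance per mode:
#' the fraction of agents whose chosen option equals the option maximizing
#' their own true weighted values. A percentile bootstrap interval on the
#' paired difference (nudged minus conventional) is included.
#'
#' @param problem A [decision_problem()].
#' @param n_agents Number of agents (>= 1).
#' @param seed Integer master seed; all randomness derives from it.
#' @param indifference_margin Passed to the decision rule (default 5).
#' @param n_boot Bootstrap replicates for the paired-difference interval
#'   (default 1000).
#' @param ... Population bias parameters passed to [sample_agents()].
#' @return A list of class `"simulation_result"`: `n_agents`, `concordance`
#'   (named: conventional, dcida), `diff`, `diff_ci` (95% percentile
#'   bootstrap), `agents` (per-agent data frame with chosen and
#'   value-optimal options), `seed`.
#' @examples
#' p <- fixture_problems()$osa
#' r <- run_experiment(p, n_agents = 50, seed = 1,
#'                     primacy_decay = 0.7, attention_capacity = 3,
#'                     prob_weight_gamma = 0.61, weight_noise_sd = 5,
#'                     default_adherence = 0.8)
#' r$concordance
#' @export
run_experiment <- function(problem, n_agents, seed, indifference_margin = 5,
                           n_boot = 1000, ...) {
  stopifnot(n_agents >= 1)
  set.seed(seed)
  agents <- sample_agents(problem, n_agents, ...)
  agent_seeds <- sample.int(2^31 - 1L, n_agents)
  u_default <- stats::runif(n_agents)

  rec <- lapply(seq_len(n_agents), function(i) {
    perception <- perceive(problem, agents[[i]], agent_seeds[i])
    optimal <- value_optimal_option(problem, agents[[i]])
    data.frame(
      agent = i,
      optimal = optimal,
      conventional = decide(problem, "conventional", perception, agents[[i]],
                            u_default[i], indifference_margin),
      dcida = decide(problem, "dcida", perception, agents[[i]],
                     u_default[i], indifference_margin),
      stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec)
  rec$conc_conventional <- rec$conventional == rec$optimal
  rec$conc_dcida <- rec$dcida == rec$optimal

  concordance <- c(conventional = mean(rec$conc_conventional),
                   dcida = mean(rec$conc_dcida))
  d <- as.numeric(rec$conc_dcida) - as.numeric(rec$conc_conventional)
  boot <- replicate(n_boot, mean(d[sample.int(n_agents, replace = TRUE)]))
  structure(list(n_agents = n_agents, concordance = concordance,
                 diff = mean(d),
                 diff_ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
                 agents = rec, seed = seed),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Paired nudge simulation (", x$n_agents, " agents, seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  concordance: conventional %.3f, nudged %.3f\n",
              x$concordance[["conventional"]], x$concordance[["dcida"]]))
  cat(sprintf("  paired difference %.3f (95%% CI %.3f to %.3f)\n",
              x$diff, x$diff_ci[1], x$diff_ci[2]))
  invisible(x)
}
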