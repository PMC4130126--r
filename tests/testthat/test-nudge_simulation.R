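bias_free <- function(problem, budget = 100) {
  # deterministic representative agent with no bias active
  attrs <- attribute_ids(problem)
  opts <- option_ids(problem)
  set.seed(1)
  w <- setNames(rexp(length(attrs)), attrs)
  w <- w / sum(w) * budget
  s <- matrix(runif(length(opts) * length(attrs), 0, 100),
              nrow = length(opts), dimnames = list(opts, attrs))
  rs <- dcida:::risk_scores(problem, gamma = 1)
  for (a in names(rs)) s[names(rs[[a]]), a] <- rs[[a]]
  agent_params(w, s)
}

test_that("probability weighting has fixed points, an identity limit and an inverse-S shape", {
  for (g in c(0.3, 0.61, 1)) {
    expect_identical(prob_weight(0, g), 0)
    expect_identical(prob_weight(1, g), 1)
  }
  p <- seq(0, 1, by = 0.01)
  expect_identical(prob_weight(p, 1), p)
  # frozen value computed independently from the closed form
  expect_equal(prob_weight(0.01, 0.61), 0.055266, tolerance = 1e-4)
  # monotone increasing for fixed gamma
  for (g in c(0.4, 0.61, 0.9)) expect_true(all(diff(prob_weight(p, g)) > 0))
  # overweighting of small p
  expect_gt(prob_weight(0.01, 0.61), 0.01)
  expect_lt(prob_weight(0.9, 0.61), 0.9)
  expect_error(prob_weight(-0.1, 0.61), "\\[0, 1\\]")
  expect_error(prob_weight(0.5, 0), "\\(0, 1\\]")
  expect_error(prob_weight(0.5, 1.5), "\\(0, 1\\]")
})

test_that("perception is exact in the bias-free limit and seeded otherwise", {
  problem <- fixture_problems()$osa
  agent <- bias_free(problem)
  p <- perceive(problem, agent, seed = 99)
  expect_equal(p$weights, agent$true_weights, tolerance = 1e-12)
  expect_equal(p$scores, agent$true_scores, tolerance = 1e-12)

  noisy <- agent_params(agent$true_weights, agent$true_scores,
                        weight_noise_sd = 5, prob_weight_gamma = 0.61)
  p1 <- perceive(problem, noisy, seed = 7)
  p2 <- perceive(problem, noisy, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1$weights, perceive(problem, noisy, seed = 8)$weights))
  expect_equal(sum(p1$weights), 100, tolerance = 1e-9)
  # rare-event risk attribute is overweighted: perceived harm score drops
  expect_lt(p1$scores["none", "cardio_risk"],
            agent$true_scores["none", "cardio_risk"])
})

test_that("geometric position decay and capacity truncation act in display order", {
  w <- c(a1 = 50, a2 = 30, a3 = 20)
  ew <- dcida:::effective_weights(w, c("a1", "a2", "a3"), d = 0.8, k = Inf)
  expect_equal(unname(ew), c(50 * 1, 30 * 0.8, 20 * 0.64))
  # same weights under a different display order pick up different multipliers
  ew2 <- dcida:::effective_weights(w, c("a3", "a2", "a1"), d = 0.8, k = Inf)
  expect_equal(unname(ew2), c(50 * 0.64, 30 * 0.8, 20 * 1))
  # capacity 1: only the first displayed row survives
  ew3 <- dcida:::effective_weights(w, c("a2", "a1", "a3"), d = 1, k = 1)
  expect_equal(unname(ew3), c(0, 30, 0))
})

test_that("a bias-free agent chooses the value-optimal option in both modes", {
  problem <- fixture_problems()$osteoarthritis
  agent <- bias_free(problem)
  optimal <- dcida:::value_optimal_option(problem, agent)
  expect_identical(choose(problem, "conventional", agent = agent, seed = 5), optimal)
  expect_identical(choose(problem, "dcida", agent = agent, seed = 5), optimal)
})

test_that("with identical options and full adherence the nudged mode returns the default", {
  prob <- tiny_problem(2, 3)
  attrs <- attribute_ids(prob)
  s <- matrix(60, 2, 3, dimnames = list(option_ids(prob), attrs))
  agent <- agent_params(setNames(c(40, 35, 25), attrs), s, default_adherence = 1)
  for (seed in 1:10)
    expect_identical(choose(prob, "dcida", agent = agent, seed = seed), "o1")
})

test_that("choice is deterministic for fixed seed and parameters", {
  problem <- fixture_problems()$nsclc
  agent <- agent_params(
    setNames(c(30, 25, 20, 15, 10), attribute_ids(problem)),
    matrix(runif(15, 0, 100), 3,
           dimnames = list(option_ids(problem), attribute_ids(problem))),
    weight_noise_sd = 8, primacy_decay = 0.7, prob_weight_gamma = 0.61,
    attention_capacity = 3, default_adherence = 0.5)
  for (mode in c("conventional", "dcida")) {
    c1 <- choose(problem, mode, agent = agent, seed = 123)
    c2 <- choose(problem, mode, agent = agent, seed = 123)
    expect_identical(c1, c2)
  }
})

test_that("modes agree agent-by-agent when document order already equals value order", {
  prob <- tiny_problem(3, 4)
  attrs <- attribute_ids(prob)
  set.seed(17)
  for (i in 1:20) {
    w <- setNames(sort(runif(4, 1, 50), decreasing = TRUE), attrs)
    w <- w / sum(w) * 100  # value order == document order
    s <- matrix(runif(12, 0, 100), 3, dimnames = list(option_ids(prob), attrs))
    agent <- agent_params(w, s, primacy_decay = 0.7, attention_capacity = 3,
                          default_adherence = 0)  # no default taken
    seed <- sample.int(1e6, 1)
    expect_identical(choose(prob, "conventional", agent = agent, seed = seed),
                     choose(prob, "dcida", agent = agent, seed = seed))
  }
})

test_that("a bias-free population reaches concordance exactly 1 in both modes", {
  problem <- fixture_problems()$osa
  res <- run_experiment(problem, n_agents = 200, seed = 42)
  expect_identical(unname(res$concordance), c(1, 1))
})

test_that("run_experiment is reproducible and single-agent concordance is 0 or 1", {
  problem <- fixture_problems()$osa
  r1 <- run_experiment(problem, n_agents = 30, seed = 9, weight_noise_sd = 5,
                       primacy_decay = 0.8, attention_capacity = 3,
                       prob_weight_gamma = 0.61, default_adherence = 0.8)
  r2 <- run_experiment(problem, n_agents = 30, seed = 9, weight_noise_sd = 5,
                       primacy_decay = 0.8, attention_capacity = 3,
                       prob_weight_gamma = 0.61, default_adherence = 0.8)
  expect_identical(r1$concordance, r2$concordance)
  expect_identical(r1$agents, r2$agents)

  single <- run_experiment(problem, n_agents = 1, seed = 3,
                           primacy_decay = 0.5, attention_capacity = 2)
  expect_true(all(single$concordance %in% c(0, 1)))
})

test_that("active order and capacity biases favour the nudged presentation", {
  problem <- fixture_problems()$osa
  res <- run_experiment(problem, n_agents = 2000, seed = 20240817,
                        weight_noise_sd = 5, primacy_decay = 0.7,
                        attention_capacity = 3, prob_weight_gamma = 0.61,
                        default_adherence = 0.8)
  expect_gte(res$concordance[["dcida"]], res$concordance[["conventional"]])
  expect_gte(res$diff, 0)
})
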