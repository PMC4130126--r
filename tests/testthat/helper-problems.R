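# Small problems built in code for unit tests.

tiny_problem <- function(n_options = 2, n_attributes = 3) {
  decision_problem(
    "tiny",
    options = data.frame(id = paste0("o", seq_len(n_options)),
                         label = paste("Option", seq_len(n_options))),
    attributes = lapply(seq_len(n_attributes), function(i)
      attribute(paste0("a", i), paste("Attr", i),
                if (i %% 2) "benefit" else "harm")))
}

random_allocation <- function(problem, budget = 100, integer = FALSE) {
  ids <- attribute_ids(problem)
  w <- stats::rexp(length(ids))
  w <- w / sum(w) * budget
  if (integer) w <- dcida:::largest_remainder(w, budget)
  weight_allocation(problem, stats::setNames(w, ids), budget = budget,
                    integer = integer)
}

random_scores <- function(problem) {
  opts <- option_ids(problem)
  attrs <- attribute_ids(problem)
  matrix(stats::runif(length(opts) * length(attrs), 0, 100),
         nrow = length(opts), dimnames = list(opts, attrs))
}

# fixation row constructor
fx <- function(duration_ms, aoi, x = 0.5, y = 0.5, start_ms = 0) {
  data.frame(start_ms = start_ms, duration_ms = duration_ms, x = x, y = y,
             aoi = aoi, stringsAsFactors = FALSE)
}
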