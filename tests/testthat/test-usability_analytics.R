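# Brute-force oracle for I-DT: enumerate all candidate windows and greedily
# take the earliest maximal low-dispersion window long enough to count.
idt_oracle <- function(samples, thr, min_dur) {
  keep <- if (is.null(samples$valid)) rep(TRUE, nrow(samples)) else samples$valid
  out <- list()
  run_id <- cumsum(c(TRUE, diff(as.integer(keep)) != 0))
  for (run in split(seq_len(nrow(samples)), run_id)) {
    if (!keep[run[1]]) next
    t <- samples$t_ms[run]; x <- samples$x[run]; y <- samples$y[run]
    i <- 1
    while (i <= length(run)) {
      best_j <- NA
      for (j in i:length(run)) {
        disp <- diff(range(x[i:j])) + diff(range(y[i:j]))
        if (disp > thr) break
        best_j <- j
      }
      if (!is.na(best_j) && t[best_j] - t[i] >= min_dur) {
        out[[length(out) + 1]] <- c(start = t[i], dur = t[best_j] - t[i],
                                    x = mean(x[i:best_j]), y = mean(y[i:best_j]))
        i <- best_j + 1
      } else i <- i + 1
    }
  }
  out
}

test_that("a steady gaze yields one fixation and a pure saccade yields none", {
  steady <- data.frame(t_ms = seq(0, 300, by = 20), x = 0.4, y = 0.4)
  f <- detect_fixations(steady, min_duration_ms = 100)
  expect_identical(nrow(f), 1L)
  expect_equal(f$duration_ms, 300)
  expect_equal(c(f$x, f$y), c(0.4, 0.4))

  saccade <- data.frame(t_ms = seq(0, 300, by = 20),
                        x = seq(0, 1, length.out = 16), y = 0.5)
  expect_identical(nrow(detect_fixations(saccade)), 0L)
  expect_identical(nrow(detect_fixations(steady[0, ])), 0L)  # empty, not error
})

test_that("two clusters separated by fast samples give two fixations at the cluster means", {
  set.seed(2)
  cl <- function(t0, cx, cy) data.frame(
    t_ms = seq(t0, t0 + 250, by = 25),
    x = cx + runif(11, -0.004, 0.004), y = cy + runif(11, -0.004, 0.004))
  trace <- rbind(cl(0, 0.2, 0.3),
                 data.frame(t_ms = c(270, 285), x = c(0.5, 0.7), y = c(0.5, 0.7)),
                 cl(300, 0.8, 0.8))
  f <- detect_fixations(trace, dispersion_threshold = 0.02, min_duration_ms = 100)
  expect_identical(nrow(f), 2L)
  expect_equal(f$x, c(0.2, 0.8), tolerance = 0.01)
  expect_equal(f$y, c(0.3, 0.8), tolerance = 0.01)

  oracle <- idt_oracle(trace, 0.02, 100)
  expect_length(oracle, 2)
  for (k in 1:2) {
    expect_equal(f$start_ms[k], unname(oracle[[k]]["start"]))
    expect_equal(f$duration_ms[k], unname(oracle[[k]]["dur"]))
    expect_equal(f$x[k], unname(oracle[[k]]["x"]), tolerance = 1e-12)
  }
})

test_that("detector matches the all-windows oracle on random traces and respects the span", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 80
    trace <- data.frame(
      t_ms = cumsum(runif(n, 10, 30)),
      x = cumsum(rnorm(n, 0, 0.01)) %% 1,
      y = cumsum(rnorm(n, 0, 0.01)) %% 1,
      valid = runif(n) > 0.05)
    f <- detect_fixations(trace, 0.03, 80)
    oracle <- idt_oracle(trace, 0.03, 80)
    expect_identical(nrow(f), length(oracle))
    if (nrow(f) > 0) {
      expect_equal(f$start_ms, vapply(oracle, `[[`, 0, "start"))
      expect_equal(f$duration_ms, vapply(oracle, `[[`, 0, "dur"))
    }
    expect_lte(sum(f$duration_ms), max(trace$t_ms) - min(trace$t_ms))
  }
})

test_that("assign_aoi does point-in-rectangle with half-open boundaries", {
  boxes <- data.frame(attribute_id = c("top", "bottom"),
                      x0 = 0, x1 = 1, y0 = c(0.2, 0.6), y1 = c(0.6, 1.0))
  f <- rbind(fx(100, NA, x = 0.5, y = 0.4),   # inside top row
             fx(100, NA, x = 0.5, y = 0.05),  # page header
             fx(100, NA, x = 0.5, y = 0.6))   # shared boundary -> lower row
  labelled <- assign_aoi(f, boxes)
  expect_identical(labelled$aoi, c("top", "other_screen", "bottom"))

  overlap <- data.frame(attribute_id = c("a", "b"),
                        x0 = 0, x1 = 1, y0 = c(0.2, 0.5), y1 = c(0.7, 1.0))
  expect_error(assign_aoi(f, overlap), "overlap")
})

test_that("relative fixation shares use the on-attribute denominator", {
  ranking <- paste0("a", 1:5)
  f <- rbind(fx(5600, "a1"), fx(3300, "a2"), fx(1100, "a5"),
             fx(4000, "a3"), fx(4500, "a4"), fx(12800, "other_screen"))
  rf <- relative_fixation(f, ranking)
  expect_identical(unname(rf$shares_pct),
                   c(30, 18, 6, 46))  # most, second, least, other
  expect_equal(unname(rf$durations_s),
               c(5.6, 3.3, 1.1, 8.5, 12.8), tolerance = 1e-12)
  expect_equal(rf$total_on_screen_s, 31.3, tolerance = 1e-12)
})

test_that("relative fixation handles edge cases: one attribute, zero time, unknown labels", {
  expect_identical(unname(relative_fixation(fx(2000, "a1"), "a1")$shares_pct[1]), 100)
  expect_warning(rf0 <- relative_fixation(fx(2000, "other_screen"), paste0("a", 1:3)),
                 "undefined")
  expect_true(rf0$undefined)
  expect_true(all(is.na(rf0$shares_pct)))
  expect_error(relative_fixation(fx(100, "zz"), c("a1", "a2")), "outside the ranking")
})

test_that("bucket durations partition on-attribute time and shares sum to 100 up to rounding", {
  set.seed(77)
  ranking <- paste0("a", 1:5)
  for (i in 1:100) {
    f <- do.call(rbind, lapply(1:12, function(j)
      fx(runif(1, 50, 3000), sample(c(ranking, "other_screen"), 1))))
    if (!any(f$aoi %in% ranking)) next
    rf <- relative_fixation(f, ranking)
    on_attr_s <- sum(f$duration_ms[f$aoi %in% ranking]) / 1000
    expect_equal(sum(rf$durations_s[names(rf$shares_pct)]), on_attr_s,
                 tolerance = 1e-9)
    expect_lte(abs(sum(rf$shares_pct) - 100), 2)  # 4 buckets rounded to percent
  }
})

test_that("heatmap grids conserve fixation time", {
  one <- fx(500, NA, x = 0.1, y = 0.1)
  m <- heatmap_grid(one, 3, 3)
  expect_identical(m[1, 1], 1)
  expect_identical(sum(m), 1)

  two <- rbind(fx(500, NA, x = 0.1, y = 0.1), fx(500, NA, x = 0.9, y = 0.9))
  m2 <- heatmap_grid(two, 2, 2)
  expect_identical(c(m2[1, 1], m2[2, 2]), c(0.5, 0.5))

  set.seed(6)
  rand <- do.call(rbind, lapply(1:50, function(i)
    fx(runif(1, 10, 1000), NA, x = runif(1), y = runif(1))))
  expect_equal(sum(heatmap_grid(rand, 7, 5)), 1, tolerance = 1e-12)

  m0 <- heatmap_grid(one[0, ], 2, 2)
  expect_true(all(m0 == 0))
  expect_true(attr(m0, "empty"))
})

test_that("SUS scoring follows the standard arithmetic and its symmetries", {
  best <- c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)
  worst <- c(1, 5, 1, 5, 1, 5, 1, 5, 1, 5)
  expect_identical(sus_score(best), 100)
  expect_identical(sus_score(worst), 0)
  expect_identical(sus_score(rep(3, 10)), 50)
  # permutation within the odd set and within the even set leaves the score
  set.seed(14)
  for (i in 1:25) {
    items <- sample(1:5, 10, replace = TRUE)
    perm <- items
    perm[seq(1, 9, 2)] <- sample(items[seq(1, 9, 2)])
    perm[seq(2, 10, 2)] <- sample(items[seq(2, 10, 2)])
    expect_identical(sus_score(perm), sus_score(items))
  }
  expect_error(sus_score(rep(3, 9)), "10 items")
  expect_error(sus_score(c(rep(3, 9), 6)), "10 items")
})

test_that("DCS uncertainty subscale scores (mean-1)*25 with 0/100 anchors", {
  expect_identical(dcs_uncertainty(c(1, 1, 1)), 0)
  expect_identical(dcs_uncertainty(c(5, 5, 5)), 100)
  expect_identical(dcs_uncertainty(c(2.3, 2.2, 3.1)), 38.3)
  expect_error(dcs_uncertainty(c(1, 2)), "3 items")
  expect_error(dcs_uncertainty(c(0.5, 2, 2)), "\\[1, 5\\]")
})

test_that("cohort_summary reproduces means, ranges and paired differences", {
  one <- data.frame(participant_id = "p1", measure = "sus", value = 70)
  s1 <- cohort_summary(one)$summary
  expect_equal(s1$mean, 70)

  two <- data.frame(participant_id = c("p1", "p2"), measure = "sus",
                    value = c(68, 85))
  s2 <- cohort_summary(two)$summary
  expect_equal(c(s2$min, s2$max), c(68, 85))

  set.seed(50)
  vals <- runif(30, 0, 100)
  cohort <- data.frame(participant_id = paste0("p", 1:30), measure = "dcs",
                       value = vals)
  # streaming-oracle recomputation of the mean
  acc <- 0; for (v in vals) acc <- acc + v
  expect_equal(cohort_summary(cohort)$summary$mean, acc / 30, tolerance = 1e-12)

  paired <- data.frame(
    participant_id = rep(paste0("p", 1:4), 2),
    mode = rep(c("conventional", "dcida"), each = 4),
    measure = "dcs",
    value = c(50, 60, 40, 55, 40, 45, 35, 50))
  cs <- cohort_summary(paired)
  expect_equal(cs$paired_diff$mean_diff, mean(c(-10, -15, -5, -5)))
})
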