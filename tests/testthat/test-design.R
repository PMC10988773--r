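test_that("set-size control gives 600 presentations, 480 base, 120 deviants", {
  s <- make_sets(30, 30)
  p <- plan_sequence(s$dev, s$base, "set_size", seed = 1)
  expect_equal(nrow(p$stream), 600)
  expect_equal(sum(p$stream$is_deviant), 120)
  expect_equal(sum(!p$stream$is_deviant), 480)
  counts_base <- table(p$stream$label[!p$stream$is_deviant])
  counts_dev <- table(p$stream$label[p$stream$is_deviant])
  expect_true(all(counts_base == 16))
  expect_true(all(counts_dev == 4))
})

test_that("item-repetition control presents all 150 items exactly 4 times", {
  s <- make_sets(30, 120)
  p <- plan_sequence(s$dev, s$base, "item_repetition", seed = 1)
  counts <- table(p$stream$label)
  expect_equal(length(counts), 150L)
  expect_true(all(counts == 4))
})

test_that("deviants recur every 5th presentation with 0.5-s periodicity", {
  s <- make_sets(30, 30)
  p <- plan_sequence(s$dev, s$base, "set_size", seed = 3)
  dev_pos <- p$stream$position[p$stream$is_deviant]
  expect_equal(dev_pos, seq(5, 600, by = 5))
  onsets <- p$stream$onset_s[p$stream$is_deviant]
  expect_equal(unique(round(diff(onsets), 9)), 0.5)
})

test_that("smallest consistent plan places deviants at positions 5 and 10", {
  p <- plan_sequence(stimulus_set(c("da", "db"), "word", "d"),
                     stimulus_set(c("ba", "bb"), "nonword", "b"),
                     "set_size", duration_s = 1, f_base = 10, seed = 0,
                     n_task_events = 0)
  expect_equal(nrow(p$stream), 10)
  expect_equal(which(p$stream$is_deviant), c(5L, 10L))
  lab <- p$stream$label
  expect_true(all(lab[-1] != lab[-length(lab)]))
})

test_that("no plan ever repeats a label on adjacent presentations", {
  s <- make_sets(6, 6)
  for (seed in 1:1000) {
    p <- plan_sequence(s$dev, s$base, "set_size", duration_s = 3,
                       f_base = 10, seed = seed, n_task_events = 0)
    lab <- p$stream$label
    expect_true(all(lab[-1] != lab[-length(lab)]))
  }
  big <- make_sets(30, 30)
  for (seed in 1:25) {
    p <- plan_sequence(big$dev, big$base, "set_size", seed = seed)
    lab <- p$stream$label
    expect_true(all(lab[-1] != lab[-length(lab)]))
  }
})

test_that("plans are byte-for-byte reproducible per seed", {
  s <- make_sets(30, 30)
  p1 <- plan_sequence(s$dev, s$base, "set_size", seed = 11)
  p2 <- plan_sequence(s$dev, s$base, "set_size", seed = 11)
  p3 <- plan_sequence(s$dev, s$base, "set_size", seed = 12)
  expect_identical(p1, p2)
  expect_false(identical(p1$stream$label, p3$stream$label))
})

test_that("mismatched set sizes and infeasible sets raise errors", {
  s <- make_sets(30, 25)
  expect_error(plan_sequence(s$dev, s$base, "set_size", seed = 1),
               "set_size control")
  expect_error(plan_sequence(s$dev, s$base, "item_repetition", seed = 1),
               "item_repetition control")
  one <- stimulus_set("aa", "nonword", "b1")
  expect_error(
    plan_sequence(stimulus_set("dd", "word", "d"), one, "set_size",
                  duration_s = 1, f_base = 10, seed = 1, n_task_events = 0),
    "scheduling error")
})

test_that("cross-task events are all go and respect the minimum gap", {
  ev <- plan_task_events("cross", 8, 60, seed = 3)
  expect_equal(nrow(ev), 8)
  expect_true(all(ev$is_go))
  expect_true(all(ev$kind == "cross_change"))
  expect_true(all(diff(ev$onset_s) >= 1.0 + 0.2 - 1e-9))
  expect_true(all(ev$onset_s >= 0 & ev$onset_s + ev$duration_s <= 60))
  expect_equal(nrow(plan_task_events("bars", 0, 60, seed = 1)), 0)
  expect_error(plan_task_events("cross", 100, 60, seed = 1),
               "scheduling error")
})

test_that("bars-task go count is binomial with expectation 4 of 8", {
  gos <- vapply(1:10000, function(seed) {
    sum(plan_task_events("bars", 8, 60, seed = seed)$is_go)
  }, 0)
  expect_lt(abs(mean(gos) - 4.0), 0.05)
  # no-go sides are equiprobable
  kinds <- unlist(lapply(1:500, function(seed) {
    plan_task_events("bars", 8, 60, seed = seed)$kind
  }))
  n_left <- sum(kinds == "bars_left"); n_right <- sum(kinds == "bars_right")
  expect_lt(abs(n_left / (n_left + n_right) - 0.5), 0.05)
})

test_that("a default session has 24 sequences, 12 per task, blocked", {
  stim <- demo_stimuli(seed = 1)
  s <- plan_session(stim, n_reps = 3, seed = 1)
  expect_equal(length(s$sequences), 24)
  expect_equal(as.integer(table(s$index$task)[c("cross", "bars")]),
               c(12L, 12L))
  # blocked: task changes exactly once along the session
  expect_equal(sum(diff(as.integer(factor(s$index$task,
                                          levels = unique(s$index$task)))) != 0),
               1L)
  # every condition cell appears n_reps times per task
  cells <- table(s$index$task, s$index$discrimination, s$index$control_type)
  expect_true(all(cells == 3))
})

test_that("session scales with n_reps and is deterministic per seed", {
  stim <- demo_stimuli(n_words = 10, seed = 2)
  s1 <- plan_session(stim, n_reps = 1, task_order = c("bars", "cross"),
                     seed = 1, duration_s = 5, n_task_events = 2)
  expect_equal(length(s1$sequences), 8)
  expect_equal(s1$index$task[1], "bars")
  s2 <- plan_session(stim, n_reps = 1, task_order = c("bars", "cross"),
                     seed = 1, duration_s = 5, n_task_events = 2)
  expect_identical(s1, s2)
})

test_that("matching validation flags differing attribute distributions", {
  jit <- with_seed(5, rnorm(30, sd = 1e-3))
  a <- stimulus_set(sprintf("a%02d", 1:30), "word", "a",
                    neighbours = 0 + jit, bigram_freq = 0 + jit)
  b <- stimulus_set(sprintf("b%02d", 1:30), "pseudoword", "b",
                    neighbours = 10 + jit, bigram_freq = 0 + jit)
  r <- validate_matching(a, b)
  expect_true(r$flagged[r$attribute == "neighbours"])
  expect_false(r$flagged[r$attribute == "bigram_freq"])
  # identical sets: p = 1, nothing flagged
  r0 <- validate_matching(a, a)
  expect_true(all(r0$p == 1))
  expect_false(any(r0$flagged))
  # missing attributes error
  c1 <- stimulus_set(sprintf("c%02d", 1:30), "nonword", "c")
  expect_error(validate_matching(a, c1), "validation error")
})

test_that("t statistics match a direct Welch computation", {
  x <- with_seed(7, rnorm(30)); y <- with_seed(8, rnorm(30))
  a <- stimulus_set(sprintf("a%02d", 1:30), "word", "a",
                    neighbours = x, bigram_freq = x)
  b <- stimulus_set(sprintf("b%02d", 1:30), "pseudoword", "b",
                    neighbours = y, bigram_freq = y)
  r <- validate_matching(a, b)
  se <- sqrt(var(x) / 30 + var(y) / 30)
  t_manual <- (mean(x) - mean(y)) / se
  df_manual <- se^4 / ((var(x) / 30)^2 / 29 + (var(y) / 30)^2 / 29)
  p_manual <- 2 * pt(abs(t_manual), df_manual, lower.tail = FALSE)
  expect_equal(r$t[1], t_manual, tolerance = 1e-12)
  expect_equal(r$p[1], p_manual, tolerance = 1e-12)
})

test_that("stimulus sets round-trip through TSV and enforce invariants", {
  expect_error(stimulus_set(c("aa", "aa"), "word"), "unique")
  expect_error(stimulus_set(character(0), "word"), "at least one")
  s <- stimulus_set(c("radio", "tigre"), "word", "w", neighbours = c(1, 2),
                    bigram_freq = c(100, 200))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stimulus_tsv(s, path)
  s2 <- read_stimulus_tsv(path, set_id = "w")
  expect_equal(as.data.frame(s), as.data.frame(s2))
})

test_that("plans export a sidecar and BIDS-style events table", {
  s <- make_sets(6, 6)
  p <- plan_sequence(s$dev, s$base, "set_size", duration_s = 3, f_base = 10,
                     seed = 1, n_task_events = 1)
  stem <- file.path(withr::local_tempdir(), "seq")
  paths <- write_plan(p, stem)
  expect_true(all(file.exists(paths)))
  ev <- read.delim(paths[2])
  expect_equal(sum(ev$trial_type == "deviant"), 6)
  expect_false(is.unsorted(ev$onset))
})
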