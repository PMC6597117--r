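test_that("trace update is the low-pass filter on both object rows", {
  p <- ost_params("M1", alpha = 0.6, beta = 0)
  s <- new_trace_state(0)
  s <- update_trace(s, list(loc_obj1 = 1, loc_obj2 = 3), p)
  expect_equal(s$m[1, ], c(0.6, 0, 0, 0))
  expect_equal(s$m[2, ], c(0, 0, 0.6, 0))
  expect_equal(s$trial_index, 1L)

  # full-overwrite limit: alpha = 1 makes each row one-hot
  p1 <- ost_params("M1", alpha = 1, beta = 0)
  s1 <- new_trace_state(0.7)
  s1 <- update_trace(s1, list(loc_obj1 = 2, loc_obj2 = 4), p1)
  expect_equal(s1$m[1, ], c(0, 1, 0, 0))
  expect_equal(s1$m[2, ], c(0, 0, 0, 1))
})

test_that("repeated observation follows the geometric closed form 1 - (1-alpha)^n", {
  alpha <- 0.6
  p <- ost_params("M1", alpha, 0)
  s <- new_trace_state(0)
  for (n in 1:8) {
    s <- update_trace(s, list(loc_obj1 = 1, loc_obj2 = 2), p)
    expect_equal(s$m[1, 1], 1 - (1 - alpha)^n, tolerance = 1e-12)
  }
})

test_that("day forgetting pulls traces toward m0 and is restricted to M2/M3", {
  s <- new_trace_state(0)
  s$m[] <- 1
  # gamma = 1: no forgetting
  s_keep <- apply_day_forgetting(s, ost_params("M2", 0.5, 0, gamma = 1))
  expect_equal(s_keep$m, s$m)
  # gamma = 0, m0 = 0: full overnight reset
  s_reset <- apply_day_forgetting(s, ost_params("M2", 0.5, 0, gamma = 0))
  expect_equal(s_reset$m, matrix(0, 2, 4))
  # direct substitution: gamma = 0.36, m = 1, m0 = 0 -> 0.36
  s_part <- apply_day_forgetting(s, ost_params("M2", 0.5, 0, gamma = 0.36))
  expect_equal(s_part$m[1, 1], 0.36, tolerance = 1e-12)
  # attractor above current value pulls upward (M3, free m0)
  s0 <- new_trace_state(0)
  s_up <- apply_day_forgetting(s0, ost_params("M3", 0.5, 0, gamma = 0.5,
                                              m0 = 2))
  expect_equal(s_up$m[1, 1], 1)
  expect_error(apply_day_forgetting(s, ost_params("M1", 0.5, 0)), "M2")
})

test_that("trace entropy matches hand-computed values and conventions", {
  s <- new_trace_state(0)
  s$m[1, ] <- c(0.25, 0.25, 0.25, 0.25)
  expect_equal(trace_entropy(s, 1), log(4), tolerance = 1e-12)
  s$m[1, ] <- c(0.7, 0, 0, 0)       # normalizes to one-hot
  expect_equal(trace_entropy(s, 1), 0)
  s$m[1, ] <- c(0.5, 0.5, 0, 0)     # two-point uniform
  expect_equal(trace_entropy(s, 1), log(2), tolerance = 1e-12)
  s$m[1, ] <- c(0, 0, 0, 0)         # all-zero row: maximal uncertainty
  expect_equal(trace_entropy(s, 1), log(4))
})

test_that("entropy is invariant under location permutations and bounded", {
  set.seed(42)
  s <- new_trace_state(0)
  for (i in 1:50) {
    row <- runif(4)
    s$m[1, ] <- row
    e <- trace_entropy(s, 1)
    expect_gte(e, 0)
    expect_lte(e, log(4) + 1e-12)
    s$m[2, ] <- row[sample(4)]
    expect_equal(trace_entropy(s, 2), e, tolerance = 1e-12)
  }
})

test_that("softmax allocation matches hand evaluation and limit behavior", {
  # beta = 0: no preference whatever the entropies
  p0 <- allocation_probabilities(1.2, 0.3, ost_params("M1", 0.5, 0))
  expect_equal(unname(p0), c(0.5, 0.5))
  # the simulation parameters: S = (log 4, 0), beta = 0.2
  p <- allocation_probabilities(log(4), 0, ost_params("M1", 0.6, 0.2))
  expect_equal(unname(p[1]), exp(0.2 * log(4)) / (exp(0.2 * log(4)) + 1),
               tolerance = 1e-12)
  expect_equal(unname(p[1]), 0.56887, tolerance = 1e-4)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # neophobia limit: beta -> -Inf prefers the certain object
  plim <- allocation_probabilities(0, log(4), ost_params("M1", 0.5, -1e6))
  expect_equal(unname(plim[1]), 1)
})

test_that("allocation is symmetric under argument swap and beta sign flip", {
  par_pos <- ost_params("M1", 0.5, 1.3)
  par_neg <- ost_params("M1", 0.5, -1.3)
  for (S in list(c(0.2, 1.1), c(1.3, 0.4), c(0.8, 0.8))) {
    a <- allocation_probabilities(S[1], S[2], par_pos)
    b <- allocation_probabilities(S[2], S[1], par_pos)
    expect_equal(unname(a), unname(rev(b)), tolerance = 1e-12)
    flipped <- allocation_probabilities(S[1], S[2], par_neg)
    if (S[1] != S[2]) {
      expect_equal(unname(flipped[1]), unname(a[2]), tolerance = 1e-12)
    }
  }
})

test_that("traces stay in [0, 1] for any update/forgetting sequence with m0 in [0, 1]", {
  set.seed(7)
  for (rep in 1:20) {
    m0 <- runif(1)
    model <- sample(c("M2", "M3"), 1)
    p <- ost_params(model, runif(1), rnorm(1), gamma = runif(1),
                    m0 = if (model == "M3") m0 else NULL)
    s <- new_trace_state(if (model == "M3") m0 else 0)
    for (t in 1:30) {
      locs <- sample(4, 2)
      s <- update_trace(s, list(loc_obj1 = locs[1], loc_obj2 = locs[2]), p)
      if (runif(1) < 0.3) s <- apply_day_forgetting(s, p)
      expect_true(all(s$m >= 0 & s$m <= 1))
    }
  }
})

test_that("M1 with alpha near 0 reproduces the exact-counter entropy ranking", {
  # oracle: perfect counts (increment observed cell by 1, no decay),
  # normalized per row
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    l1 <- sample(4, n, replace = TRUE)
    l2 <- vapply(l1, function(x) sample(setdiff(1:4, x), 1), integer(1))
    counts1 <- counts2 <- rep(0, 4)
    p <- ost_params("M1", 1e-6, 0)
    s <- new_trace_state(0)
    for (t in 1:n) {
      counts1[l1[t]] <- counts1[l1[t]] + 1
      counts2[l2[t]] <- counts2[l2[t]] + 1
      s <- update_trace(s, list(loc_obj1 = l1[t], loc_obj2 = l2[t]), p)
    }
    ent <- function(cnt) {
      q <- cnt / sum(cnt); q <- q[q > 0]; -sum(q * log(q))
    }
    zsign <- function(x) sign(x) * (abs(x) > 1e-4)  # treat near-ties as ties
    oracle_order <- zsign(ent(counts1) - ent(counts2))
    model_order <- zsign(trace_entropy(s, 1) - trace_entropy(s, 2))
    expect_equal(model_order, oracle_order)
  }
})

test_that("session run predicts from the just-updated trace", {
  sch <- generate_session("stable", "rat_2day", 0, seed = 1)
  p <- ost_params("M1", 0.95, 0.2)
  out <- run_trace_model(sch, p)
  expect_equal(nrow(out), 6L)
  # trial 1: both rows one-hot after the first update -> equal entropies
  expect_equal(out$p_obj1[1], 0.5)
  # high alpha: near-zero entropies through the samples ...
  expect_true(all(out$S_obj1[2:5] < 0.25))
  expect_true(all(out$S_obj2[2:5] < 0.25))
  # ... and a jump for the moved object at test, not for the stable one
  expect_gt(out$S_obj2[6], 0.15)
  expect_lt(out$S_obj1[6], 1e-6)
  expect_gt(out$p_obj2[6], 0.5)
})

test_that("overlapping build-up: the moving object's allocation rises on average", {
  p <- ost_params("M1", 0.6, 0.2)
  probs <- sapply(1:12, function(cb) {
    sch <- generate_session("overlapping", "rat_2day", cb - 1, seed = cb)
    run_trace_model(sch, p)$p_obj2
  })
  avg <- rowMeans(probs)
  expect_equal(avg[1], 0.5)
  expect_gt(avg[5], avg[1])
  expect_gt(avg[6], 0.5)  # test trial keeps the preference
  expect_true(all(diff(avg[1:5]) > -0.02))  # monotone up to schedule noise
})

test_that("alpha = 1 predictions depend only on the current trial", {
  p <- ost_params("M1", 1, 5)
  sch1 <- generate_session("overlapping", "rat_2day", 0, seed = 1)
  sch2 <- generate_session("random", "rat_2day", 0, seed = 5)
  o1 <- run_trace_model(sch1, p)
  o2 <- run_trace_model(sch2, p)
  # one-hot traces every trial: zero entropies, chance allocation always
  expect_equal(o1$p_obj1, rep(0.5, 6))
  expect_equal(o2$p_obj1, rep(0.5, 6))
})

test_that("M2 overnight forgetting resets traces when gamma = 0", {
  sch <- generate_session("stable", "mouse_5day", 0, seed = 1)
  p_forget <- ost_params("M2", 0.6, 0.2, gamma = 0)
  out <- run_trace_model(sch, p_forget)
  # first trial of each day behaves like trial 1: full reset -> p = 0.5
  first_of_day <- !duplicated(sch$day)
  expect_equal(out$p_obj1[first_of_day], rep(0.5, 5))
  # gamma = 1 must reproduce M1 exactly
  p_keep <- ost_params("M2", 0.6, 0.2, gamma = 1)
  p_m1 <- ost_params("M1", 0.6, 0.2)
  expect_equal(run_trace_model(sch, p_keep)$p_obj1,
               run_trace_model(sch, p_m1)$p_obj1, tolerance = 1e-12)
})

test_that("unordered trials are rejected", {
  sch <- generate_session("stable", "rat_2day", 0, seed = 1)
  expect_error(run_trace_model(sch[c(2, 1, 3:6), ], ost_params("M1", 0.5, 0)),
               "ordered")
})
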