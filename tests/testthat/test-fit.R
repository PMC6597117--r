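test_that("chance log-likelihood is N log(1/2)", {
  expect_equal(chance_log_likelihood(1), log(0.5))
  expect_equal(chance_log_likelihood(1), -0.6931, tolerance = 1e-4)
  expect_equal(chance_log_likelihood(6), -4.1589, tolerance = 1e-4)
  expect_equal(chance_log_likelihood(21), -14.556, tolerance = 1e-3)
  expect_error(chance_log_likelihood(0))
})

test_that("beta = 0 likelihood equals chance for any data and alpha", {
  sch <- generate_session("overlapping", "rat_2day", 0, seed = 1)
  set.seed(3)
  beh <- behavior_from_props(sch, runif(6))
  for (a in c(0.1, 0.5, 0.9)) {
    ll <- session_log_likelihood(beh, sch, ost_params("M1", a, 0))
    expect_equal(as.numeric(ll), 6 * log(0.5), tolerance = 1e-12)
  }
})

test_that("session likelihood is the proportion-weighted cross-entropy", {
  sch <- generate_session("overlapping", "mouse_5day", 1, seed = 2)
  set.seed(4)
  q <- runif(21)
  beh <- behavior_from_props(sch, q)
  params <- ost_params("M1", 0.55, 2.3)
  ll <- session_log_likelihood(beh, sch, params)
  # independent recomputation from the prediction table
  p <- run_trace_model(sch, params)$p_obj1
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  expect_equal(as.numeric(ll), sum(q * log(p) + (1 - q) * log(1 - p)),
               tolerance = 1e-10)
  # single-trial hand value: q = p -> q log q + (1-q) log(1-q)
  expect_equal(0.7 * log(0.7) + 0.3 * log(0.3), -0.6109, tolerance = 1e-4)
})

test_that("zero-exploration trials are skipped, not propagated", {
  sch <- generate_session("overlapping", "rat_2day", 0, seed = 1)
  beh <- behavior_from_props(sch, rep(0.6, 6))
  beh$time_obj1_s[3] <- 0
  beh$time_obj2_s[3] <- 0
  ll <- session_log_likelihood(beh, sch, ost_params("M1", 0.5, 0))
  expect_equal(as.numeric(ll), 5 * log(0.5), tolerance = 1e-12)
  expect_equal(attr(ll, "n_skipped"), 1L)
  fit <- fit_ost(beh, sch, "M1", n_starts = 20, seed = 1)
  expect_equal(fit$n_trials, 5L)
  expect_equal(fit$n_skipped, 1L)
})

test_that("likelihood is invariant to a joint slot relabeling", {
  sch <- generate_session("random", "rat_2day", 0, seed = 7)
  set.seed(8)
  q <- runif(6)
  beh <- behavior_from_props(sch, q)
  params <- ost_params("M1", 0.4, 1.7)
  ll <- session_log_likelihood(beh, sch, params)
  swapped <- sch
  swapped$loc_slot1 <- sch$loc_slot2
  swapped$loc_slot2 <- sch$loc_slot1
  beh_sw <- behavior_from_props(swapped, 1 - q)
  ll_sw <- session_log_likelihood(beh_sw, swapped, params)
  expect_equal(as.numeric(ll), as.numeric(ll_sw), tolerance = 1e-12)
})

test_that("uninformative data fit to chance with zero pseudo-R2", {
  sch <- generate_session("overlapping", "mouse_5day", 0, seed = 1)
  beh <- behavior_from_props(sch, rep(0.5, 21))
  fit <- fit_ost(beh, sch, "M1", n_starts = 30, seed = 2)
  expect_equal(fit$ll_opt, fit$ll_chance, tolerance = 1e-6)
  expect_equal(fit$pseudo_r2, 0, tolerance = 1e-6)
})

test_that("fits are deterministic given the seed and never below chance", {
  sch <- generate_session("overlapping", "rat_2day", 0, seed = 1)
  sim <- simulate_session(sch, ost_params("M1", 0.7, 3), noise_sd = 0.1,
                          seed = 5)
  f1 <- fit_ost(sim$behavior, sch, "M1", n_starts = 40, seed = 6)
  f2 <- fit_ost(sim$behavior, sch, "M1", n_starts = 40, seed = 6)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$ll_opt, f2$ll_opt)
  expect_gte(f1$ll_opt, f1$ll_chance - 1e-9)
  expect_gte(f1$pseudo_r2, 0)
})

test_that("simulated parameters are recovered from 20-trial sessions", {
  errs <- sapply(1:3, function(i) {
    sch <- generate_session("overlapping", "mouse_5day", i - 1, seed = i)
    sim <- simulate_session(sch, ost_params("M1", 0.6, 5), noise_sd = 0.05,
                            seed = 10 + i)
    fit <- fit_ost(sim$behavior, sch, "M1", n_starts = 100, seed = 20 + i)
    c(abs(coef(fit)["alpha"] - 0.6), sign(coef(fit)["beta"]))
  })
  expect_lte(median(errs[1, ]), 0.2)
  expect_true(all(errs[2, ] == 1))
})

test_that("the model object supports the standard S3 accessors", {
  sch <- generate_session("overlapping", "mouse_5day", 0, seed = 1)
  sim <- simulate_session(sch, ost_params("M1", 0.6, 5), noise_sd = 0.05,
                          seed = 2)
  fit <- fit_ost(sim$behavior, sch, "M1", n_starts = 50, seed = 3)
  expect_s3_class(fit, "ost_fit")
  expect_named(coef(fit), c("alpha", "beta"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 2L)
  expect_equal(attr(ll, "nobs"), 21L)
  expect_equal(AIC(fit), 2 * 2 - 2 * fit$ll_opt)
  expect_equal(BIC(fit), 2 * log(21) - 2 * fit$ll_opt)
  pred <- predict(fit)
  expect_equal(nrow(pred), 21L)
  expect_equal(pred$p_obj1, fit$p, tolerance = 1e-12)
  res <- residuals(fit)
  expect_length(res, 21L)
  expect_equal(res, fit$q - fit$p)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_equal(sims[[1]]$proportions, fit$p, tolerance = 1e-12)
  expect_output(print(summary(fit)), "pseudo-R2")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("likelihood-ratio test against chance follows the chi-square", {
  f0 <- fake_fit("M1", ll = -14.556, n = 21, ll_chance = -14.556)
  lr0 <- likelihood_ratio_vs_chance(f0)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  f1 <- fake_fit("M1", ll = -11.556, n = 21, ll_chance = -14.556)
  lr1 <- likelihood_ratio_vs_chance(f1)
  expect_equal(lr1$statistic, 6, tolerance = 1e-12)
  expect_equal(lr1$df, 2L)
  expect_equal(lr1$p_value, 0.0498, tolerance = 1e-3)
})

test_that("information criteria sum the per-session penalized deviances", {
  one <- information_criteria(list(fake_fit("M1", ll = -10, n = 21)))
  expect_equal(one$aic_total, 24)
  expect_equal(one$bic_total, 2 * log(21) + 20, tolerance = 1e-10)
  two <- information_criteria(list(fake_fit("M2", ll = -10, n = 21,
                                            ll_chance = -14),
                                   fake_fit("M2", ll = -8, n = 6,
                                            ll_chance = -4.2)))
  expect_equal(two$aic_total, (6 + 20) + (6 + 16))
  expect_equal(two$bic_total, 3 * log(21) + 20 + 3 * log(6) + 16,
               tolerance = 1e-10)
  expect_error(information_criteria(list()), "no fits")
  expect_error(information_criteria(list(fake_fit("M1"), fake_fit("M2"))),
               "share one model")
})

test_that("fitting the brute-force grid optimum on a short session", {
  # 2-parameter M1, 6 trials: a coarse grid must not beat the optimizer
  sch <- generate_session("overlapping", "rat_2day", 1, seed = 3)
  sim <- simulate_session(sch, ost_params("M1", 0.5, 4), noise_sd = 0.1,
                          seed = 4)
  fit <- fit_ost(sim$behavior, sch, "M1", n_starts = 60, seed = 5)
  q <- sim$behavior$time_obj1_s / 40
  grid_best <- -Inf
  for (a in seq(0.005, 0.995, length.out = 60)) {
    pred <- run_trace_model(sch, ost_params("M1", a, 1))
    dS <- qlogis(pmin(pmax(pred$p_obj1, 1e-12), 1 - 1e-12))  # beta=1 logits
    for (b in seq(-20, 20, length.out = 60)) {
      p <- pmin(pmax(plogis(b * dS), 1e-12), 1 - 1e-12)
      ll <- sum(q * log(p) + (1 - q) * log(1 - p))
      if (ll > grid_best) grid_best <- ll
    }
  }
  expect_gte(fit$ll_opt, grid_best - 1e-3)
})

test_that("cohort fitting produces the tidy per-session table", {
  ds <- generate_dataset(cohort_spec(n_animals = 2, protocol = "rat_2day",
                                     conditions = c("stable", "overlapping"),
                                     seed = 6))
  fl <- fit_cohort(ds, "M1", n_starts = 30, seed = 7)
  expect_equal(nrow(fl$table), 4L)
  expect_true(all(c("animal_id", "condition", "alpha", "beta", "ll",
                    "pseudo_r2", "aic", "bic", "lr_p", "beta_outlier") %in%
                  names(fl$table)))
  expect_true(all(fl$table$pseudo_r2 >= 0))
  # single-session summaries: SEM is NA, no error
  ds1 <- generate_dataset(cohort_spec(n_animals = 1, protocol = "rat_2day",
                                      conditions = "overlapping", seed = 8))
  cmp1 <- compare_ost_models(ds1, models = "M1", n_starts = 20, seed = 9)
  expect_true(is.na(cmp1$table$sem_alpha))
  expect_false(is.na(cmp1$table$mean_alpha))
})
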