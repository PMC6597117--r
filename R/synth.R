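#' Specify a synthetic cohort
#'
#' Defines the generative assumptions of a synthetic Object Space Task
#' dataset: latent per-animal model parameters, proportion noise, an
#' exploration-time profile with within-day habituation and across-day
#' recovery, and optionally some deliberately low-exploring animals that
#' trigger the exclusion rule downstream.
#'
#' Population heterogeneity: `alpha` is drawn on the logit scale (so draws
#' stay in (0, 1)); `beta` is Gaussian. Total exploration time per trial
#' is lognormal around the profile mean, so totals are positive and
#' right-skewed as exploration durations are.
#'
#' @param n_animals number of animals (>= 1).
#' @param protocol schedule protocol.
#' @param conditions conditions to run (default all three; `mouse_4week`
#'   forces overlapping).
#' @param alpha_population `c(mean, sd)` of alpha on the logit scale;
#'   default `qlogis(0.6), 0.5` (median alpha 0.6, the value that
#'   reproduces the task's average behavioral curves).
#' @param beta_population `c(mean, sd)` of beta; default `c(5, 2)`.
#' @param noise_sd additive truncated-Gaussian noise on per-trial
#'   proportions (default 0.05).
#' @param time_profile list with `base_s` (mean total seconds on day 1
#'   trial 1, default 35), `trial_slope` (per-trial log-scale habituation
#'   within a day, default -0.05), `day_slope` (per-day log-scale change,
#'   default -0.03) and `sdlog` (lognormal spread, default 0.25).
#' @param exclusion_plants number of animals whose exploration times are
#'   scaled to near zero so that [apply_exclusions()] removes them.
#' @param seed master seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 30L, protocol = "rat_2day",
                        conditions = NULL,
                        alpha_population = c(mean = qlogis(0.6), sd = 0.5),
                        beta_population = c(mean = 5, sd = 2),
                        noise_sd = 0.05,
                        time_profile = list(base_s = 35, trial_slope = -0.05,
                                            day_slope = -0.03, sdlog = 0.25),
                        exclusion_plants = 0L, seed = 1L) {
  stopifnot(n_animals >= 1, noise_sd >= 0, time_profile$base_s > 0)
  if (exclusion_plants > n_animals)
    stop("exclusion_plants (", exclusion_plants,
         ") cannot exceed n_animals (", n_animals, ")")
  protocol <- match.arg(protocol, .ost_protocols)
  if (is.null(conditions))
    conditions <- if (protocol == "mouse_4week") "overlapping"
                  else .ost_conditions
  stopifnot(length(alpha_population) == 2, length(beta_population) == 2)
  alpha_population <- setNames(as.numeric(alpha_population), c("mean", "sd"))
  beta_population <- setNames(as.numeric(beta_population), c("mean", "sd"))
  structure(list(n_animals = as.integer(n_animals), protocol = protocol,
                 conditions = conditions,
                 alpha_population = alpha_population,
                 beta_population = beta_population, noise_sd = noise_sd,
                 time_profile = time_profile,
                 exclusion_plants = as.integer(exclusion_plants),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# mean per-trial total time (log scale) for the habituation profile
profile_log_mean <- function(tp, day, trial_in_day) {
  day_index <- match(day, sort(unique(day)))  # calendar gaps don't habituate
  log(tp$base_s) + tp$trial_slope * (trial_in_day - 1) +
    tp$day_slope * (day_index - 1)
}

# simulate one session's behavior rows from latent (alpha, beta); all
# randomness (proportion noise + time draws) flows from `seed`, so a
# session is reproducible from the truth table alone
simulate_behavior_session <- function(schedule, alpha, beta, spec, seed,
                                      time_scale = 1) {
  params <- ost_params("M1", alpha, beta)
  pred <- run_trace_model(schedule, params)
  n <- nrow(schedule)
  with_seed(seed, {
    prop <- pred$p_obj1
    if (spec$noise_sd > 0)
      prop <- pmin(pmax(prop + rnorm(n, 0, spec$noise_sd), 0), 1)
    tp <- spec$time_profile
    mu <- profile_log_mean(tp, schedule$day, schedule$trial_in_day)
    tot <- rlnorm(n, meanlog = mu, sdlog = tp$sdlog) * time_scale
    full_factor <- 1 + rlnorm(n, meanlog = log(0.8), sdlog = 0.2)
    beh <- data.frame(
      animal_id = schedule$animal_id,
      condition = schedule$condition,
      day = schedule$day,
      trial_in_day = schedule$trial_in_day,
      phase = schedule$phase,
      loc_slot1 = schedule$loc_slot1,
      loc_slot2 = schedule$loc_slot2,
      time_obj1_s = prop * tot,
      time_obj2_s = (1 - prop) * tot,
      time_obj1_full_s = prop * tot,
      time_obj2_full_s = (1 - prop) * tot,
      stringsAsFactors = FALSE)
    # test trials carry both a first-5-min score (the default analysis
    # window) and a longer full-10-min score
    is_test <- schedule$phase %in% c("test", "delayed_test")
    beh$time_obj1_full_s[is_test] <- beh$time_obj1_s[is_test] *
      full_factor[is_test]
    beh$time_obj2_full_s[is_test] <- beh$time_obj2_s[is_test] *
      full_factor[is_test]
    beh
  })
}

#' Generate a complete synthetic dataset
#'
#' Draws per-animal latent parameters from the population, builds
#' counterbalanced schedules via [generate_cohort()], simulates per-trial
#' exploration proportions with the memory-trace model, converts them to
#' seconds with the habituation time profile, and records the ground
#' truth. Fully reproducible from the spec's seed; each session's noise
#' uses the substream seed recorded in the truth table, so behavior can be
#' regenerated from (schedule, truth, spec) alone.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `ost_dataset` with data frames `schedule`,
#'   `behavior` and `truth` (`animal_id, condition, alpha, beta, gamma,
#'   m0, seed_substream`), plus the `spec`.
#' @examples
#' ds <- generate_dataset(cohort_spec(n_animals = 4, seed = 7))
#' head(ds$truth)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  schedule <- generate_cohort(spec$n_animals, spec$protocol,
                              seed = substream_seed(spec$seed, "schedules"),
                              conditions = spec$conditions)
  animals <- unique(schedule$animal_id)
  latent <- with_seed(substream_seed(spec$seed, "latent"), {
    data.frame(
      animal_id = animals,
      alpha = plogis(rnorm(length(animals), spec$alpha_population[["mean"]],
                           spec$alpha_population[["sd"]])),
      beta = rnorm(length(animals), spec$beta_population[["mean"]],
                   spec$beta_population[["sd"]]),
      stringsAsFactors = FALSE)
  })
  planted <- head(animals, spec$exclusion_plants)

  sessions <- as_session_list(schedule)
  beh <- list()
  truth <- list()
  for (s in sessions) {
    aid <- s$animal_id[1]; cond <- s$condition[1]
    row <- latent[latent$animal_id == aid, ]
    sseed <- substream_seed(spec$seed, "behavior", aid, cond)
    beh[[paste(aid, cond)]] <- simulate_behavior_session(
      s, row$alpha, row$beta, spec, sseed,
      time_scale = if (aid %in% planted) 0.01 else 1)
    truth[[paste(aid, cond)]] <- data.frame(
      animal_id = aid, condition = cond, alpha = row$alpha, beta = row$beta,
      gamma = NA_real_, m0 = 0, seed_substream = sseed,
      stringsAsFactors = FALSE)
  }
  structure(list(
    schedule = schedule,
    behavior = do.call(rbind, c(beh, list(make.row.names = FALSE))),
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    spec = spec),
    class = "ost_dataset")
}

#' @export
print.ost_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d animals, %s, conditions %s\n",
              x$spec$n_animals, x$spec$protocol,
              paste(x$spec$conditions, collapse = "/")))
  cat(sprintf("  %d schedule rows, %d behavior rows\n", nrow(x$schedule),
              nrow(x$behavior)))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Generates a synthetic dataset, fits every session, and reports how well
#' the latent parameters are recovered: per-parameter bias, mean absolute
#' error, truth-vs-estimate correlation and the fraction of sessions with
#' the sign of beta recovered.
#'
#' @param spec a [cohort_spec()].
#' @param model model to fit (the generator itself is M1).
#' @param n_starts,seed passed to [fit_cohort()].
#' @return a list of class `ost_recovery`: `table` (per-session truth and
#'   estimates), `summary` (bias/MAE/correlation per parameter,
#'   `beta_sign_rate`), and the underlying `fits`.
#' @export
recovery_experiment <- function(spec, model = "M1", n_starts = 200L,
                                seed = 1L) {
  ds <- generate_dataset(spec)
  fl <- fit_cohort(ds, model, n_starts = n_starts, seed = seed)
  tab <- merge(ds$truth[, c("animal_id", "condition", "alpha", "beta")],
               fl$table[, c("animal_id", "condition", "alpha", "beta",
                            "pseudo_r2", "beta_outlier")],
               by = c("animal_id", "condition"),
               suffixes = c("_true", "_hat"))
  param_summary <- function(true, hat) {
    list(bias = mean(hat - true), mae = mean(abs(hat - true)),
         cor = if (length(true) > 2 && sd(true) > 0 && sd(hat) > 0)
           stats::cor(true, hat) else NA_real_)
  }
  summary <- list(
    alpha = param_summary(tab$alpha_true, tab$alpha_hat),
    beta = param_summary(tab$beta_true, tab$beta_hat),
    beta_sign_rate = mean(sign(tab$beta_hat) == sign(tab$beta_true)),
    n_sessions = nrow(tab))
  structure(list(table = tab, summary = summary, fits = fl),
            class = "ost_recovery")
}

#' @export
print.ost_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Parameter recovery over %d sessions:\n", s$n_sessions))
  cat(sprintf("  alpha: bias %+.3f, MAE %.3f, cor %.2f\n", s$alpha$bias,
              s$alpha$mae, s$alpha$cor))
  cat(sprintf("  beta:  bias %+.3f, MAE %.3f, cor %.2f; sign recovered %.0f%%\n",
              s$beta$bias, s$beta$mae, s$beta$cor, 100 * s$beta_sign_rate))
  invisible(x)
}
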