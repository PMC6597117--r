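#' Simulate a model agent over one session schedule
#'
#' Runs the memory-trace model over the session and converts allocation
#' probabilities into simulated exploration behavior. The slot-1
#' (stable-role) exploration proportion of trial t is
#' `clamp(p_obj1 + e_t, 0, 1)` with `e_t ~ N(0, noise_sd)`; with
#' `noise_sd = 0` the simulation is a pure function of the schedule and
#' parameters.
#'
#' @param schedule a single-session `ost_schedule` data frame.
#' @param params an [ost_params()] object.
#' @param noise_sd standard deviation of the additive truncated Gaussian
#'   proportion noise (>= 0, default 0).
#' @param seed seed for the noise draws (ignored when `noise_sd = 0`).
#' @param total_time_s per-trial total exploration seconds; a scalar
#'   (default nominal 40 s) or a vector of length `nrow(schedule)`. Total
#'   times do not affect the DI of proportions.
#' @param forget_test_delay passed to [run_trace_model()].
#' @return a list of class `ost_simulation` with elements `schedule`,
#'   `params`, `predictions` (the [run_trace_model()] output),
#'   `proportions` (slot-1 proportion per trial), `total_time_s` and
#'   `behavior`, a behavior-format data frame with columns `animal_id,
#'   condition, day, trial_in_day, phase, loc_slot1, loc_slot2,
#'   time_obj1_s, time_obj2_s`.
#' @examples
#' sch <- generate_session("overlapping", "rat_2day", 0, 1)
#' sim <- simulate_session(sch, ost_params("M1", 0.6, 0.2))
#' sim$proportions
#' @export
simulate_session <- function(schedule, params, noise_sd = 0, seed = 1L,
                             total_time_s = 40, forget_test_delay = TRUE) {
  stopifnot(noise_sd >= 0)
  pred <- run_trace_model(schedule, params, forget_test_delay)
  n <- nrow(schedule)
  prop <- pred$p_obj1
  if (noise_sd > 0) {
    eps <- with_seed(seed, rnorm(n, 0, noise_sd))
    prop <- pmin(pmax(prop + eps, 0), 1)
  }
  tt <- rep_len(total_time_s, n)
  stopifnot(all(tt > 0))
  behavior <- data.frame(
    animal_id = schedule$animal_id,
    condition = schedule$condition,
    day = schedule$day,
    trial_in_day = schedule$trial_in_day,
    phase = schedule$phase,
    loc_slot1 = schedule$loc_slot1,
    loc_slot2 = schedule$loc_slot2,
    time_obj1_s = prop * tt,
    time_obj2_s = (1 - prop) * tt,
    stringsAsFactors = FALSE)
  structure(list(schedule = schedule, params = params, predictions = pred,
                 proportions = prop, total_time_s = tt, behavior = behavior),
            class = "ost_simulation")
}

#' @export
print.ost_simulation <- function(x, ...) {
  cat(sprintf("Simulated %s session (%s, %d trials), model %s\n",
              x$schedule$condition[1], x$schedule$protocol[1],
              nrow(x$schedule), x$params$model))
  cat(sprintf("  alpha = %.3g, beta = %.3g; test-trial DI = %.3f\n",
              x$params$alpha, x$params$beta,
              simulated_di(x)[nrow(x$schedule)]))
  invisible(x)
}

# per-trial DI of a simulation: slot 2 is the novel-role slot, so
# DI = (time_novel - time_stable) / total = 1 - 2 * proportion_slot1
simulated_di <- function(sim) {
  mapply(discrimination_index,
         time_novel_s = (1 - sim$proportions) * sim$total_time_s,
         time_stable_s = sim$proportions * sim$total_time_s)
}

#' Simulate a cohort of sessions
#'
#' @param schedules a list of single-session schedules, or a multi-session
#'   `ost_schedule` data frame (split on animal x condition).
#' @param params_per_session one [ost_params()] for all sessions, or a list
#'   with one element per session.
#' @param noise_sd,total_time_s,forget_test_delay as [simulate_session()].
#' @param seed master seed; each session uses an independent substream.
#' @return a list of `ost_simulation` objects.
#' @export
simulate_cohort <- function(schedules, params_per_session, noise_sd = 0,
                            seed = 1L, total_time_s = 40,
                            forget_test_delay = TRUE) {
  schedules <- as_session_list(schedules)
  n <- length(schedules)
  if (inherits(params_per_session, "ost_params"))
    params_per_session <- rep(list(params_per_session), n)
  if (length(params_per_session) != n)
    stop("need one parameter set per session (", n, " sessions, ",
         length(params_per_session), " parameter sets)")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- schedules[[i]]
    out[[i]] <- simulate_session(
      s, params_per_session[[i]], noise_sd,
      seed = substream_seed(seed, s$animal_id[1], s$condition[1], "sim"),
      total_time_s = total_time_s, forget_test_delay = forget_test_delay)
  }
  out
}

# split a stacked schedule data frame into single sessions, in a stable
# order (animal then condition as first encountered)
as_session_list <- function(schedules) {
  if (is.data.frame(schedules)) {
    key <- paste(schedules$animal_id, schedules$condition, schedules$protocol)
    idx <- split(seq_len(nrow(schedules)), factor(key, levels = unique(key)))
    schedules <- lapply(idx, function(i) {
      s <- schedules[i, , drop = FALSE]
      s[order(s$day, s$trial_in_day), , drop = FALSE]
    })
  }
  schedules
}

#' Sweep the (alpha, beta) parameter grid
#'
#' For every grid cell, `n_sessions` counterbalanced sessions are
#' simulated without noise and the mean DI at the last sample trial and at
#' the test trial recorded. Reproduces the task's characteristic parameter
#' landscape: a build-up of positive DI in overlapping for small alpha and
#' positive beta, its absence for alpha >= 0.9, a stable-test DI peaking
#' near alpha = 0.5, and sign reversal under negative beta.
#'
#' @param alpha_grid,beta_grid numeric vectors of parameter values.
#' @param condition,protocol schedule arguments.
#' @param n_sessions sessions per cell (counterbalance slots rotate).
#' @param seed master seed for schedule generation.
#' @param model model id; extra parameters for M2--M4 via `gamma`, `m0`.
#' @param gamma,m0 optional extra parameters passed to [ost_params()].
#' @return a data frame `alpha, beta, di_last_sample, di_test`.
#' @export
sweep_parameters <- function(alpha_grid, beta_grid, condition = "overlapping",
                             protocol = "rat_2day", n_sessions = 8L,
                             seed = 1L, model = "M1", gamma = NULL,
                             m0 = NULL) {
  stopifnot(length(alpha_grid) >= 1, length(beta_grid) >= 1, n_sessions >= 1)
  schedules <- lapply(seq_len(n_sessions), function(i)
    generate_session(condition, protocol,
                     counterbalance_slot = i - 1L,
                     seed = substream_seed(seed, "sweep", i),
                     animal_id = sprintf("a%02d", i)))
  grid <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  di_last <- numeric(nrow(grid))
  di_test <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- ost_params(model, grid$alpha[g], grid$beta[g], gamma = gamma,
                    m0 = m0)
    dl <- dt <- numeric(length(schedules))
    for (j in seq_along(schedules)) {
      sim <- simulate_session(schedules[[j]], p, noise_sd = 0)
      di <- simulated_di(sim)
      test_idx <- which(sim$schedule$phase %in% c("test", "delayed_test"))
      test_idx <- test_idx[length(test_idx)]
      sample_idx <- max(which(sim$schedule$phase == "sample"))
      dl[j] <- di[sample_idx]
      dt[j] <- di[test_idx]
    }
    di_last[g] <- mean(dl)
    di_test[g] <- mean(dt)
  }
  cbind(grid, di_last_sample = di_last, di_test = di_test)
}
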