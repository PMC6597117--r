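#' Session log-likelihood of a memory-trace model
#'
#' The data enter as per-trial proportions of time spent on the slot-1
#' object, `q_t = time_obj1 / (time_obj1 + time_obj2)`, scored against the
#' model's allocation `p_t` with the proportion-weighted Bernoulli
#' cross-entropy `ll = sum_t q_t log p_t + (1 - q_t) log(1 - p_t)`. Under
#' this form the 50/50 chance model has `ll = N log 0.5` regardless of the
#' data, which the chance comparison presupposes. Probabilities are
#' clamped to `[1e-12, 1 - 1e-12]` before logs. Trials with zero total
#' exploration are skipped (the likelihood runs over explored trials only)
#' and counted in the `"n_skipped"` attribute.
#'
#' @param behavior behavior data frame for one session (`time_obj1_s`,
#'   `time_obj2_s`, ordered as the schedule).
#' @param schedule_trials the session's schedule (same trial order).
#' @param params an [ost_params()] object.
#' @param weight_by_time if `TRUE`, each trial's term is multiplied by its
#'   total exploration seconds (time-weighted variant).
#' @param forget_test_delay passed to [run_trace_model()].
#' @return log-likelihood in nats.
#' @export
session_log_likelihood <- function(behavior, schedule_trials, params,
                                   weight_by_time = FALSE,
                                   forget_test_delay = TRUE) {
  q <- session_proportions(behavior)
  if (length(q) != nrow(schedule_trials))
    stop("behavior and schedule have different trial counts")
  pred <- run_trace_core(schedule_trials$day, schedule_trials$loc_slot1,
                         schedule_trials$loc_slot2, params,
                         skip_forget = if (!forget_test_delay)
                           schedule_trials$phase %in% c("test", "delayed_test")
                         else NULL)
  w <- if (weight_by_time)
    behavior$time_obj1_s + behavior$time_obj2_s else rep(1, length(q))
  ll_from_pred(q, pred$p1, w)
}

ll_from_pred <- function(q, p1, w = rep(1, length(q))) {
  keep <- !is.na(q)
  p <- pmin(pmax(p1[keep], 1e-12), 1 - 1e-12)
  qq <- q[keep]
  ll <- sum(w[keep] * (qq * log(p) + (1 - qq) * log(1 - p)))
  attr(ll, "n_used") <- sum(keep)
  attr(ll, "n_skipped") <- sum(!keep)
  ll
}

session_proportions <- function(behavior) {
  tot <- behavior$time_obj1_s + behavior$time_obj2_s
  ifelse(tot > 0, behavior$time_obj1_s / tot, NA_real_)
}

#' Chance-model log-likelihood
#'
#' The chance model always allocates 50/50, so its log-likelihood is
#' `n_trials * log(0.5)` independent of the observed proportions.
#'
#' @param n_trials number of (explored) trials, >= 1.
#' @return log-likelihood in nats.
#' @examples
#' chance_log_likelihood(6)  # -4.1589
#' @export
chance_log_likelihood <- function(n_trials) {
  stopifnot(n_trials >= 1)
  n_trials * log(0.5)
}

# parameter transforms: alpha/gamma on the logit scale, m0 on the log
# scale, beta free; keeps Nelder-Mead off hard bounds
theta_to_params <- function(theta, model) {
  alpha <- plogis(theta[1])
  beta <- theta[2]
  gamma <- if (model %in% c("M2", "M3")) plogis(theta[3]) else NULL
  m0 <- if (model == "M3") exp(theta[4]) else if (model == "M4") exp(theta[3])
        else NULL
  ost_params(model, alpha, beta, gamma = gamma, m0 = m0)
}

sample_start <- function(model) {
  # alpha ~ U(0,1); beta heavy-tailed (Cauchy x 5) since the search range
  # for beta is unbounded; gamma ~ U(0,1); m0 ~ U(0,1)
  th <- c(qlogis(runif(1, 0.02, 0.98)), 5 * rcauchy(1))
  if (model %in% c("M2", "M3")) th <- c(th, qlogis(runif(1, 0.02, 0.98)))
  if (model %in% c("M3", "M4")) th <- c(th, log(runif(1, 0.02, 1)))
  th
}

#' Fit a memory-trace model to one session by maximum likelihood
#'
#' Multi-start Nelder-Mead maximization of [session_log_likelihood()].
#' Starts are drawn randomly (alpha, gamma uniform; beta heavy-tailed;
#' m0 log-uniform) plus one deterministic start at the chance model
#' (alpha = 0.5, beta = 0), which guarantees the optimum is never below
#' the chance log-likelihood. The returned object is a classed model fit
#' supporting `print`, `summary`, `coef`, `logLik`, `AIC`/`BIC`,
#' `predict`, `residuals`, `simulate` and `plot`.
#'
#' @param behavior behavior data frame for one session.
#' @param schedule the session's schedule (an `ost_schedule`; must match
#'   the behavior rows on day/trial).
#' @param model one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param n_starts number of random starts (default 1000; a few hundred
#'   suffice for the 2-parameter M1).
#' @param seed seed for start sampling; the fit is deterministic given it.
#' @param weight_by_time,forget_test_delay see [session_log_likelihood()].
#' @param maxit Nelder-Mead iteration cap per start.
#' @return an object of class `ost_fit`: parameters at the optimum,
#'   `ll_opt`, `ll_chance`, `pseudo_r2 = 1 - ll_opt/ll_chance`, trial
#'   counts, start diagnostics and the beta-outlier flag (`|beta| >=
#'   1000`, the threshold used when summarizing fitted parameters).
#' @examples
#' sch <- generate_session("overlapping", "mouse_5day", 0, 1)
#' sim <- simulate_session(sch, ost_params("M1", 0.6, 5), noise_sd = 0.05,
#'                         seed = 2)
#' fit <- fit_ost(sim$behavior, sch, "M1", n_starts = 50, seed = 3)
#' coef(fit)
#' @export
fit_ost <- function(behavior, schedule, model = c("M1", "M2", "M3", "M4"),
                    n_starts = 1000L, seed = 1L, weight_by_time = FALSE,
                    forget_test_delay = TRUE, maxit = 500L) {
  model <- match.arg(model)
  stopifnot(n_starts >= 1)
  schedule <- schedule[order(schedule$day, schedule$trial_in_day), ,
                       drop = FALSE]
  behavior <- behavior[order(behavior$day, behavior$trial_in_day), ,
                       drop = FALSE]
  if (nrow(behavior) != nrow(schedule) ||
      !all(behavior$day == schedule$day &
           behavior$trial_in_day == schedule$trial_in_day))
    stop("behavior rows do not match schedule trials on (day, trial_in_day)")

  q <- session_proportions(behavior)
  w <- if (weight_by_time)
    behavior$time_obj1_s + behavior$time_obj2_s else rep(1, length(q))
  skip <- if (!forget_test_delay)
    schedule$phase %in% c("test", "delayed_test") else NULL
  day <- schedule$day; l1 <- schedule$loc_slot1; l2 <- schedule$loc_slot2

  negll <- function(theta) {
    p <- theta_to_params(theta, model)
    pred <- run_trace_core(day, l1, l2, p, skip_forget = skip)
    -as.numeric(ll_from_pred(q, pred$p1, w))
  }

  k <- n_free_params(model)
  chance_theta <- c(0, 0, if (k >= 3) 0, if (k >= 4) 0)[seq_len(k)]
  starts <- with_seed(substream_seed(seed, "fit", model), {
    c(list(chance_theta),
      lapply(seq_len(max(0L, n_starts - 1L)), function(i) sample_start(model)))
  })

  best <- NULL
  n_conv <- 0L
  for (th0 in starts) {
    opt <- tryCatch(
      optim(th0, negll, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (opt$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("optimizer failure: all ", length(starts), " starts failed for ",
         model)

  n_used <- sum(!is.na(q))
  ll_chance <- chance_log_likelihood(n_used)
  ll_opt <- -best$value
  params_opt <- theta_to_params(best$par, model)
  if (ll_opt < ll_chance) {  # safeguard; the chance start prevents this
    ll_opt <- ll_chance
    params_opt <- ost_params(model, 0.5, 0,
                             gamma = if (model %in% c("M2", "M3")) 0.5,
                             m0 = if (model %in% c("M3", "M4")) 0)
  }
  pred <- run_trace_core(day, l1, l2, params_opt, skip_forget = skip)

  structure(list(
    params = params_opt, model = model,
    ll_opt = ll_opt, ll_chance = ll_chance,
    pseudo_r2 = 1 - ll_opt / ll_chance,
    n_trials = n_used, n_skipped = sum(is.na(q)),
    n_starts = length(starts),
    converged_fraction = n_conv / length(starts),
    is_beta_outlier = abs(params_opt$beta) >= 1000,
    q = q, p = pred$p1, schedule = schedule,
    weight_by_time = weight_by_time,
    forget_test_delay = forget_test_delay, seed = seed,
    call = match.call()),
    class = "ost_fit")
}

#' @export
print.ost_fit <- function(x, ...) {
  cat(sprintf("Memory-trace model %s fit (%s, %s; %d trials)\n", x$model,
              x$schedule$animal_id[1], x$schedule$condition[1], x$n_trials))
  p <- x$params
  cat(sprintf("  alpha = %.3f  beta = %.3f", p$alpha, p$beta))
  if (!is.na(p$gamma)) cat(sprintf("  gamma = %.3f", p$gamma))
  if (x$model %in% c("M3", "M4")) cat(sprintf("  m0 = %.3g", p$m0))
  cat("\n")
  cat(sprintf("  logLik %.3f (chance %.3f), pseudo-R2 %.3f\n", x$ll_opt,
              x$ll_chance, x$pseudo_r2))
  if (x$is_beta_outlier) cat("  note: |beta| >= 1000 (outlier)\n")
  invisible(x)
}

#' @export
coef.ost_fit <- function(object, ...) {
  p <- object$params
  out <- c(alpha = p$alpha, beta = p$beta)
  if (!is.na(p$gamma)) out <- c(out, gamma = p$gamma)
  if (object$model %in% c("M3", "M4")) out <- c(out, m0 = p$m0)
  out
}

#' @export
logLik.ost_fit <- function(object, ...) {
  structure(object$ll_opt, df = n_free_params(object$model),
            nobs = object$n_trials, class = "logLik")
}

#' @export
summary.ost_fit <- function(object, ...) {
  lr <- likelihood_ratio_vs_chance(object)
  structure(list(fit = object, lr = lr,
                 aic = AIC(object), bic = BIC(object)),
            class = "summary.ost_fit")
}

#' @export
print.summary.ost_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  AIC %.2f  BIC %.2f\n", x$aic, x$bic))
  cat(sprintf("  LR vs chance: chi2(%d) = %.3f, p = %.4g\n",
              x$lr$df, x$lr$statistic, x$lr$p_value))
  cat(sprintf("  starts: %d (%.0f%% converged)\n", x$fit$n_starts,
              100 * x$fit$converged_fraction))
  invisible(x)
}

#' Predict per-trial allocation probabilities from a fitted model
#'
#' @param object an `ost_fit`.
#' @param newdata optionally a new schedule; defaults to the fitted
#'   session's schedule.
#' @param ... unused.
#' @return the [run_trace_model()] prediction table.
#' @export
predict.ost_fit <- function(object, newdata = NULL, ...) {
  sch <- if (is.null(newdata)) object$schedule else newdata
  run_trace_model(sch, object$params,
                  forget_test_delay = object$forget_test_delay)
}

#' @export
residuals.ost_fit <- function(object, ...) {
  object$q - object$p
}

#' Simulate behavior from a fitted model
#'
#' @param object an `ost_fit`.
#' @param nsim number of simulated sessions.
#' @param seed seed for the noise draws.
#' @param noise_sd proportion noise (0 reproduces the model probabilities).
#' @param ... unused.
#' @return a list of `ost_simulation` objects (length `nsim`).
#' @export
simulate.ost_fit <- function(object, nsim = 1, seed = 1L, noise_sd = 0,
                             ...) {
  lapply(seq_len(nsim), function(i)
    simulate_session(object$schedule, object$params, noise_sd = noise_sd,
                     seed = substream_seed(seed, "fitsim", i),
                     forget_test_delay = object$forget_test_delay))
}

#' Plot observed vs fitted exploration proportions
#'
#' @param x an `ost_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ost_fit <- function(x, ...) {
  n <- length(x$q)
  matplot(seq_len(n), cbind(x$q, x$p), type = "b", pch = c(1, 16),
          lty = c(1, 2), col = c("grey40", "firebrick"),
          xlab = "trial", ylab = "proportion on slot-1 object",
          ylim = c(0, 1), ...)
  abline(h = 0.5, lty = 3)
  legend("topleft", c("observed", "model"), pch = c(1, 16),
         col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Likelihood-ratio test of a fit against the chance model
#'
#' `statistic = 2 (ll_opt - ll_chance)`, compared to a chi-square with as
#' many degrees of freedom as the model has free parameters.
#'
#' @param fit an `ost_fit`.
#' @return list `statistic, df, p_value`.
#' @export
likelihood_ratio_vs_chance <- function(fit) {
  stat <- max(0, 2 * (fit$ll_opt - fit$ll_chance))
  df <- n_free_params(fit$model)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Summed information criteria over a set of session fits
#'
#' Per session `AIC_s = 2k - 2 ll_s` and `BIC_s = k log(n_s) - 2 ll_s`
#' with `k` the model's free-parameter count (M1: 2, M2: 3, M3: 4, M4: 3)
#' and `n_s` the session's explored-trial count; totals are sums over
#' sessions.
#'
#' @param fits list of `ost_fit` objects sharing one model.
#' @return list `aic_total, bic_total, n_sessions`.
#' @export
information_criteria <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied")
  models <- unique(vapply(fits, `[[`, character(1), "model"))
  if (length(models) != 1L)
    stop("all fits must share one model (got ",
         paste(models, collapse = ", "), ")")
  k <- n_free_params(models)
  ll <- vapply(fits, `[[`, numeric(1), "ll_opt")
  n <- vapply(fits, `[[`, numeric(1), "n_trials")
  list(aic_total = sum(2 * k - 2 * ll),
       bic_total = sum(k * log(n) - 2 * ll),
       n_sessions = length(fits))
}

#' Fit one model to every session of a dataset
#'
#' @param dataset a list with `schedule` and `behavior` data frames (as
#'   from [generate_dataset()] or [read_dataset()]).
#' @param model model id.
#' @param n_starts,seed,... passed to [fit_ost()]; per-session seeds are
#'   substreams of `seed`.
#' @return a list of class `ost_fit_list`: `fits` (named by
#'   animal/condition) and `table`, a tidy per-session data frame with
#'   columns `animal_id, condition, model, alpha, beta, gamma, m0, ll,
#'   ll_chance, pseudo_r2, aic, bic, lr_stat, lr_p, beta_outlier`.
#' @export
fit_cohort <- function(dataset, model = "M1", n_starts = 200L, seed = 1L,
                       ...) {
  sessions <- as_session_list(dataset$schedule)
  beh_key <- paste(dataset$behavior$animal_id, dataset$behavior$condition)
  fits <- list()
  rows <- list()
  for (s in sessions) {
    key <- paste(s$animal_id[1], s$condition[1])
    beh <- dataset$behavior[beh_key == key, , drop = FALSE]
    if (nrow(beh) == 0L) next
    fit <- fit_ost(beh, s, model, n_starts = n_starts,
                   seed = substream_seed(seed, key, model), ...)
    fits[[key]] <- fit
    lr <- likelihood_ratio_vs_chance(fit)
    rows[[key]] <- data.frame(
      animal_id = s$animal_id[1], condition = s$condition[1], model = model,
      alpha = fit$params$alpha, beta = fit$params$beta,
      gamma = fit$params$gamma,
      m0 = if (model %in% c("M3", "M4")) fit$params$m0 else NA_real_,
      ll = fit$ll_opt, ll_chance = fit$ll_chance,
      pseudo_r2 = fit$pseudo_r2,
      aic = 2 * n_free_params(model) - 2 * fit$ll_opt,
      bic = n_free_params(model) * log(fit$n_trials) - 2 * fit$ll_opt,
      lr_stat = lr$statistic, lr_p = lr$p_value,
      beta_outlier = fit$is_beta_outlier,
      stringsAsFactors = FALSE)
  }
  structure(list(fits = fits,
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE)))),
            class = "ost_fit_list")
}

#' @export
print.ost_fit_list <- function(x, ...) {
  cat(sprintf("%d session fits, model %s\n", length(x$fits),
              x$table$model[1]))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("  ...\n")
  invisible(x)
}

#' Compare the model family M1--M4 across sessions
#'
#' Fits every model to every session and assembles the comparison table:
#' mean and SEM of each parameter across sessions (excluding beta-outlier
#' sessions, `|beta| >= 1000`, which are flagged but retained in the
#' criteria sums), mean log-likelihood and pseudo-R2, and summed AIC/BIC.
#' The winner by each criterion is flagged.
#'
#' @param dataset list with `schedule` and `behavior`.
#' @param models models to compare (default all four).
#' @param n_starts,seed,... passed to [fit_cohort()].
#' @return a list of class `ost_model_comparison`: `table` (one row per
#'   model), `fits` (per-model `ost_fit_list`s), and the winner ids
#'   `winner_aic`, `winner_bic`.
#' @export
compare_ost_models <- function(dataset, models = c("M1", "M2", "M3", "M4"),
                               n_starts = 200L, seed = 1L, ...) {
  fits <- list()
  rows <- list()
  for (m in models) {
    fl <- fit_cohort(dataset, m, n_starts = n_starts,
                     seed = substream_seed(seed, "compare", m), ...)
    fits[[m]] <- fl
    tab <- fl$table
    keep <- !tab$beta_outlier
    msem <- function(x) {
      x <- x[keep & !is.na(x)]
      if (length(x) == 0L) return(c(NA_real_, NA_real_))
      c(mean(x), if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_)
    }
    a <- msem(tab$alpha); b <- msem(tab$beta); g <- msem(tab$gamma)
    m0 <- msem(tab$m0)
    ic <- information_criteria(fl$fits)
    rows[[m]] <- data.frame(
      model = m,
      mean_alpha = a[1], sem_alpha = a[2],
      mean_beta = b[1], sem_beta = b[2],
      mean_gamma = g[1], sem_gamma = g[2],
      mean_m0 = m0[1], sem_m0 = m0[2],
      mean_ll = mean(tab$ll), aic_total = ic$aic_total,
      bic_total = ic$bic_total, mean_pseudo_r2 = mean(tab$pseudo_r2),
      n_outliers = sum(tab$beta_outlier),
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(table = table, fits = fits,
                 winner_aic = table$model[which.min(table$aic_total)],
                 winner_bic = table$model[which.min(table$bic_total)]),
            class = "ost_model_comparison")
}

#' @export
print.ost_model_comparison <- function(x, ...) {
  cat("Model comparison (summed AIC/BIC over sessions):\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-3s alpha %.2f+-%.2f  beta %6.1f  LL %8.2f  AIC %9.1f  BIC %9.1f  pR2 %.2f%s\n",
                tab$model[i], tab$mean_alpha[i],
                ifelse(is.na(tab$sem_alpha[i]), 0, tab$sem_alpha[i]),
                tab$mean_beta[i], tab$mean_ll[i], tab$aic_total[i],
                tab$bic_total[i], tab$mean_pseudo_r2[i],
                if (tab$model[i] == x$winner_aic &&
                    tab$model[i] == x$winner_bic) "  <- winner" else ""))
  }
  invisible(x)
}
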