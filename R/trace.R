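#' Memory-trace model parameters
#'
#' The model family shares a 2 objects x 4 locations trace matrix
#' `m(o, l)`, a leaky count of how often the object in slot `o` has been
#' seen at location `l`. Variants:
#' \describe{
#'   \item{M1}{learning rate `alpha`, softmax weight `beta`; traces start
#'     at 0.}
#'   \item{M2}{M1 plus an overnight forgetting rate `gamma` pulling traces
#'     toward `m0 = 0` between days.}
#'   \item{M3}{M2 with the attractor/initial value `m0` free.}
#'   \item{M4}{M1 with `m0` free but no forgetting.}
#' }
#'
#' @param model one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param alpha learning rate in \[0, 1\]: close to 1 the trace reflects
#'   only the most recent trial (episodic-like), close to 0 information is
#'   integrated over many trials (cumulative).
#' @param beta softmax exploration weight; `beta > 0` is neophilia
#'   (preference for the higher-entropy object), `beta < 0` neophobia.
#' @param gamma overnight retention in \[0, 1\] (M2/M3 only): `gamma = 1`
#'   keeps traces intact, `gamma = 0` resets them to `m0` every night.
#' @param m0 initial trace value and forgetting attractor, >= 0; fixed at 0
#'   for M1/M2, free for M3/M4.
#' @return a list of class `ost_params`.
#' @examples
#' ost_params("M1", alpha = 0.6, beta = 0.2)
#' @export
ost_params <- function(model = c("M1", "M2", "M3", "M4"), alpha, beta,
                       gamma = NULL, m0 = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  has_gamma <- model %in% c("M2", "M3")
  free_m0 <- model %in% c("M3", "M4")
  if (has_gamma) {
    if (is.null(gamma))
      stop("model ", model, " requires a gamma (overnight retention)")
    stopifnot(gamma >= 0, gamma <= 1)
  } else if (!is.null(gamma)) {
    stop("gamma is only defined for models M2 and M3")
  }
  if (free_m0) {
    if (is.null(m0)) m0 <- 0
    stopifnot(m0 >= 0)
  } else {
    if (!is.null(m0) && m0 != 0)
      stop("m0 is fixed at 0 for models M1 and M2")
    m0 <- 0
  }
  structure(list(model = model, alpha = alpha, beta = beta,
                 gamma = if (has_gamma) gamma else NA_real_,
                 m0 = m0),
            class = "ost_params")
}

#' @export
print.ost_params <- function(x, ...) {
  cat("Memory-trace model", x$model, "parameters:\n")
  cat(sprintf("  alpha = %.4g  beta = %.4g", x$alpha, x$beta))
  if (!is.na(x$gamma)) cat(sprintf("  gamma = %.4g", x$gamma))
  if (x$model %in% c("M3", "M4")) cat(sprintf("  m0 = %.4g", x$m0))
  cat("\n")
  invisible(x)
}

# number of free parameters per model (AIC/BIC penalty k)
n_free_params <- function(model) {
  switch(model, M1 = 2L, M2 = 3L, M3 = 4L, M4 = 3L,
         stop("unknown model: ", model))
}

#' Create a fresh memory-trace state
#'
#' @param m0 initial value of every trace entry (>= 0).
#' @return a list with the 2 x 4 trace matrix `m` and `trial_index = 0`.
#' @export
new_trace_state <- function(m0 = 0) {
  stopifnot(m0 >= 0)
  list(m = matrix(as.double(m0), nrow = 2L, ncol = 4L), trial_index = 0L)
}

#' Update the memory trace with one trial's observation
#'
#' Both object rows are low-pass filtered in the same call:
#' `m'(o, l) = (1 - alpha) m(o, l) + alpha * delta(o, l)` with `delta` the
#' indicator of the location at which each object was observed.
#'
#' @param state trace state from [new_trace_state()] or a previous update.
#' @param observation list or 1-row data frame with `loc_obj1`, `loc_obj2`
#'   (distinct integers in 1..4).
#' @param params an [ost_params()] object (only `alpha` is used).
#' @return the updated state with `trial_index` incremented.
#' @export
update_trace <- function(state, observation, params) {
  l1 <- as.integer(observation$loc_obj1)
  l2 <- as.integer(observation$loc_obj2)
  stopifnot(l1 %in% 1:4, l2 %in% 1:4, l1 != l2)
  a <- params$alpha
  m <- (1 - a) * state$m
  m[1L, l1] <- m[1L, l1] + a
  m[2L, l2] <- m[2L, l2] + a
  list(m = m, trial_index = state$trial_index + 1L)
}

#' Apply one night of trace forgetting (models M2/M3)
#'
#' Every entry relaxes toward the attractor:
#' `m' = m + (1 - gamma) (m0 - m)`. `gamma = 1` leaves the trace intact,
#' `gamma = 0` resets it to `m0`.
#'
#' @param state trace state.
#' @param params an [ost_params()] with `model` M2 or M3.
#' @return the state after one day boundary.
#' @export
apply_day_forgetting <- function(state, params) {
  if (!params$model %in% c("M2", "M3"))
    stop("day forgetting is only defined for models M2 and M3")
  g <- params$gamma
  state$m <- state$m + (1 - g) * (params$m0 - state$m)
  state
}

#' Shannon entropy of one object's normalized trace row
#'
#' The row is normalized to sum to 1 and its entropy computed in nats with
#' the convention `0 * log(0) = 0`. An all-zero row is treated as a uniform
#' distribution (maximal uncertainty, `log(4)`), which makes the
#' first-trial allocation 0.5/0.5 and is continuous with `m0 -> 0`.
#'
#' @param state trace state.
#' @param object_index 1 or 2.
#' @return entropy in nats, between 0 and `log(4)`.
#' @examples
#' s <- new_trace_state(0.25)
#' trace_entropy(s, 1)  # log(4)
#' @export
trace_entropy <- function(state, object_index) {
  row_entropy(state$m[object_index, ])
}

row_entropy <- function(row) {
  tot <- sum(row)
  if (tot <= 0) return(log(4))
  p <- row / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Softmax exploration allocation from the two entropies
#'
#' `p_k = exp(beta * S_k) / (exp(beta * S_1) + exp(beta * S_2))`, computed
#' with max-subtraction so extreme `beta` yields the correct limits 0/1
#' rather than overflow.
#'
#' @param entropy_obj1,entropy_obj2 entropies in nats (>= 0, finite).
#' @param params an [ost_params()] (only `beta` is used).
#' @return named numeric vector `c(p_obj1, p_obj2)` summing to 1.
#' @examples
#' allocation_probabilities(log(4), 0, ost_params("M1", 0.6, 0.2))
#' @export
allocation_probabilities <- function(entropy_obj1, entropy_obj2, params) {
  stopifnot(is.finite(entropy_obj1), is.finite(entropy_obj2),
            entropy_obj1 >= 0, entropy_obj2 >= 0)
  p1 <- plogis(params$beta * (entropy_obj1 - entropy_obj2))
  c(p_obj1 = p1, p_obj2 = 1 - p1)
}

#' Run a memory-trace model over a session
#'
#' For each trial, the trace is first updated with the trial's observation
#' (both objects at their current locations) and the entropies and
#' exploration allocation for that trial are then computed from the updated
#' trace, so that a displaced object raises its own entropy in the very
#' trial in which the displacement is observed. For M2/M3, one forgetting
#' step is applied per night elapsed between consecutive trial days
#' (including the 24-h pre-test delay and multi-night delays of the 4-week
#' protocol), before the next day's first trial.
#'
#' @param trials a schedule data frame (ordered or orderable by
#'   `day`, `trial_in_day`) with columns `day`, `loc_slot1`, `loc_slot2`.
#' @param params an [ost_params()] object.
#' @param forget_test_delay if `FALSE`, M2/M3 forgetting is not applied
#'   across the delay preceding a `test`/`delayed_test` trial.
#' @return a data frame with one row per trial: `day`, `trial_in_day`,
#'   `phase` (if present), entropies `S_obj1`, `S_obj2` and allocation
#'   probabilities `p_obj1`, `p_obj2`; the final trace matrix is attached
#'   as attribute `"final_trace"`.
#' @examples
#' sch <- generate_session("overlapping", "rat_2day", 0, 1)
#' run_trace_model(sch, ost_params("M1", 0.6, 0.2))
#' @export
run_trace_model <- function(trials, params, forget_test_delay = TRUE) {
  ord <- order(trials$day, trials$trial_in_day)
  if (!identical(ord, seq_len(nrow(trials))))
    stop("trials must be ordered by (day, trial_in_day)")
  res <- run_trace_core(trials$day, trials$loc_slot1, trials$loc_slot2,
                        params, forget_test_delay,
                        skip_forget = if (!forget_test_delay)
                          trials$phase %in% c("test", "delayed_test")
                        else NULL)
  out <- data.frame(day = trials$day, trial_in_day = trials$trial_in_day,
                    S_obj1 = res$S1, S_obj2 = res$S2,
                    p_obj1 = res$p1, p_obj2 = 1 - res$p1)
  if (!is.null(trials$phase)) out$phase <- trials$phase
  attr(out, "final_trace") <- res$m
  out
}

# tight inner loop shared by simulation and likelihood evaluation; the
# entropy uses the identity -sum(p log p) = log(tot) - sum(m log m)/tot,
# with log(m + (m == 0)) sending 0 log 0 to 0
run_trace_core <- function(day, loc1, loc2, params, forget_test_delay = TRUE,
                           skip_forget = NULL) {
  n <- length(day)
  alpha <- params$alpha
  beta <- params$beta
  forget <- params$model %in% c("M2", "M3")
  gamma <- params$gamma
  m0 <- params$m0
  m1 <- rep.int(as.double(m0), 4L)
  m2 <- m1
  S1 <- numeric(n); S2 <- numeric(n); p1 <- numeric(n)
  log4 <- log(4)
  keep <- 1 - alpha
  for (t in seq_len(n)) {
    if (forget && t > 1L) {
      nights <- day[t] - day[t - 1L]
      if (nights > 0L && !(isTRUE(skip_forget[t]))) {
        w <- gamma^nights
        m1 <- w * m1 + (1 - w) * m0
        m2 <- w * m2 + (1 - w) * m0
      }
    }
    m1 <- keep * m1
    m1[loc1[t]] <- m1[loc1[t]] + alpha
    m2 <- keep * m2
    m2[loc2[t]] <- m2[loc2[t]] + alpha
    tot1 <- sum(m1)
    S1[t] <- if (tot1 <= 0) log4 else
      log(tot1) - sum(m1 * log(m1 + (m1 == 0))) / tot1
    tot2 <- sum(m2)
    S2[t] <- if (tot2 <= 0) log4 else
      log(tot2) - sum(m2 * log(m2 + (m2 == 0))) / tot2
    p1[t] <- 1 / (1 + exp(-beta * (S1[t] - S2[t])))
  }
  list(S1 = S1, S2 = S2, p1 = p1, m = rbind(m1, m2, deparse.level = 0))
}
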