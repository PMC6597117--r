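#' @name schedules
#' @title Counterbalanced trial schedules for the Object Space Task
#'
#' @description
#' A session is a sequence of trials in one condition for one animal. Each
#' trial places two objects at two of the four magnet-marked corner
#' locations (1--4) of the arena. Object identity changes every trial, so
#' the only identity that persists across trials is the \emph{slot}:
#' slot 1 is the stable-role slot (the location held constant in the stable
#' and overlapping conditions, or a fixed counterbalanced pseudo-stable
#' reference in random) and slot 2 is the novel-role slot (displaced at the
#' stable test, moving every trial in overlapping).
#'
#' Protocols:
#' \describe{
#'   \item{rat_2day}{5 sample trials on day 1, test trial 24 h later.}
#'   \item{mouse_5day}{5 sample trials/day on days 1--4, test on day 5.}
#'   \item{mouse_3trial}{3 sample trials/day on days 1--4, test on day 5.}
#'   \item{mouse_4week}{overlapping only; 5 trials/day Mon--Fri for 3 weeks
#'     plus a final trial on Wednesday of week 4. Trials 26 and 76 repeat
#'     the previous trial's configuration and serve as 3-day and 5-day
#'     delayed tests. Days are numbered as calendar days so that day
#'     differences count the nights elapsed (weekends included).}
#' }
NULL

.ost_conditions <- c("stable", "overlapping", "random")
.ost_protocols <- c("rat_2day", "mouse_5day", "mouse_3trial", "mouse_4week")

# per-protocol trial skeleton: day (calendar), trial_in_day, phase
protocol_skeleton <- function(protocol) {
  switch(protocol,
    rat_2day = data.frame(
      day = c(rep(1L, 5L), 2L),
      trial_in_day = c(1:5, 1L),
      phase = c(rep("sample", 5L), "test"),
      stringsAsFactors = FALSE),
    mouse_5day = data.frame(
      day = c(rep(1:4, each = 5L), 5L),
      trial_in_day = c(rep(1:5, 4L), 1L),
      phase = c(rep("sample", 20L), "test"),
      stringsAsFactors = FALSE),
    mouse_3trial = data.frame(
      day = c(rep(1:4, each = 3L), 5L),
      trial_in_day = c(rep(1:3, 4L), 1L),
      phase = c(rep("sample", 12L), "test"),
      stringsAsFactors = FALSE),
    mouse_4week = {
      training_days <- c(1:5, 8:12, 15:19)   # Mon-Fri, weeks 1-3
      d <- data.frame(
        day = c(rep(training_days, each = 5L), 24L),  # Wed of week 4
        trial_in_day = c(rep(1:5, 15L), 1L),
        phase = "sample",
        stringsAsFactors = FALSE)
      d$phase[c(26L, 76L)] <- "delayed_test"  # 3-day and 5-day tests
      d
    },
    stop("unknown protocol: ", protocol))
}

# decode the counterbalance slot into the location roles of a session
decode_counterbalance <- function(condition, counterbalance_slot) {
  cb <- as.integer(counterbalance_slot)
  if (condition == "stable") {
    a <- cb %% 4L + 1L
    b <- setdiff(1:4, a)[(cb %/% 4L) %% 3L + 1L]
    dest <- setdiff(1:4, c(a, b))[(cb %/% 12L) %% 2L + 1L]
    list(stable_loc = a, second_loc = b, test_dest = dest)
  } else if (condition == "overlapping") {
    a <- cb %% 4L + 1L
    list(stable_loc = a, movers = setdiff(1:4, a),
         rotation = (cb %/% 4L) %% 3L)
  } else {
    # random: parity decides which member of each (sorted) pair is the
    # pseudo-stable slot-1 reference; counterbalanced across animals it
    # yields expected DI of 0
    list(ref_high = cb %% 2L == 1L)
  }
}

#' Generate one counterbalanced session schedule
#'
#' @param condition one of `"stable"`, `"overlapping"`, `"random"`.
#' @param protocol one of `"rat_2day"`, `"mouse_5day"`, `"mouse_3trial"`,
#'   `"mouse_4week"` (the last is overlapping only).
#' @param counterbalance_slot non-negative integer selecting the
#'   counterbalanced location assignment (stable-role location, second
#'   location, test destination, mover rotation, or random-reference
#'   parity, depending on condition).
#' @param seed integer seed; the schedule is deterministic given all
#'   arguments.
#' @param animal_id identifier written into the schedule rows.
#' @return a data frame of class `ost_schedule` with one row per trial and
#'   columns `animal_id, protocol, condition, day, trial_in_day, phase,
#'   loc_slot1, loc_slot2, object_pair_id, counterbalance_slot`.
#'
#' @details The random condition is pseudo-random with rejection sampling:
#' per training day every location is used equally often over the object
#' slots (max minus min count at most 1), every location appears within the
#' first 3 trials, with 5 trials/day the last 2 trials jointly use each
#' location exactly once, and no two consecutive trials share the same
#' location pair. If no valid day is found within 10,000 attempts a
#' constraint-infeasible error names the violated rule.
#'
#' @examples
#' s <- generate_session("overlapping", "rat_2day", 0, seed = 1)
#' validate_schedule(s)
#' @export
generate_session <- function(condition, protocol, counterbalance_slot = 0L,
                             seed = 1L, animal_id = "a01") {
  condition <- match.arg(condition, .ost_conditions)
  protocol <- match.arg(protocol, .ost_protocols)
  if (protocol == "mouse_4week" && condition != "overlapping")
    stop("protocol 'mouse_4week' is defined for the overlapping condition only")
  skel <- protocol_skeleton(protocol)
  n <- nrow(skel)
  cbi <- decode_counterbalance(condition, counterbalance_slot)

  loc1 <- integer(n)
  loc2 <- integer(n)
  if (condition == "stable") {
    is_test <- skel$phase == "test"
    loc1[] <- cbi$stable_loc
    loc2[!is_test] <- cbi$second_loc
    loc2[is_test] <- cbi$test_dest
  } else if (condition == "overlapping") {
    loc1[] <- cbi$stable_loc
    copies <- which(skel$phase %in% c("test", "delayed_test"))
    fresh <- setdiff(seq_len(n), copies)
    k <- length(fresh)
    base <- k %/% 3L
    extra <- k %% 3L
    counts <- rep(base, 3L)
    if (extra > 0L) {
      who <- ((cbi$rotation + seq_len(extra) - 1L) %% 3L) + 1L
      counts[who] <- counts[who] + 1L
    }
    movers <- rep(cbi$movers, counts)
    movers <- with_seed(substream_seed(seed, animal_id, condition, "movers"),
                        sample(movers))
    loc2[fresh] <- movers
    for (i in copies) loc2[i] <- loc2[i - 1L]
  } else {
    pairs <- generate_random_pairs(skel, seed, animal_id)
    ord1 <- vapply(pairs, min, integer(1))
    ord2 <- vapply(pairs, max, integer(1))
    if (cbi$ref_high) {
      loc1 <- ord2; loc2 <- ord1
    } else {
      loc1 <- ord1; loc2 <- ord2
    }
  }

  out <- data.frame(
    animal_id = animal_id,
    protocol = protocol,
    condition = condition,
    day = skel$day,
    trial_in_day = skel$trial_in_day,
    phase = skel$phase,
    loc_slot1 = loc1,
    loc_slot2 = loc2,
    object_pair_id = sprintf("%s_%s_pair%02d", animal_id, condition,
                             seq_len(n)),
    counterbalance_slot = as.integer(counterbalance_slot),
    stringsAsFactors = FALSE)
  class(out) <- c("ost_schedule", "data.frame")
  out
}

# rejection-sample the pseudo-random location pairs for a whole session
generate_random_pairs <- function(skel, seed, animal_id) {
  pairs <- vector("list", nrow(skel))
  prev <- NULL
  idx <- 1L
  with_seed(substream_seed(seed, animal_id, "random", "pairs"), {
    for (day in unique(skel$day)) {
      tpd <- sum(skel$day == day)
      if (tpd == 1L) {
        # test day: a single pair, only the no-run constraint applies
        repeat {
          p <- sort(sample(4L, 2L))
          if (is.null(prev) || any(p != prev)) break
        }
        day_pairs <- list(p)
      } else {
        day_pairs <- sample_random_day(tpd, prev)
      }
      for (p in day_pairs) {
        pairs[[idx]] <- p
        idx <- idx + 1L
        prev <- p
      }
    }
  })
  pairs
}

# one pseudo-random training day satisfying the balance/coverage/no-run
# rules; tpd is trials per day (3 or 5)
sample_random_day <- function(tpd, prev) {
  if (tpd < 3L)
    stop("constraint-infeasible: random condition needs >= 3 trials/day ",
         "to cover all 4 locations (rule: per-day location coverage)")
  for (attempt in seq_len(10000L)) {
    if (tpd == 5L) {
      # last 2 trials: each location exactly once
      perm <- sample(4L)
      tail_pairs <- list(sort(perm[1:2]), sort(perm[3:4]))
      head_pairs <- replicate(3L, sort(sample(4L, 2L)), simplify = FALSE)
      day_pairs <- c(head_pairs, tail_pairs)
      counts_head <- tabulate(unlist(head_pairs), nbins = 4L)
      # total counts are 1 + head counts; balance needs head in {1,2}
      if (any(counts_head < 1L) || any(counts_head > 2L)) next
    } else {
      day_pairs <- replicate(tpd, sort(sample(4L, 2L)), simplify = FALSE)
      counts <- tabulate(unlist(day_pairs), nbins = 4L)
      if (any(counts < 1L) || max(counts) - min(counts) > 1L) next
    }
    # no consecutive identical configurations (incl. across day boundary)
    seqs <- c(list(prev), day_pairs)
    ok <- TRUE
    for (i in seq_len(length(seqs) - 1L)) {
      a <- seqs[[i]]; b <- seqs[[i + 1L]]
      if (!is.null(a) && all(a == b)) { ok <- FALSE; break }
    }
    if (ok) return(day_pairs)
  }
  stop("constraint-infeasible: no valid pseudo-random day found in 10,000 ",
       "attempts (rules: balance, coverage, no runs)")
}

#' Generate a counterbalanced cohort of schedules
#'
#' Stable-role locations, moving locations and condition orders are rotated
#' across animals so that each assignment is used as evenly as `n_animals`
#' permits, and within every animal the stable-role location differs
#' between its stable and overlapping sessions.
#'
#' @param n_animals number of animals (>= 1).
#' @param protocol protocol name, see [generate_session()].
#' @param seed master seed; per-session seeds are derived substreams.
#' @param conditions conditions to run; defaults to all three, or
#'   `"overlapping"` for `mouse_4week`.
#' @return an `ost_schedule` data frame with one row per trial across all
#'   animals and sessions; the per-animal condition orders are stored in
#'   the `"condition_order"` attribute.
#' @examples
#' coh <- generate_cohort(4, "rat_2day", seed = 3)
#' table(coh$animal_id, coh$condition)
#' @export
generate_cohort <- function(n_animals, protocol, seed = 1L,
                            conditions = NULL) {
  stopifnot(n_animals >= 1)
  protocol <- match.arg(protocol, .ost_protocols)
  if (is.null(conditions))
    conditions <- if (protocol == "mouse_4week") "overlapping" else .ost_conditions
  conditions <- match.arg(conditions, .ost_conditions, several.ok = TRUE)

  orders <- condition_orders(conditions)
  sessions <- list()
  cond_order <- list()
  for (i in seq_len(n_animals)) {
    aid <- sprintf("a%02d", i)
    ord <- orders[[(i - 1L) %% length(orders) + 1L]]
    cond_order[[aid]] <- ord
    for (cond in ord) {
      cb <- cohort_cb_slot(cond, i)
      sessions[[paste(aid, cond)]] <- generate_session(
        cond, protocol, cb, seed = substream_seed(seed, aid, cond),
        animal_id = aid)
    }
  }
  out <- do.call(rbind, c(sessions, list(make.row.names = FALSE)))
  attr(out, "condition_order") <- cond_order
  class(out) <- c("ost_schedule", "data.frame")
  out
}

# all orderings of the condition set, in a fixed enumeration
condition_orders <- function(conditions) {
  k <- length(conditions)
  if (k == 1L) return(list(conditions))
  perm_idx <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (j in seq_along(v))
      for (rest in perm_idx(v[-j])) out <- c(out, list(c(v[j], rest)))
    out
  }
  perm_idx(conditions)
}

# per-animal counterbalance slots: stable-role locations rotate across
# animals and differ within animal between stable and overlapping
cohort_cb_slot <- function(condition, i) {
  if (condition == "overlapping") {
    (i - 1L) %% 4L + 4L * ((i - 1L) %/% 4L %% 3L)
  } else if (condition == "stable") {
    a_idx <- i %% 4L                       # shifted by 1 vs overlapping
    a_idx + 4L * ((i - 1L) %% 3L) + 12L * (((i - 1L) %/% 3L) %% 2L)
  } else {
    (i - 1L) %% 2L
  }
}

#' Validate a schedule against the task's structural rules
#'
#' Checks every invariant the generators promise: distinct locations per
#' trial, protocol trial counts, unique object pairs, the constant-pair
#' rule in stable (with a one-slot displacement at test), the constant
#' slot-1 and last-sample-equals-test rules in overlapping, and the
#' balance, coverage and no-run rules in random. Validation never raises;
#' it returns a character vector of violations (empty when the schedule is
#' valid), each naming the session, trial or day, and the violated rule.
#'
#' @param schedule an `ost_schedule` data frame (one or many sessions).
#' @return character vector of violation messages, empty if valid.
#' @examples
#' validate_schedule(generate_session("stable", "rat_2day", 0, 1))
#' @export
validate_schedule <- function(schedule) {
  required <- c("animal_id", "protocol", "condition", "day", "trial_in_day",
                "phase", "loc_slot1", "loc_slot2", "object_pair_id")
  missing <- setdiff(required, names(schedule))
  if (length(missing))
    return(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  v <- character(0)
  key <- paste(schedule$animal_id, schedule$condition, schedule$protocol)
  for (k in unique(key)) {
    v <- c(v, validate_one_session(schedule[key == k, , drop = FALSE]))
  }
  v
}

validate_one_session <- function(s) {
  v <- character(0)
  tag <- sprintf("[%s/%s]", s$animal_id[1], s$condition[1])
  s <- s[order(s$day, s$trial_in_day), , drop = FALSE]
  n <- nrow(s)
  bad <- which(s$loc_slot1 == s$loc_slot2 |
               !(s$loc_slot1 %in% 1:4) | !(s$loc_slot2 %in% 1:4))
  for (i in bad)
    v <- c(v, sprintf("%s trial %d: locations must be 2 distinct values in 1..4",
                      tag, i))
  if (anyDuplicated(s$object_pair_id))
    v <- c(v, sprintf("%s: object_pair_id repeats within session", tag))

  skel <- protocol_skeleton(s$protocol[1])
  if (n != nrow(skel)) {
    v <- c(v, sprintf("%s: %d trials, protocol %s requires %d", tag, n,
                      s$protocol[1], nrow(skel)))
    return(v)
  }
  if (!all(s$phase == skel$phase))
    v <- c(v, sprintf("%s: phase sequence does not match protocol", tag))

  cond <- s$condition[1]
  is_sample <- s$phase == "sample"
  if (cond == "stable") {
    if (length(unique(s$loc_slot1[is_sample])) != 1L ||
        length(unique(s$loc_slot2[is_sample])) != 1L)
      v <- c(v, sprintf("%s: stable sample trials must share one location pair", tag))
    ti <- which(s$phase == "test")
    if (length(ti) == 1L) {
      same1 <- s$loc_slot1[ti] == s$loc_slot1[1]
      same2 <- s$loc_slot2[ti] == s$loc_slot2[1]
      if (sum(c(same1, same2)) != 1L)
        v <- c(v, sprintf("%s trial %d: exactly one slot must move at the stable test",
                          tag, ti))
      if (!same1)
        v <- c(v, sprintf("%s trial %d: slot 1 is the stable role and must not move",
                          tag, ti))
    }
  } else if (cond == "overlapping") {
    if (length(unique(s$loc_slot1)) != 1L)
      v <- c(v, sprintf("%s: overlapping slot 1 must be constant incl. test", tag))
    for (ti in which(s$phase %in% c("test", "delayed_test"))) {
      if (ti == 1L) next
      if (s$loc_slot1[ti] != s$loc_slot1[ti - 1L] ||
          s$loc_slot2[ti] != s$loc_slot2[ti - 1L])
        v <- c(v, sprintf("%s trial %d: test configuration must equal the previous trial",
                          tag, ti))
    }
  } else {
    for (d in unique(s$day[is_sample])) {
      sd <- s[s$day == d & is_sample, , drop = FALSE]
      counts <- tabulate(c(sd$loc_slot1, sd$loc_slot2), nbins = 4L)
      if (max(counts) - min(counts) > 1L)
        v <- c(v, sprintf("%s day %d: location use unbalanced (counts %s)",
                          tag, d, paste(counts, collapse = ",")))
      k <- min(3L, nrow(sd))
      cov <- tabulate(c(sd$loc_slot1[1:k], sd$loc_slot2[1:k]), nbins = 4L)
      if (any(cov == 0L))
        v <- c(v, sprintf("%s day %d: a location is unused in the first 3 trials",
                          tag, d))
      if (nrow(sd) == 5L) {
        last2 <- tabulate(c(sd$loc_slot1[4:5], sd$loc_slot2[4:5]), nbins = 4L)
        if (any(last2 != 1L))
          v <- c(v, sprintf("%s day %d: last 2 trials must use each location exactly once",
                            tag, d))
      }
    }
    for (i in seq_len(n - 1L)) {
      a <- sort(c(s$loc_slot1[i], s$loc_slot2[i]))
      b <- sort(c(s$loc_slot1[i + 1L], s$loc_slot2[i + 1L]))
      if (all(a == b))
        v <- c(v, sprintf("%s trial %d: identical configuration on consecutive random trials",
                          tag, i + 1L))
    }
  }
  v
}
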