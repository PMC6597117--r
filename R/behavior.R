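#' Discrimination index
#'
#' `DI = (time_novel - time_stable) / (time_novel + time_stable)`, ranging
#' from -1 (exclusive preference for the stable location) through 0 (no
#' preference) to +1 (exclusive preference for the novel/moved location).
#' A trial with zero total exploration has no defined DI and returns `NA`.
#'
#' @param time_novel_s exploration seconds at the novel-role location
#'   (slot 2: moved at the stable test, moving in overlapping, the
#'   counterbalanced pseudo-novel reference in random).
#' @param time_stable_s exploration seconds at the stable-role location.
#' @return DI in \[-1, 1\], or `NA` when both times are 0. Vectorized.
#' @examples
#' discrimination_index(33, 27)  # 0.1
#' @export
discrimination_index <- function(time_novel_s, time_stable_s) {
  stopifnot(all(time_novel_s >= 0, na.rm = TRUE),
            all(time_stable_s >= 0, na.rm = TRUE))
  tot <- time_novel_s + time_stable_s
  ifelse(is.na(tot) | tot <= 0, NA_real_,
         (time_novel_s - time_stable_s) / tot)
}

#' Add DI and proportion columns to a behavior table
#'
#' @param behavior behavior data frame with `time_obj1_s` (slot 1, stable
#'   role) and `time_obj2_s` (slot 2, novel role).
#' @param use_full_test_window if `TRUE` and the table carries the
#'   full-10-minute test columns `time_obj1_full_s`/`time_obj2_full_s`,
#'   test trials are scored on the full window instead of the default
#'   first-5-minute times.
#' @return the table with columns `di` and `prop_obj1` appended.
#' @export
compute_di <- function(behavior, use_full_test_window = FALSE) {
  t1 <- behavior$time_obj1_s
  t2 <- behavior$time_obj2_s
  if (use_full_test_window &&
      all(c("time_obj1_full_s", "time_obj2_full_s") %in% names(behavior))) {
    is_test <- behavior$phase %in% c("test", "delayed_test")
    t1[is_test] <- behavior$time_obj1_full_s[is_test]
    t2[is_test] <- behavior$time_obj2_full_s[is_test]
  }
  behavior$di <- discrimination_index(t2, t1)
  tot <- t1 + t2
  behavior$prop_obj1 <- ifelse(tot > 0, t1 / tot, NA_real_)
  behavior
}

#' Exclude animals with insufficient exploration
#'
#' Mirrors the task's exclusion rule: an animal whose exploration falls
#' below the threshold (default 5 s) is removed from the dataset. The
#' qualifying quantity is the animal's minimum session-mean total
#' exploration time per trial, so one session of near-zero exploration is
#' enough to exclude.
#'
#' @param behavior behavior data frame with `time_obj1_s`, `time_obj2_s`.
#' @param min_total_exploration_s threshold in seconds (>= 0, default 5).
#' @return a list with `behavior` (rows of retained animals) and
#'   `exclusions`, a data frame `animal_id, mean_total_s, reason`.
#' @export
apply_exclusions <- function(behavior, min_total_exploration_s = 5) {
  stopifnot(min_total_exploration_s >= 0)
  tot <- behavior$time_obj1_s + behavior$time_obj2_s
  per_session <- aggregate(tot,
    by = list(animal_id = behavior$animal_id, condition = behavior$condition),
    FUN = mean)
  per_animal <- aggregate(per_session$x,
    by = list(animal_id = per_session$animal_id), FUN = min)
  bad <- per_animal[per_animal$x < min_total_exploration_s, , drop = FALSE]
  exclusions <- data.frame(
    animal_id = bad$animal_id,
    mean_total_s = bad$x,
    reason = sprintf("mean exploration %.2f s below %.2f s threshold",
                     bad$x, min_total_exploration_s),
    stringsAsFactors = FALSE)
  list(behavior = behavior[!behavior$animal_id %in% bad$animal_id, ,
                           drop = FALSE],
       exclusions = exclusions)
}

#' One-sample t test of DI values against chance (0)
#'
#' @param di_values numeric DI values; `NA`s are dropped.
#' @return a list `t, df, p, mean, n` (two-sided p).
#' @examples
#' one_sample_t_vs_chance(c(0.3, 0.25, 0.1, -0.05, 0.2, 0.15, 0.35, 0))
#' @export
one_sample_t_vs_chance <- function(di_values) {
  x <- di_values[!is.na(di_values)]
  if (length(x) < 2L)
    stop("need at least 2 non-missing values for a one-sample t test")
  if (sd(x) == 0) {
    # degenerate constant sample: zero deviation from chance is t = 0,
    # p = 1; a constant nonzero sample is an infinite t
    t_stat <- if (mean(x) == 0) 0 else sign(mean(x)) * Inf
    return(list(t = t_stat, df = length(x) - 1,
                p = if (mean(x) == 0) 1 else 0, mean = mean(x),
                n = length(x)))
  }
  tt <- t.test(x, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(x), n = length(x))
}

#' Repeated-measures ANOVA on a within-subject behavioral table
#'
#' Fits the standard univariate repeated-measures ANOVA (subjects crossed
#' with every within factor) and reports F, dfs and p for all main effects
#' and interactions. With `correction = "greenhouse-geisser"` the
#' sphericity-corrected dfs and p-values are computed via the multivariate
#' formulation (used for the 4-week week analysis); the default
#' uncorrected dfs match the integer dfs reported for the 2-day and 5-day
#' designs.
#'
#' @param data data frame with one row per subject x cell.
#' @param dv name of the dependent-variable column (e.g. `"di"` or a total
#'   exploration time).
#' @param factors character vector of within-subject factor columns, a
#'   subset of `condition`, `trial_in_day`, `day`, `week` (any column
#'   works; they are treated as factors).
#' @param subject name of the subject identifier column.
#' @param correction `"none"` (default) or `"greenhouse-geisser"`.
#' @return a list of class `ost_anova` with `table`, a data frame
#'   `effect, F, df_num, df_den, p` (plus `eps` under correction), and the
#'   design metadata.
#' @examples
#' coh <- generate_cohort(6, "rat_2day", seed = 1)
#' sims <- simulate_cohort(coh, ost_params("M1", 0.6, 0.2), noise_sd = 0.1)
#' beh <- compute_di(do.call(rbind, lapply(sims, `[[`, "behavior")))
#' test <- beh[beh$phase == "test", ]
#' rm_anova(test, dv = "di", factors = "condition")
#' @export
rm_anova <- function(data, dv, factors, subject = "animal_id",
                     correction = c("none", "greenhouse-geisser")) {
  correction <- match.arg(correction)
  stopifnot(dv %in% names(data), all(factors %in% names(data)),
            subject %in% names(data))
  d <- data[, c(subject, factors, dv)]
  names(d) <- c(".subject", paste0(".f", seq_along(factors)), ".y")
  d$.subject <- factor(d$.subject)
  fcols <- paste0(".f", seq_along(factors))
  for (fc in fcols) d[[fc]] <- factor(d[[fc]])

  # completeness: every subject must have every cell exactly once
  cell <- interaction(d[fcols], drop = FALSE)
  counts <- table(d$.subject, cell)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)
    stop("incomplete within-subject design; missing/duplicated cells: ",
         paste(sprintf("%s x %s", rownames(counts)[bad[, 1]],
                       colnames(counts)[bad[, 2]]),
               collapse = "; "))
  }
  if (anyNA(d$.y))
    stop("missing dependent-variable values; repeated-measures ANOVA ",
         "requires complete data (missing trials are not imputed)")

  if (correction == "none") {
    tab <- rm_anova_univariate(d, fcols)
  } else {
    tab <- rm_anova_gg(d, fcols)
  }
  # restore user-facing effect names
  for (i in seq_along(factors))
    tab$effect <- gsub(paste0("\\.f", i, "\\b"), factors[i], tab$effect)
  structure(list(table = tab, dv = dv, factors = factors,
                 n_subjects = nlevels(d$.subject), correction = correction),
            class = "ost_anova")
}

# classic univariate rm-ANOVA via aov with Error strata
rm_anova_univariate <- function(d, fcols) {
  rhs <- paste(fcols, collapse = " * ")
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + Error(.subject/(",
                                   rhs, "))"))
  fit <- aov(form, data = d)
  out <- data.frame(effect = character(0), F = numeric(0),
                    df_num = numeric(0), df_den = numeric(0),
                    p = numeric(0), stringsAsFactors = FALSE)
  for (stratum in summary(fit)) {
    s <- stratum[[1]]
    rn <- trimws(rownames(s))
    for (i in seq_len(nrow(s))) {
      if (rn[i] == "Residuals") next
      df_den <- s[rn == "Residuals", "Df"]
      out <- rbind(out, data.frame(
        effect = gsub(":", " x ", rn[i]), F = s[i, "F value"],
        df_num = s[i, "Df"], df_den = df_den, p = s[i, "Pr(>F)"],
        stringsAsFactors = FALSE))
    }
  }
  out
}

# Greenhouse-Geisser corrected rm-ANOVA via car's multivariate machinery
rm_anova_gg <- function(d, fcols) {
  cell <- interaction(d[fcols], drop = FALSE, lex.order = TRUE)
  wide <- tapply(d$.y, list(d$.subject, cell), identity)
  idata <- unique(d[order(cell), fcols, drop = FALSE])
  rownames(idata) <- NULL
  mlm <- lm(wide ~ 1)
  idesign <- stats::as.formula(paste("~", paste(fcols, collapse = " * ")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = "III")
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  eps <- s$pval.adjustments
  out <- data.frame(effect = character(0), F = numeric(0),
                    df_num = numeric(0), df_den = numeric(0),
                    p = numeric(0), eps = numeric(0),
                    stringsAsFactors = FALSE)
  for (rn in rownames(uni)) {
    if (rn == "(Intercept)") next
    e <- if (!is.null(eps) && rn %in% rownames(eps))
      eps[rn, "GG eps"] else 1
    out <- rbind(out, data.frame(
      effect = gsub(":", " x ", rn), F = uni[rn, "F value"],
      df_num = uni[rn, "num Df"] * e, df_den = uni[rn, "den Df"] * e,
      p = if (!is.null(eps) && rn %in% rownames(eps))
        eps[rn, "Pr(>F[GG])"] else uni[rn, "Pr(>F)"],
      eps = e, stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.ost_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s (%d subjects%s)\n", x$dv,
              x$n_subjects,
              if (x$correction != "none") ", Greenhouse-Geisser" else ""))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-28s F(%.4g, %.4g) = %.3f, p = %.4g\n", tab$effect[i],
                tab$df_num[i], tab$df_den[i], tab$F[i], tab$p[i]))
  }
  invisible(x)
}

#' DI time course: group means and SEMs
#'
#' @param behavior behavior data frame (DI is computed if absent).
#' @param grouping character vector of grouping columns, default
#'   `c("condition", "day", "trial_in_day")`.
#' @param use_full_test_window see [compute_di()].
#' @return a data frame with the grouping columns plus `mean_di`, `sem_di`
#'   and `n` (animals contributing); SEM is `NA` for a single animal.
#' @export
di_timecourse <- function(behavior,
                          grouping = c("condition", "day", "trial_in_day"),
                          use_full_test_window = FALSE) {
  if (!"di" %in% names(behavior))
    behavior <- compute_di(behavior, use_full_test_window)
  keys <- behavior[, grouping, drop = FALSE]
  out <- aggregate(behavior$di, by = as.list(keys),
                   FUN = function(x) mean(x, na.rm = TRUE))
  names(out)[ncol(out)] <- "mean_di"
  nn <- aggregate(behavior$di, by = as.list(keys),
                  FUN = function(x) sum(!is.na(x)))$x
  sdv <- aggregate(behavior$di, by = as.list(keys),
                   FUN = function(x) sd(x, na.rm = TRUE))$x
  out$sem_di <- ifelse(nn > 1, sdv / sqrt(nn), NA_real_)
  out$n <- nn
  out[do.call(order, out[grouping]), , drop = FALSE]
}
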