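# shared fixture builders; all fixtures are generated in code

# behavior rows from explicit slot-1 proportions on a schedule
behavior_from_props <- function(schedule, props, total = 40) {
  stopifnot(length(props) == nrow(schedule))
  data.frame(
    animal_id = schedule$animal_id,
    condition = schedule$condition,
    day = schedule$day,
    trial_in_day = schedule$trial_in_day,
    phase = schedule$phase,
    loc_slot1 = schedule$loc_slot1,
    loc_slot2 = schedule$loc_slot2,
    time_obj1_s = props * total,
    time_obj2_s = (1 - props) * total,
    stringsAsFactors = FALSE)
}

# a minimal ost_fit-shaped object for testing downstream accessors
fake_fit <- function(model = "M1", ll = -10, n = 21, ll_chance = n * log(0.5)) {
  structure(list(model = model, ll_opt = ll, ll_chance = ll_chance,
                 pseudo_r2 = 1 - ll / ll_chance, n_trials = n,
                 params = ost_params(model, 0.5, 0,
                                     gamma = if (model %in% c("M2", "M3")) 0.5,
                                     m0 = if (model %in% c("M3", "M4")) 0)),
            class = "ost_fit")
}

# independent repeated-measures ANOVA oracle: explicit sums-of-squares
# decomposition for a two-within-factor design (subject x A x B), used to
# check rm_anova against first principles
rm_anova_oracle_2w <- function(d, subject, fA, fB, dv) {
  y <- d[[dv]]
  s <- factor(d[[subject]]); a <- factor(d[[fA]]); b <- factor(d[[fB]])
  N <- length(y); gm <- mean(y)
  ns <- nlevels(s); na <- nlevels(a); nb <- nlevels(b)
  mean_by <- function(...) tapply(y, list(...), mean)
  ss <- function(m, mult) mult * sum((m - gm)^2)
  ss_a <- ss(mean_by(a), ns * nb)
  ss_b <- ss(mean_by(b), ns * na)
  m_ab <- mean_by(a, b)
  ss_ab <- ns * sum((m_ab - outer(mean_by(a) - gm, mean_by(b) - gm, "+") - gm)^2)
  m_sa <- mean_by(s, a); m_sb <- mean_by(s, b)
  m_s <- mean_by(s)
  ss_sa <- nb * sum((m_sa - outer(m_s - gm, mean_by(a) - gm, "+") - gm)^2)
  ss_sb <- na * sum((m_sb - outer(m_s - gm, mean_by(b) - gm, "+") - gm)^2)
  # residual for A x B: total interaction SS minus modeled pieces
  cell <- tapply(y, list(s, a, b), mean)
  ss_tot <- sum((y - gm)^2)
  ss_s <- na * nb * sum((m_s - gm)^2)
  ss_sab <- ss_tot - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb
  f <- function(ss_eff, df_eff, ss_err, df_err)
    c(F = (ss_eff / df_eff) / (ss_err / df_err), df1 = df_eff, df2 = df_err,
      p = stats::pf((ss_eff / df_eff) / (ss_err / df_err), df_eff, df_err,
                    lower.tail = FALSE))
  list(
    A = f(ss_a, na - 1, ss_sa, (ns - 1) * (na - 1)),
    B = f(ss_b, nb - 1, ss_sb, (ns - 1) * (nb - 1)),
    AB = f(ss_ab, (na - 1) * (nb - 1), ss_sab, (ns - 1) * (na - 1) * (nb - 1)))
}
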