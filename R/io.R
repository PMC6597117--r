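.schedule_cols <- c("animal_id", "protocol", "condition", "day",
                    "trial_in_day", "phase", "loc_slot1", "loc_slot2",
                    "object_pair_id", "counterbalance_slot")
.behavior_cols <- c("animal_id", "condition", "day", "trial_in_day",
                    "phase", "loc_slot1", "loc_slot2", "time_obj1_s",
                    "time_obj2_s")

#' Read and join a schedule/behavior CSV pair into a validated dataset
#'
#' Every behavior row must match exactly one schedule trial on
#' `(animal_id, condition, day, trial_in_day)` and the two tables must
#' agree on the trial's locations; violations are reported with the
#' offending row.
#'
#' @param schedule_path,behavior_path CSV paths (comma-separated, header
#'   required, UTF-8; locations as integers 1--4, one row per trial).
#' @return a list of class `ost_dataset` with `schedule`, `behavior` and
#'   `provenance` (source paths); row-order independent.
#' @export
read_dataset <- function(schedule_path, behavior_path) {
  schedule <- read.csv(schedule_path, stringsAsFactors = FALSE,
                       encoding = "UTF-8")
  behavior <- read.csv(behavior_path, stringsAsFactors = FALSE,
                       encoding = "UTF-8")
  miss_s <- setdiff(.schedule_cols, names(schedule))
  if (length(miss_s))
    stop("schedule file lacks columns: ", paste(miss_s, collapse = ", "))
  miss_b <- setdiff(.behavior_cols, names(behavior))
  if (length(miss_b))
    stop("behavior file lacks columns: ", paste(miss_b, collapse = ", "))

  skey <- paste(schedule$animal_id, schedule$condition, schedule$day,
                schedule$trial_in_day)
  bkey <- paste(behavior$animal_id, behavior$condition, behavior$day,
                behavior$trial_in_day)
  if (anyDuplicated(skey))
    stop("duplicate schedule trials: ", skey[duplicated(skey)][1])
  orphan <- which(!bkey %in% skey)
  if (length(orphan))
    stop("behavior row ", orphan[1], " (", bkey[orphan[1]],
         ") matches no schedule trial")
  idx <- match(bkey, skey)
  locbad <- which(behavior$loc_slot1 != schedule$loc_slot1[idx] |
                  behavior$loc_slot2 != schedule$loc_slot2[idx])
  if (length(locbad))
    stop("behavior row ", locbad[1], " (", bkey[locbad[1]],
         "): locations disagree with the schedule")

  schedule <- schedule[order(schedule$animal_id, schedule$condition,
                             schedule$day, schedule$trial_in_day), ,
                       drop = FALSE]
  behavior <- behavior[order(behavior$animal_id, behavior$condition,
                             behavior$day, behavior$trial_in_day), ,
                       drop = FALSE]
  rownames(schedule) <- NULL
  rownames(behavior) <- NULL
  class(schedule) <- c("ost_schedule", "data.frame")
  structure(list(schedule = schedule, behavior = behavior,
                 provenance = list(schedule_path = schedule_path,
                                   behavior_path = behavior_path)),
            class = "ost_dataset")
}

#' Write a table as a deterministic CSV
#'
#' Rows are sorted on the identifying columns present (animal, condition,
#' day, trial), floats rendered with 6 significant digits, UTF-8, no row
#' names, so writing the same object twice yields byte-identical files.
#'
#' @param x a data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_tables <- function(x, path) {
  keys <- intersect(c("animal_id", "condition", "model", "day",
                      "trial_in_day"), names(x))
  if (length(keys) && nrow(x) > 1)
    x <- x[do.call(order, x[keys]), , drop = FALSE]
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(col) signif(col, 6))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the end-to-end pipeline from a configuration
#'
#' Executes named stages in order -- `synth` (or reading existing CSVs),
#' `fit`, `compare`, `analyze` -- with a single master seed split into
#' named substreams, writes each stage's tables under `out_dir`, and
#' returns (and writes) a manifest listing inputs, seeds, package version
#' and outputs. A stage failure aborts with the stage name; earlier
#' outputs are preserved.
#'
#' @param config a list (or path to a YAML file, read with the `yaml`
#'   package) with elements: `seed`; `out_dir`; `synth` (a list of
#'   [cohort_spec()] arguments) or `schedule`/`behavior` CSV paths;
#'   optional `fit = list(model=, n_starts=)`; optional
#'   `compare = list(models=, n_starts=)`; optional `analyze = TRUE`.
#' @return the manifest list, invisibly; side effect: CSV/JSON files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # pre-flight: referenced input files must exist before any stage runs
  for (p in c(config$schedule, config$behavior))
    if (!file.exists(p)) stop("pre-flight: input file not found: ", p)

  manifest <- list(seed = seed,
                   version = as.character(utils::packageVersion("objspace")),
                   stages = list(), outputs = character(0))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$synth)) {
    ds <- run_stage("synth", {
      args <- config$synth
      args$seed <- substream_seed(seed, "synth")
      do.call(cohort_spec, args)
    })
    ds <- run_stage("synth", generate_dataset(ds))
    write_tables(ds$schedule, file.path(out_dir, "schedule.csv"))
    write_tables(ds$behavior, file.path(out_dir, "behavior.csv"))
    write_tables(ds$truth, file.path(out_dir, "truth.csv"))
    manifest$stages$synth <- list(seed = substream_seed(seed, "synth"),
                                  n_animals = ds$spec$n_animals,
                                  protocol = ds$spec$protocol)
    manifest$outputs <- c(manifest$outputs, "schedule.csv", "behavior.csv",
                          "truth.csv")
  } else {
    ds <- run_stage("read", read_dataset(config$schedule, config$behavior))
    manifest$stages$read <- ds$provenance
  }

  if (!is.null(config$fit)) {
    fl <- run_stage("fit", fit_cohort(
      ds, model = if (is.null(config$fit$model)) "M1" else config$fit$model,
      n_starts = if (is.null(config$fit$n_starts)) 200L
                 else config$fit$n_starts,
      seed = substream_seed(seed, "fit")))
    write_tables(fl$table, file.path(out_dir, "fits.csv"))
    manifest$stages$fit <- list(model = fl$table$model[1],
                                seed = substream_seed(seed, "fit"),
                                n_sessions = nrow(fl$table))
    manifest$outputs <- c(manifest$outputs, "fits.csv")
  }

  if (!is.null(config$compare)) {
    cmp <- run_stage("compare", compare_ost_models(
      ds, models = if (is.null(config$compare$models))
        c("M1", "M2", "M3", "M4") else config$compare$models,
      n_starts = if (is.null(config$compare$n_starts)) 100L
                 else config$compare$n_starts,
      seed = substream_seed(seed, "compare")))
    write_tables(cmp$table, file.path(out_dir, "comparison.csv"))
    manifest$stages$compare <- list(winner_aic = cmp$winner_aic,
                                    winner_bic = cmp$winner_bic,
                                    seed = substream_seed(seed, "compare"))
    manifest$outputs <- c(manifest$outputs, "comparison.csv")
  }

  if (isTRUE(config$analyze)) {
    rep <- run_stage("analyze", {
      excl <- apply_exclusions(ds$behavior)
      beh <- compute_di(excl$behavior)
      test <- beh[beh$phase %in% c("test", "delayed_test"), , drop = FALSE]
      tt <- lapply(split(test$di, test$condition), function(x)
        if (sum(!is.na(x)) >= 2) one_sample_t_vs_chance(x) else NULL)
      list(timecourse = di_timecourse(beh),
           t_tests = tt[!vapply(tt, is.null, logical(1))],
           exclusions = excl$exclusions)
    })
    write_tables(rep$timecourse, file.path(out_dir, "di_timecourse.csv"))
    jsonlite::write_json(
      list(t_tests = rep$t_tests,
           exclusions = rep$exclusions),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$analyze <- list(n_excluded = nrow(rep$exclusions))
    manifest$outputs <- c(manifest$outputs, "di_timecourse.csv",
                          "report.json")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a supplementary-style spreadsheet export (CSV) into behavior format
#'
#' The study's raw data are distributed as spreadsheets whose internal
#' layout is not standardized; this adapter is configuration-driven: it
#' reads a CSV export of a sheet and renames columns according to
#' `column_map`, returning a behavior-format data frame. It is a
#' best-effort bridge, not a parser of any specific workbook.
#'
#' @param path CSV path (a spreadsheet sheet exported to CSV).
#' @param column_map named character vector mapping behavior-schema names
#'   (see [read_dataset()]) to the file's column names, e.g.
#'   `c(animal_id = "Rat", time_obj1_s = "Stable_s", ...)`.
#' @return a behavior data frame with the standard columns.
#' @export
read_supplementary <- function(path, column_map) {
  raw <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(unname(column_map), names(raw))
  if (length(missing))
    stop("mapped columns absent from file: ", paste(missing, collapse = ", "))
  out <- raw[unname(column_map)]
  names(out) <- names(column_map)
  need <- setdiff(.behavior_cols, names(out))
  if (length(need))
    stop("column_map must cover: ", paste(need, collapse = ", "))
  out
}
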