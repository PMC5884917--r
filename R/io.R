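marker_channels <- function() {
  as.vector(outer(
    c("toe", "mall", "heel"), c("ap", "ml", "z"),
    function(m, a) paste(m, a, sep = "_")
  )) -> ma
  c(t(outer(c("left", "right"), ma, paste, sep = "_")))
}

write_signal_tsv <- function(df, path, rate, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# precstep %s table", what),
    sprintf("# sampling_rate_hz\t%g", rate),
    "# units\tseconds_and_meters"
  ), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_signal_tsv <- function(path, what, expected_cols) {
  lines <- readLines(path, n = 10)
  hdr <- grep("^# sampling_rate_hz", lines, value = TRUE)
  rate <- if (length(hdr)) as.numeric(sub(".*\t", "", hdr[1])) else NA_real_
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (ncol(df) != length(expected_cols)) {
    stopf("%s table must have %d columns (time + %d channels), found %d",
          what, length(expected_cols), length(expected_cols) - 1, ncol(df))
  }
  missing <- setdiff(expected_cols, names(df))
  if (length(missing)) {
    stopf("%s table is missing column '%s'", what, missing[1])
  }
  if (any(diff(df$time) <= 0)) stopf("column 'time' must be strictly increasing")
  attr(df, "sampling_rate") <- rate
  df
}

#' Write / read marker trajectories as TSV
#'
#' Tab-separated table with commented header lines carrying the sampling
#' rate and units, a `time` column (s) and 18 marker channels
#' (`<foot>_<marker>_<axis>`, meters).
#'
#' @param markers marker data.frame (`time` + 18 channels).
#' @param path file path.
#' @param rate sampling rate in samples/s.
#' @return `path` (write) or the validated data.frame with attribute
#'   `sampling_rate` (read).
#' @export
write_marker_table <- function(markers, path, rate = 150) {
  write_signal_tsv(markers, path, rate, "marker")
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  read_signal_tsv(path, "marker", c("time", marker_channels()))
}

#' Write / read a COP trajectory as TSV
#' @param cop data.frame `time`, `ap`, `ml`.
#' @inheritParams write_marker_table
#' @return `path` (write) or the validated data.frame (read).
#' @export
write_cop_table <- function(cop, path, rate = 1000) {
  write_signal_tsv(cop, path, rate, "cop")
}

#' @rdname write_cop_table
#' @export
read_cop_table <- function(path) {
  read_signal_tsv(path, "cop", c("time", "ap", "ml"))
}

#' Serialize gait events to JSON
#' @param events a `gait_events` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(as.data.frame(events), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path) {
  ev <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(ev, stringsAsFactors = FALSE)
  class(ev) <- c("gait_events", "data.frame")
  ev
}

#' Write / read a full trial as plain-text files
#'
#' A trial directory holds `markers.tsv`, `cop.tsv` and `trial.json` (block,
#' protocol parameters and the target log with appearance and shift-onset
#' times). [read_trial()] reconstructs a trial that [score_trial()] accepts.
#'
#' @param trial a `stepping_trial`.
#' @param dir directory (created if needed).
#' @return `dir` (write) or the reconstructed trial list (read).
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_marker_table(trial$markers, file.path(dir, "markers.tsv"),
                     rate = trial$marker_rate)
  write_cop_table(trial$cop, file.path(dir, "cop.tsv"), rate = trial$cop_rate)
  jsonlite::write_json(
    list(kind = attr(trial$block, "kind"),
         params = unclass(trial$params),
         targets = trial$block,
         target_log = trial$target_log),
    file.path(dir, "trial.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "trial.json"),
                             simplifyVector = TRUE)
  p <- obj$params
  p$gap_range <- as.integer(p$gap_range)
  class(p) <- "protocol_params"
  b <- as.data.frame(obj$targets, stringsAsFactors = FALSE)
  if (!"shift_direction" %in% names(b)) b$shift_direction <- NA_character_
  for (col in c("shift_ard", "displaced_ap_center")) {
    if (!col %in% names(b)) b[[col]] <- NA_real_
  }
  b$shift_direction <- as.character(b$shift_direction)
  attr(b, "kind") <- obj$kind
  attr(b, "params") <- p
  class(b) <- c("step_block", "data.frame")
  log <- as.data.frame(obj$target_log, stringsAsFactors = FALSE)
  if (!"shift_onset" %in% names(log)) log$shift_onset <- NA_real_
  log$shift_onset <- as.numeric(log$shift_onset)
  structure(list(
    markers = read_marker_table(file.path(dir, "markers.tsv")),
    cop = read_cop_table(file.path(dir, "cop.tsv")),
    block = b, params = p, target_log = log
  ), class = "stepping_trial")
}

#' Assemble the cohort table
#'
#' Joins per-subject summaries with ages and covariates into the one-row-
#' per-subject table consumed by the statistics layer.
#'
#' @param summaries data.frame of [subject_summary()] rows with an `id`
#'   column.
#' @param cohort a [make_cohort()] table (or any data.frame with `id`,
#'   `age`, optional `sex` and covariates).
#' @return a `cohort_table` data.frame.
#' @export
cohort_table <- function(summaries, cohort) {
  if (anyDuplicated(cohort$id)) stopf("subject ids must be unique")
  if (any(is.na(cohort$age))) stopf("every subject needs an age")
  keep <- intersect(c("id", "age", "sex", "preferred_step_length"),
                    names(cohort))
  out <- merge(cohort[, keep, drop = FALSE], summaries, by = "id",
               sort = TRUE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Run the study's statistical analyses on a cohort table
#'
#' Computes the behavioral statistics: two-tailed Pearson correlations of
#' age with unperturbed step error and variability, and repeated-measures
#' ANCOVAs (age covariate, ARD within-subject factor) for perturbed step
#' error and variability. If `measures` names additional per-subject
#' columns (e.g. externally supplied regional brain measures), each is
#' correlated with the four summary measures, optionally partialling out
#' `control` columns and adding permutation p values, with BH-FDR applied
#' per dependent variable across the measure family.
#'
#' @param tbl a [cohort_table()].
#' @param measures character vector of extra per-subject columns to
#'   correlate with the summary measures (may be empty).
#' @param control character vector of columns to partial out (e.g. `"age"`).
#' @param n_perm permutations for permutation p values (0 = skip).
#' @param q FDR level.
#' @param seed integer seed (needed when `n_perm > 0`).
#' @return list with `correlations` (data.frame), `ancova` (list of
#'   [rm_ancova()] results), and `measure_correlations` (data.frame or
#'   `NULL`).
#' @export
analyze_cohort <- function(tbl, measures = character(), control = character(),
                           n_perm = 0, q = 0.05, seed = 1L) {
  behav <- c(unperturbed_error = "unperturbed_error",
             unperturbed_variability = "unperturbed_variability")
  cors <- do.call(rbind, lapply(names(behav), function(nm) {
    ct <- pearson_corr(tbl$age, tbl[[behav[[nm]]]])
    data.frame(x = "age", y = nm, r = ct$r, df = ct$df, p = ct$p,
               stringsAsFactors = FALSE)
  }))

  ard_err <- as.matrix(tbl[, grep("^error_ard", names(tbl)), drop = FALSE])
  ard_var <- as.matrix(tbl[, grep("^variability_ard", names(tbl)), drop = FALSE])
  ancova <- list(
    perturbed_error = rm_ancova(ard_err, tbl$age),
    perturbed_variability = rm_ancova(ard_var, tbl$age)
  )

  meas <- NULL
  if (length(measures)) {
    targets <- c("unperturbed_error", "unperturbed_variability",
                 "perturbed_error", "perturbed_variability")
    seeds <- derive_seeds(seed, length(measures) * length(targets))
    si <- 0L
    rows <- list()
    for (dv in targets) {
      fam <- list()
      for (mv in measures) {
        si <- si + 1L
        res <- if (length(control)) {
          partial_corr(tbl[[mv]], tbl[[dv]],
                       tbl[, control, drop = FALSE])
        } else {
          pearson_corr(tbl[[mv]], tbl[[dv]])
        }
        p_perm <- NA_real_
        if (n_perm > 0) {
          p_perm <- permutation_pearson(tbl[[mv]], tbl[[dv]],
                                        n_perm = n_perm,
                                        seed = seeds[si])$p_perm
        }
        fam[[mv]] <- data.frame(
          measure = mv, outcome = dv, r = res$r, df = res$df, p = res$p,
          p_perm = p_perm, stringsAsFactors = FALSE
        )
      }
      famdf <- do.call(rbind, fam)
      bh <- fdr_bh(famdf$p, q)
      famdf$p_fdr <- bh$adjusted
      famdf$significant <- bh$rejected
      rows[[dv]] <- famdf
    }
    meas <- do.call(rbind, rows)
    rownames(meas) <- NULL
  }

  list(correlations = cors, ancova = ancova, measure_correlations = meas)
}

#' Configuration for an end-to-end pipeline run
#'
#' @param n cohort size.
#' @param age_range ages in years, `c(min, max)`.
#' @param model a [subject_model()].
#' @param protocol a [protocol_params()]; each subject's preferred step
#'   length overrides its `preferred_step_length`.
#' @param level `"scores"` draws landing errors directly from the subject
#'   model (fast path); `"signals"` synthesizes marker/COP signals, detects
#'   events and scores them (full path).
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir output directory for [write_report()], or `NULL`.
#' @return a `run_config` list.
#' @export
run_config <- function(n = 30, age_range = c(9, 18.5),
                       model = subject_model(),
                       protocol = protocol_params(),
                       level = c("scores", "signals"),
                       seed = 1L, outdir = NULL) {
  level <- match.arg(level)
  structure(list(n = n, age_range = age_range, model = model,
                 protocol = protocol, level = level,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

score_subject_signals <- function(subject, params, seed) {
  p <- params
  p$preferred_step_length <- subject$preferred_step_length
  seeds <- derive_seeds(seed, 1L + p$n_perturbed_blocks + 1L)
  session <- generate_session(p, seed = seeds[1])
  scores <- list()
  for (bi in seq_along(session)) {
    trial <- simulate_trial(subject, session[[bi]], p, seed = seeds[bi + 1])
    scores[[bi]] <- score_trial(trial)
  }
  out <- do.call(rbind, scores)
  attr(out, "L") <- p$preferred_step_length
  class(out) <- c("step_scores", "data.frame")
  out
}

#' Run the full pipeline: simulate, detect, score, analyze
#'
#' @param config a [run_config()].
#' @return list with `cohort` (the [cohort_table()]), `analysis`
#'   (from [analyze_cohort()]), `config`, and `seeds` (per-stage seeds);
#'   written to `config$outdir` via [write_report()] when set.
#' @export
run_pipeline <- function(config = run_config()) {
  stage_seeds <- derive_seeds(config$seed, 2L)
  cohort <- make_cohort(config$n, config$age_range, config$model,
                        seed = stage_seeds[1])
  subj_seeds <- derive_seeds(stage_seeds[2], config$n)
  summaries <- do.call(rbind, lapply(seq_len(config$n), function(i) {
    subj <- cohort[i, ]
    scores <- if (config$level == "scores") {
      simulate_subject_scores(subj, config$protocol, seed = subj_seeds[i])
    } else {
      score_subject_signals(subj, config$protocol, seed = subj_seeds[i])
    }
    cbind(id = subj$id, subject_summary(scores))
  }))
  tbl <- cohort_table(summaries, cohort)
  analysis <- analyze_cohort(tbl)
  result <- list(cohort = tbl, analysis = analysis, config = config,
                 seeds = list(master = config$seed, cohort = stage_seeds[1],
                              subjects = subj_seeds))
  if (!is.null(config$outdir)) write_report(result, config$outdir)
  result
}

#' Write a pipeline report
#'
#' CSV tables (cohort, correlations, ANCOVA effects, measure correlations
#' when present), a JSON summary, and a log listing every seed used and the
#' package and R versions. Rerunning the same configuration reproduces the
#' files byte for byte.
#'
#' @param result a [run_pipeline()] result (or a compatible list; missing
#'   parts yield valid empty tables).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  cohort <- result$cohort
  if (is.null(cohort)) cohort <- data.frame(id = character(0))
  wcsv(cohort, "cohort.csv")

  cors <- result$analysis$correlations
  if (is.null(cors)) {
    cors <- data.frame(x = character(0), y = character(0), r = numeric(0),
                       df = numeric(0), p = numeric(0))
  }
  wcsv(cors, "correlations.csv")

  anc <- result$analysis$ancova
  anc_df <- if (length(anc)) {
    do.call(rbind, lapply(names(anc), function(nm) {
      cbind(outcome = nm, anc[[nm]]$effects)
    }))
  } else {
    data.frame(outcome = character(0), effect = character(0), F = numeric(0),
               df1 = numeric(0), df2 = numeric(0), epsilon = numeric(0),
               p = numeric(0))
  }
  wcsv(anc_df, "ancova.csv")

  if (!is.null(result$analysis$measure_correlations)) {
    wcsv(result$analysis$measure_correlations, "measure_correlations.csv")
  }

  summary <- list(
    n_subjects = nrow(cohort),
    correlations = cors,
    ancova = anc_df,
    seeds = result$seeds
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")

  seeds <- result$seeds
  log_lines <- c(
    "precstep run log",
    sprintf("package_version: %s",
            as.character(utils::packageVersion("precstep"))),
    sprintf("r_version: %s", R.version.string),
    if (!is.null(seeds)) {
      c(sprintf("seed_master: %s", seeds$master),
        sprintf("seed_cohort: %s", seeds$cohort),
        sprintf("seed_subjects: %s", paste(seeds$subjects, collapse = ",")))
    } else "seeds: none recorded"
  )
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
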