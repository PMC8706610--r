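#' Write a cohort to CSV
#'
#' Plain UTF-8 CSV with a header, dot decimal separator, booleans encoded
#' as 0/1 and Clavien grades as the strings 0, 1, 2, 3a, 3b, 4, 5 — the
#' interchange schema read back by [read_cohort()].
#'
#' @param cohort A `surg_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- data.frame(
    case_index = as.integer(cohort$case_index),
    operative_time_min = cohort$operative_time_min,
    hb_drop_gdl = cohort$hb_drop_gdl,
    max_clavien = as.character(cohort$max_clavien),
    psm = as.integer(cohort$psm),
    ln_count = as.integer(cohort$ln_count),
    los_days = as.integer(cohort$los_days),
    readmitted = as.integer(cohort$readmitted)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Reads and validates the schema written by [write_cohort()]. Every
#' validation failure reports the offending row and column.
#'
#' @param path Path to a cohort CSV.
#' @return A validated `surg_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                         strip.white = TRUE)
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("cohort file is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) stop("cohort file contains no cases", call. = FALSE)

  num_col <- function(col, integer = FALSE, min = -Inf) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | v < min | (integer & v != floor(v)))
    if (length(bad)) {
      stop(sprintf("row %d, column `%s`: unparseable or out-of-range value '%s'",
                   bad[1L], col, raw[[col]][bad[1L]]), call. = FALSE)
    }
    if (integer) as.integer(v) else v
  }
  ci <- num_col("case_index", integer = TRUE, min = 1)
  if (!identical(ci, seq_len(n))) {
    bad <- which(ci != seq_len(n))[1L]
    stop(sprintf("row %d, column `case_index`: expected %d, found %d (indices must run 1..n)",
                 bad, bad, ci[bad]), call. = FALSE)
  }
  grade <- raw$max_clavien
  bad <- which(!grade %in% clavien_levels)
  if (length(bad)) {
    stop(sprintf("row %d, column `max_clavien`: unparseable grade '%s'",
                 bad[1L], grade[bad[1L]]), call. = FALSE)
  }
  bool_col <- function(col) {
    v <- raw[[col]]
    bad <- which(!v %in% c("0", "1"))
    if (length(bad)) {
      stop(sprintf("row %d, column `%s`: expected 0/1, found '%s'",
                   bad[1L], col, v[bad[1L]]), call. = FALSE)
    }
    v == "1"
  }
  new_surg_cohort(data.frame(
    case_index = ci,
    operative_time_min = num_col("operative_time_min", min = 1e-9),
    hb_drop_gdl = num_col("hb_drop_gdl", min = 0),
    max_clavien = grade,
    psm = bool_col("psm"),
    ln_count = num_col("ln_count", integer = TRUE, min = 0),
    los_days = num_col("los_days", integer = TRUE, min = 1),
    readmitted = bool_col("readmitted"),
    stringsAsFactors = FALSE
  ))
}

# ---- flat key = value configuration files --------------------------------

flatten_config <- function(cfg) {
  kv <- c(
    n_cases = cfg$n_cases, learning_break = cfg$learning_break,
    mastery_break = cfg$mastery_break, breakthrough_run = cfg$breakthrough_run,
    seed = cfg$seed
  )
  out <- sprintf("%s = %s", names(kv), kv)
  for (nm in c("ot_early", "ot_mid", "ot_late", "hb_early", "hb_late",
               "ln_count", "los", "clavien_low_weights", "clavien_high_weights")) {
    v <- cfg[[nm]]
    out <- c(out, sprintf("%s.%s = %s", nm, names(v), format(v, digits = 15)))
  }
  qp <- cfg$quintile_probs
  for (ev in rownames(qp)) {
    out <- c(out, sprintf("quintile_probs.%s = %s", ev,
                          paste(format(qp[ev, ], digits = 15), collapse = ", ")))
  }
  out
}

#' Write a generator configuration as flat key = value text
#'
#' One `key = value` pair per line; nested numeric fields use dotted keys
#' (`ot_early.median = 450`) and the per-quintile probability rows are
#' comma-separated vectors (`quintile_probs.psm = 0.15, 0.15, ...`).
#' [read_config()] restores the full `generator_config`.
#'
#' @param cfg A `generator_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  writeLines(flatten_config(cfg), path)
  invisible(path)
}

#' Read a generator configuration from flat key = value text
#'
#' @param path Path to a file written by [write_config()].
#' @return A validated `generator_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  get1 <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) stop(sprintf("config file is missing key `%s`", key), call. = FALSE)
    v <- as.numeric(strsplit(vals[i], ",")[[1L]])
    if (anyNA(v)) stop(sprintf("config key `%s` is not numeric", key), call. = FALSE)
    v
  }
  pair <- function(nm, parts = c("median", "sdlog")) {
    stats::setNames(vapply(parts, function(p) get1(paste(nm, p, sep = ".")),
                           numeric(1)), parts)
  }
  weights <- function(nm, grades) {
    stats::setNames(vapply(grades, function(g) get1(paste(nm, g, sep = ".")),
                           numeric(1)), grades)
  }
  qp <- do.call(rbind, lapply(rownames(default_quintile_probs()), function(ev) {
    get1(paste("quintile_probs", ev, sep = "."))
  }))
  rownames(qp) <- rownames(default_quintile_probs())
  new_generator_config(
    n_cases = get1("n_cases"), learning_break = get1("learning_break"),
    mastery_break = get1("mastery_break"),
    breakthrough_run = get1("breakthrough_run"),
    ot_early = pair("ot_early"), ot_mid = pair("ot_mid"), ot_late = pair("ot_late"),
    hb_early = pair("hb_early"), hb_late = pair("hb_late"),
    ln_count = pair("ln_count", c("mu", "size")), los = pair("los"),
    quintile_probs = qp,
    clavien_low_weights = weights("clavien_low_weights", c("1", "2")),
    clavien_high_weights = weights("clavien_high_weights", c("3a", "3b", "4", "5")),
    seed = get1("seed")
  )
}

# ---- charts ---------------------------------------------------------------

#' Plot a CUSUM trajectory
#'
#' CUSUM value against case number; for binary series the competence
#' control lines (`h_lower`, `2 h_lower`) and the inadequacy boundary
#' (`h_upper`) are drawn as horizontal dashed lines.
#'
#' @param series A `cusum_series`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_cusum <- function(series, title = "CUSUM") {
  stopifnot(inherits(series, "cusum_series"))
  df <- data.frame(case = seq_along(series$values), value = series$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$case, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(title = title, x = "Case number", y = "CUSUM value") +
    ggplot2::theme_minimal()
  if (!is.null(series$limits)) {
    h <- series$limits
    p <- p + ggplot2::geom_hline(
      yintercept = c(h$h_lower, 2 * h$h_lower, h$h_upper),
      linetype = "dashed", colour = c("steelblue", "steelblue", "firebrick")
    )
  }
  p
}

#' Plot the quintile pentafecta benchmark
#'
#' Number of pentafecta items satisfied in each quintile against the
#' quintile end case index, with the benchmark case count marked.
#'
#' @param qb A `quintile_benchmark`.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(qb) {
  stopifnot(inherits(qb, "quintile_benchmark"))
  df <- data.frame(end = qb$bounds[, "end"], satisfied = qb$items_satisfied)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$end, y = .data$satisfied)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 5), breaks = 0:5) +
    ggplot2::labs(x = "Cases completed (quintile end)",
                  y = "Pentafecta items satisfied",
                  title = "Pentafecta benchmark by quintile") +
    ggplot2::theme_minimal()
  bm <- qb$benchmark_case_count
  if (!is.na(bm) && bm > 0) {
    p <- p + ggplot2::geom_vline(xintercept = bm, linetype = "dotted",
                                 colour = "firebrick")
  }
  p
}

# ---- end-to-end report ----------------------------------------------------

#' Run the full learning-curve report on a cohort
#'
#' One invocation of the whole pipeline: cohort summary, continuous CUSUM
#' of operative time and haemoglobin drop, the operative-time plateau rule,
#' binary competence CUSUM of severe complications with SPRT limits, the
#' quintile pentafecta benchmark, and nonparametric across-quintile tests.
#' When `out_dir` is given, the tables are written as CSV and the charts as
#' PNG; outputs are deterministic given the input cohort and settings.
#'
#' @param cohort A `surg_cohort`, or a path to a cohort CSV.
#' @param out_dir Optional output directory (created if needed).
#' @param criteria A [pentafecta_criteria()] object.
#' @param limits SPRT control limits for the severe-complication competence
#'   CUSUM; defaults to `sprt_limits()`.
#' @param plateau_threshold,plateau_run Arguments passed to
#'   [detect_plateau()] for operative time.
#' @return A `report_bundle` list: `summary`, `cusum_ot`, `cusum_hb`,
#'   `plateau_index`, `competence` (signal indices of the severe-complication
#'   CUSUM), `benchmark`, `quintile_tests` (data frame), and `files` (paths
#'   written, if any).
#' @export
run_report <- function(cohort, out_dir = NULL,
                       criteria = pentafecta_criteria(),
                       limits = sprt_limits(),
                       plateau_threshold = 300, plateau_run = 4L) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)

  cusum_ot <- cusum_continuous(cohort$operative_time_min)
  cusum_hb <- cusum_continuous(cohort$hb_drop_gdl)
  plateau_index <- detect_plateau(cohort$operative_time_min,
                                  threshold = plateau_threshold,
                                  run_length = plateau_run)
  severe <- is_high_grade(cohort$max_clavien)
  competence <- detect_competence(cusum_binary(severe, limits))
  qb <- quintile_analysis(cohort, criteria)

  test_vars <- c("operative_time_min", "hb_drop_gdl", "ln_count", "los_days",
                 "any_complication", "clavien_gt2", "psm", "readmitted")
  quintile_tests <- do.call(rbind, lapply(test_vars, function(v) {
    r <- compare_quintiles(cohort, v)
    data.frame(variable = r$variable, method = r$method,
               statistic = r$statistic, df = r$df, p_value = r$p_value)
  }))

  bundle <- structure(
    list(
      summary = summarize_cohort(cohort),
      cusum_ot = cusum_ot, cusum_hb = cusum_hb,
      plateau_index = plateau_index,
      competence = competence,
      benchmark = qb,
      quintile_tests = quintile_tests,
      files = character(0)
    ),
    class = "report_bundle"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(name) file.path(out_dir, name)
    write_series <- function(series, name) {
      utils::write.csv(
        data.frame(case_index = seq_along(series$values), value = series$values),
        fp(name), row.names = FALSE
      )
      fp(name)
    }
    s <- bundle$summary
    files <- c(
      {
        utils::write.csv(cbind(outcome = rownames(s$continuous), s$continuous),
                         fp("summary_continuous.csv"), row.names = FALSE)
        fp("summary_continuous.csv")
      },
      {
        utils::write.csv(cbind(outcome = rownames(s$binary), s$binary),
                         fp("summary_binary.csv"), row.names = FALSE)
        fp("summary_binary.csv")
      },
      write_series(cusum_ot, "cusum_operative_time.csv"),
      write_series(cusum_hb, "cusum_hb_drop.csv"),
      {
        utils::write.csv(cbind(quintile = rownames(qb$failure_rates),
                               as.data.frame(qb$failure_rates)),
                         fp("failure_rates.csv"), row.names = FALSE)
        fp("failure_rates.csv")
      },
      {
        utils::write.csv(cbind(quintile = rownames(qb$pass_matrix),
                               as.data.frame(qb$pass_matrix),
                               items_satisfied = qb$items_satisfied),
                         fp("pass_matrix.csv"), row.names = FALSE)
        fp("pass_matrix.csv")
      },
      {
        utils::write.csv(quintile_tests, fp("quintile_tests.csv"), row.names = FALSE)
        fp("quintile_tests.csv")
      },
      {
        key <- data.frame(
          quantity = c("n_cases", "plateau_index", "competence_index",
                       "inadequacy_index", "benchmark_case_count"),
          value = c(nrow(cohort), plateau_index, competence$competence,
                    competence$inadequacy, qb$benchmark_case_count)
        )
        utils::write.csv(key, fp("key_results.csv"), row.names = FALSE)
        fp("key_results.csv")
      }
    )
    for (pl in list(list(plot_cusum(cusum_ot, "CUSUM of operative time"),
                         "cusum_operative_time.png"),
                    list(plot_benchmark(qb), "pentafecta_benchmark.png"))) {
      ggplot2::ggsave(fp(pl[[2L]]), pl[[1L]], width = 7, height = 4.5, dpi = 150)
      files <- c(files, fp(pl[[2L]]))
    }
    bundle$files <- files
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  print(x$summary)
  cat(sprintf("OT plateau index: %s\n",
              ifelse(is.na(x$plateau_index), "none", x$plateau_index)))
  cat(sprintf("Severe-complication competence signal: %s (inadequacy: %s)\n",
              ifelse(is.na(x$competence$competence), "none", x$competence$competence),
              ifelse(is.na(x$competence$inadequacy), "none", x$competence$inadequacy)))
  print(x$benchmark)
  invisible(x)
}
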