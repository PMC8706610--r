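# Clavien-Dindo grade encoding shared across the package.
clavien_levels <- c("0", "1", "2", "3a", "3b", "4", "5")

clavien_rank <- function(grade) {
  r <- match(as.character(grade), clavien_levels)
  if (anyNA(r)) {
    bad <- which(is.na(r))[1L]
    stop(sprintf("invalid Clavien grade '%s' (allowed: %s)",
                 as.character(grade)[bad], paste(clavien_levels, collapse = ", ")),
         call. = FALSE)
  }
  r - 1L  # 0-based severity; "3a" -> 3
}

is_high_grade <- function(grade) clavien_rank(grade) >= 3L

#' Consecutive quintile partition of a case series
#'
#' Splits cases `1..n` into five consecutive, chronologically ordered
#' groups. The base size is `floor(n / 5)`; any remainder is distributed
#' one case per quintile starting from the last quintile and working
#' backwards, so the later (most experienced) quintiles absorb the extra
#' cases.
#'
#' @param n Number of cases, at least 5.
#' @return Integer matrix with 5 rows and columns `start`, `end`
#'   (1-based, inclusive).
#' @export
quintile_bounds <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 5L) stop("need at least 5 cases to form quintiles", call. = FALSE)
  sizes <- rep(n %/% 5L, 5L)
  r <- n %% 5L
  if (r > 0L) sizes[(5L - r + 1L):5L] <- sizes[(5L - r + 1L):5L] + 1L
  ends <- cumsum(sizes)
  cbind(start = ends - sizes + 1L, end = ends)
}

quintile_index <- function(n) {
  b <- quintile_bounds(n)
  rep.int(1:5, b[, "end"] - b[, "start"] + 1L)
}

default_quintile_probs <- function() {
  rbind(
    any_complication = c(0.35, 0.30, 0.25, 0.20, 0.20),
    clavien_gt2      = c(0.30, 0.25, 0.04, 0.02, 0.02),
    psm              = c(0.15, 0.15, 0.12, 0.08, 0.00),
    ln_low           = c(0.10, 0.05, 0.05, 0.05, 0.00),
    readmission      = c(0.40, 0.35, 0.30, 0.30, 0.30)
  )
}

#' Calibrated default generator configuration
#'
#' Returns the configuration of the synthetic 100-case robot-assisted
#' radical cystectomy cohort the package's analyses and tests run on. The
#' defaults encode a two-stage learning curve:
#'
#' * cases 1-20 (`learning_break = 20`): early phase, highly variable
#'   operative times (log-normal, median 450 min, sdlog 0.25);
#' * cases 21-24 (`breakthrough_run = 4`): a short post-break breakthrough
#'   streak drawn from the post-mastery distribution, reproducing the
#'   first run of consecutive sub-300-min procedures right after the break;
#' * cases 25-60: consolidation (median 400 min) — faster than the early
#'   phase but still mostly above the 300-min pentafecta cut-off;
#' * cases 61-100 (`mastery_break = 60`): routine mastery (median 230 min).
#'
#' Haemoglobin drop switches from a high early distribution (median
#' 3.6 g/dl through case 60) to a low one (median 1.3 g/dl) at the mastery
#' break; the mixture has overall median ~2.7 g/dl. Lymph-node count is
#' negative-binomial (overall median ~32); length of stay log-normal
#' (median 10 d). Binary events (any complication, Clavien >II, positive
#' margin, low node yield <=16, readmission) follow piecewise-constant
#' per-quintile probabilities whose means give ~26, ~12.6, 10, 5 and 33
#' expected events per 100 cases respectively.
#'
#' @param seed Integer RNG seed stored in the configuration.
#' @return A `generator_config` object (validated list).
#' @export
default_config <- function(seed = 1L) {
  new_generator_config(
    n_cases = 100L,
    learning_break = 20L,
    mastery_break = 60L,
    breakthrough_run = 4L,
    ot_early = c(median = 450, sdlog = 0.25),
    ot_mid   = c(median = 400, sdlog = 0.17),
    ot_late  = c(median = 230, sdlog = 0.17),
    hb_early = c(median = 3.6, sdlog = 0.30),
    hb_late  = c(median = 1.3, sdlog = 0.30),
    ln_count = c(mu = 33, size = 13.5),
    los      = c(median = 10, sdlog = 0.327),
    quintile_probs = default_quintile_probs(),
    clavien_low_weights  = c("1" = 9, "2" = 23),
    clavien_high_weights = c("3a" = 7, "3b" = 9, "4" = 1, "5" = 0),
    seed = as.integer(seed)
  )
}

#' Construct and validate a generator configuration
#'
#' Lower-level constructor behind [default_config()]; every field can be
#' overridden. See [default_config()] for field semantics.
#'
#' @param n_cases Number of consecutive cases (>= 5).
#' @param learning_break Case index ending the early operative-time phase.
#' @param mastery_break Case index ending the consolidation phase
#'   (`learning_break < mastery_break <= n_cases`); also the switch point
#'   of the haemoglobin-drop distribution.
#' @param breakthrough_run Number of cases immediately after
#'   `learning_break` drawn from the post-mastery operative-time
#'   distribution (0 disables the streak).
#' @param ot_early,ot_mid,ot_late Named vectors `c(median=, sdlog=)` of the
#'   log-normal operative-time phases (minutes).
#' @param hb_early,hb_late Named vectors `c(median=, sdlog=)` of the
#'   log-normal 24-h haemoglobin-drop magnitude (g/dl).
#' @param ln_count Named vector `c(mu=, size=)` of the negative-binomial
#'   lymph-node count.
#' @param los Named vector `c(median=, sdlog=)` of the log-normal length of
#'   stay (days, rounded to integers >= 1).
#' @param quintile_probs 5x5 numeric matrix, rows `any_complication`,
#'   `clavien_gt2`, `psm`, `ln_low`, `readmission`, columns quintiles 1-5.
#' @param clavien_low_weights Named weights over grades "1","2" for the
#'   severity split of low-grade complications.
#' @param clavien_high_weights Named weights over "3a","3b","4","5" for
#'   high-grade complications.
#' @param seed Integer RNG seed.
#' @return A validated `generator_config`.
#' @export
new_generator_config <- function(n_cases, learning_break, mastery_break,
                                 breakthrough_run, ot_early, ot_mid, ot_late,
                                 hb_early, hb_late, ln_count, los,
                                 quintile_probs, clavien_low_weights,
                                 clavien_high_weights, seed) {
  cfg <- structure(
    list(
      n_cases = as.integer(n_cases),
      learning_break = as.integer(learning_break),
      mastery_break = as.integer(mastery_break),
      breakthrough_run = as.integer(breakthrough_run),
      ot_early = ot_early, ot_mid = ot_mid, ot_late = ot_late,
      hb_early = hb_early, hb_late = hb_late,
      ln_count = ln_count, los = los,
      quintile_probs = quintile_probs,
      clavien_low_weights = clavien_low_weights,
      clavien_high_weights = clavien_high_weights,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_config(cfg)
}

#' Validate a generator configuration
#'
#' Checks field types, ranges and cross-field constraints; every violation
#' is reported with the name of the offending field.
#'
#' @param cfg A `generator_config`.
#' @return `cfg`, invisibly usable, after validation.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "generator_config")) {
    stop("`cfg` must be a generator_config", call. = FALSE)
  }
  fail <- function(field, why) {
    stop(sprintf("invalid generator_config field `%s`: %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$n_cases) || cfg$n_cases < 5L) fail("n_cases", "must be >= 5")
  if (is.na(cfg$learning_break) || cfg$learning_break < 1L) {
    fail("learning_break", "must be a positive integer")
  }
  if (cfg$learning_break >= cfg$n_cases) fail("learning_break", "must be < n_cases")
  if (is.na(cfg$mastery_break) || cfg$mastery_break <= cfg$learning_break ||
      cfg$mastery_break > cfg$n_cases) {
    fail("mastery_break", "must satisfy learning_break < mastery_break <= n_cases")
  }
  if (is.na(cfg$breakthrough_run) || cfg$breakthrough_run < 0L) {
    fail("breakthrough_run", "must be a non-negative integer")
  }
  for (nm in c("ot_early", "ot_mid", "ot_late", "hb_early", "hb_late", "los")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 2L || !all(c("median", "sdlog") %in% names(v))) {
      fail(nm, "must be a named numeric vector c(median=, sdlog=)")
    }
    if (v[["median"]] <= 0 || v[["sdlog"]] <= 0) fail(nm, "median and sdlog must be > 0")
  }
  ln <- cfg$ln_count
  if (!is.numeric(ln) || length(ln) != 2L || !all(c("mu", "size") %in% names(ln)) ||
      ln[["mu"]] <= 0 || ln[["size"]] <= 0) {
    fail("ln_count", "must be a named numeric vector c(mu=, size=) with positive entries")
  }
  qp <- cfg$quintile_probs
  events <- rownames(default_quintile_probs())
  if (!is.matrix(qp) || ncol(qp) != 5L || !all(events %in% rownames(qp))) {
    fail("quintile_probs",
         sprintf("must be a 5-column matrix with rows %s", paste(events, collapse = ", ")))
  }
  if (any(qp < 0 | qp > 1)) fail("quintile_probs", "probabilities must lie in [0, 1]")
  if (any(qp["clavien_gt2", ] > qp["any_complication", ])) {
    fail("quintile_probs",
         "clavien_gt2 probabilities must not exceed any_complication probabilities")
  }
  for (nm in c("clavien_low_weights", "clavien_high_weights")) {
    w <- cfg[[nm]]
    if (!is.numeric(w) || any(w < 0) || sum(w) <= 0 || is.null(names(w))) {
      fail(nm, "must be named non-negative weights with positive sum")
    }
    if (!all(names(w) %in% clavien_levels)) fail(nm, "names must be Clavien grades")
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    paste0("<generator_config> n_cases=%d, learning_break=%d, mastery_break=%d, ",
           "breakthrough_run=%d, seed=%d\n"),
    x$n_cases, x$learning_break, x$mastery_break, x$breakthrough_run, x$seed
  ))
  cat(sprintf("  OT medians (min): early %g / mid %g / late %g\n",
              x$ot_early[["median"]], x$ot_mid[["median"]], x$ot_late[["median"]]))
  cat(sprintf("  Hb drop medians (g/dl): early %g / late %g\n",
              x$hb_early[["median"]], x$hb_late[["median"]]))
  invisible(x)
}

# Inverse-CDF draw from a negative binomial restricted to {<=16} or {>16}.
rln_truncated <- function(n, mu, size, low) {
  p16 <- stats::pnbinom(16, size = size, mu = mu)
  u <- stats::runif(n)
  q <- ifelse(low, u * p16, p16 + u * (1 - p16))
  stats::qnbinom(pmin(q, 1 - 1e-12), size = size, mu = mu)
}

#' Generate a synthetic consecutive-case surgical cohort
#'
#' Draws `cfg$n_cases` consecutive cases from the phase-structured
#' distributions in `cfg`. Operative time follows the early /
#' breakthrough / consolidation / mastery phases; haemoglobin drop switches
#' distribution at the mastery break; binary events are Bernoulli draws at
#' the case's quintile probability. Complications are sampled
#' hierarchically: an any-complication draw first, then a high-grade
#' (Clavien >II) draw conditional on it, then the specific grade from the
#' configured severity weights — so every high-grade case also counts as
#' any-complication by construction. Length of stay and readmission are
#' drawn independently of the complication draws.
#'
#' Identical `(cfg, seed)` give byte-identical cohorts.
#'
#' @param cfg A `generator_config`, e.g. [default_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A `surg_cohort`: data frame with one row per case and columns
#'   `case_index`, `operative_time_min`, `hb_drop_gdl` (positive
#'   magnitude), `max_clavien` (character, one of 0,1,2,3a,3b,4,5), `psm`
#'   (logical), `ln_count` (integer), `los_days` (integer), `readmitted`
#'   (logical).
#' @examples
#' coh <- generate_cohort(default_config(seed = 7))
#' nrow(coh)
#' @export
generate_cohort <- function(cfg, seed = NULL) {
  validate_config(cfg)
  set.seed(if (is.null(seed)) cfg$seed else as.integer(seed))
  n <- cfg$n_cases

  # operative-time phase per case: 1 early, 2 consolidation, 3 mastery,
  # 4 post-break breakthrough streak (drawn from the mastery distribution)
  phase <- integer(n)
  idx <- seq_len(n)
  phase[idx <= cfg$learning_break] <- 1L
  phase[idx > cfg$learning_break & idx <= cfg$mastery_break] <- 2L
  phase[idx > cfg$mastery_break] <- 3L
  bt_end <- min(cfg$learning_break + cfg$breakthrough_run, cfg$mastery_break)
  phase[idx > cfg$learning_break & idx <= bt_end] <- 4L

  ot_pars <- list(cfg$ot_early, cfg$ot_mid, cfg$ot_late, cfg$ot_late)
  ot_med <- vapply(ot_pars, `[[`, numeric(1), "median")
  ot_sd <- vapply(ot_pars, `[[`, numeric(1), "sdlog")
  ot <- stats::rlnorm(n, meanlog = log(ot_med[phase]), sdlog = ot_sd[phase])

  hb_pars <- ifelse(idx <= cfg$mastery_break, "hb_early", "hb_late")
  hb <- stats::rlnorm(
    n,
    meanlog = log(vapply(cfg[hb_pars], `[[`, numeric(1), "median")),
    sdlog = vapply(cfg[hb_pars], `[[`, numeric(1), "sdlog")
  )

  q <- quintile_index(n)
  qp <- cfg$quintile_probs
  p_any <- qp["any_complication", q]
  p_hg <- qp["clavien_gt2", q]
  any_comp <- stats::rbinom(n, 1L, p_any) == 1L
  cond_hg <- ifelse(p_any > 0, p_hg / p_any, 0)
  high <- any_comp & stats::rbinom(n, 1L, cond_hg) == 1L

  draw_grade <- function(k, w) {
    if (k == 0L) character(0)
    else sample(names(w), k, replace = TRUE, prob = w / sum(w))
  }
  grade <- rep("0", n)
  grade[any_comp & !high] <- draw_grade(sum(any_comp & !high), cfg$clavien_low_weights)
  grade[high] <- draw_grade(sum(high), cfg$clavien_high_weights)

  psm <- stats::rbinom(n, 1L, qp["psm", q]) == 1L
  ln_low <- stats::rbinom(n, 1L, qp["ln_low", q]) == 1L
  lnc <- rln_truncated(n, mu = cfg$ln_count[["mu"]], size = cfg$ln_count[["size"]],
                       low = ln_low)
  los <- pmax(1L, as.integer(round(stats::rlnorm(
    n, meanlog = log(cfg$los[["median"]]), sdlog = cfg$los[["sdlog"]]
  ))))
  readm <- stats::rbinom(n, 1L, qp["readmission", q]) == 1L

  new_surg_cohort(data.frame(
    case_index = idx,
    operative_time_min = ot,
    hb_drop_gdl = hb,
    max_clavien = grade,
    psm = psm,
    ln_count = as.integer(lnc),
    los_days = los,
    readmitted = readm,
    stringsAsFactors = FALSE
  ))
}

new_surg_cohort <- function(df) {
  class(df) <- c("surg_cohort", "data.frame")
  df
}

cohort_columns <- c("case_index", "operative_time_min", "hb_drop_gdl",
                    "max_clavien", "psm", "ln_count", "los_days", "readmitted")

validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("`cohort` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols)) {
    stop(sprintf("cohort is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(cohort)
  if (n == 0L) stop("cohort must contain at least one case", call. = FALSE)
  if (!identical(as.integer(cohort$case_index), seq_len(n))) {
    bad <- which(as.integer(cohort$case_index) != seq_len(n))[1L]
    stop(sprintf("column `case_index` must run 1..n without gaps; row %d has %s",
                 bad, cohort$case_index[bad]), call. = FALSE)
  }
  clavien_rank(cohort$max_clavien)  # errors on invalid grades
  invisible(cohort)
}

#' Summarise a surgical cohort
#'
#' Medians and interquartile ranges of the continuous outcomes plus counts
#' and rates of the binary ones — the standard cohort-characteristics
#' table.
#'
#' @param cohort A `surg_cohort` (or compatible data frame).
#' @return A `cohort_summary`: list with `n`, a `continuous` data frame
#'   (median, q25, q75 of operative time, Hb drop, lymph-node count,
#'   length of stay) and a `binary` data frame (count, rate of any
#'   complication, Clavien >II, positive margins, readmission).
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  med_iqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(median = q[2], q25 = q[1], q75 = q[3])
  }
  cont <- rbind(
    operative_time_min = med_iqr(cohort$operative_time_min),
    hb_drop_gdl = med_iqr(cohort$hb_drop_gdl),
    ln_count = med_iqr(cohort$ln_count),
    los_days = med_iqr(cohort$los_days)
  )
  flags <- cbind(
    any_complication = cohort$max_clavien != "0",
    clavien_gt2 = is_high_grade(cohort$max_clavien),
    psm = cohort$psm,
    readmitted = cohort$readmitted
  )
  structure(
    list(
      n = nrow(cohort),
      continuous = as.data.frame(cont),
      binary = data.frame(
        count = colSums(flags),
        rate = colMeans(flags),
        row.names = colnames(flags)
      )
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d cases\n", x$n))
  cat("Continuous outcomes (median [IQR]):\n")
  for (nm in rownames(x$continuous)) {
    v <- x$continuous[nm, ]
    cat(sprintf("  %-20s %.1f [%.1f, %.1f]\n", nm, v$median, v$q25, v$q75))
  }
  cat("Binary outcomes (count, rate):\n")
  for (nm in rownames(x$binary)) {
    cat(sprintf("  %-20s %d (%.0f%%)\n", nm, x$binary[nm, "count"],
                100 * x$binary[nm, "rate"]))
  }
  invisible(x)
}
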