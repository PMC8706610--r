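#' Pentafecta criteria thresholds
#'
#' The five per-case Pasadena-consensus quality items and the quintile
#' failure-rate threshold. A case fails an item when (strict comparisons
#' throughout, matching the "<" / ">" wording of the consensus):
#'
#' * operative time `>= ot_max_min` (default 300 min, i.e. adequate only
#'   when strictly under 5 h);
#' * 24-h haemoglobin drop `>= hb_drop_max_gdl` (default 2 g/dl);
#' * maximum Clavien-Dindo grade at or above `min_severe_grade`
#'   (default "3a", i.e. any grade >II);
#' * positive surgical margin (when `psm_fails`, the default);
#' * lymph-node count `<= ln_min_count` (default 16; complete dissection
#'   requires strictly more than 16 nodes).
#'
#' A quintile passes an item when its failure rate is strictly below
#' `quintile_failure_max` (default 0.20).
#'
#' @param ot_max_min Operative-time threshold in minutes.
#' @param hb_drop_max_gdl Haemoglobin-drop threshold in g/dl.
#' @param min_severe_grade Lowest Clavien grade counted as a severe
#'   complication.
#' @param psm_fails Whether any positive margin is a per-case failure.
#' @param ln_min_count Lymph-node count at or below which the dissection is
#'   incomplete.
#' @param quintile_failure_max Per-quintile failure-rate threshold in
#'   (0, 1).
#' @return A `pentafecta_criteria` object.
#' @export
pentafecta_criteria <- function(ot_max_min = 300, hb_drop_max_gdl = 2,
                                min_severe_grade = "3a", psm_fails = TRUE,
                                ln_min_count = 16L,
                                quintile_failure_max = 0.20) {
  if (!is.numeric(ot_max_min) || ot_max_min <= 0) {
    stop("`ot_max_min` must be > 0", call. = FALSE)
  }
  if (!is.numeric(hb_drop_max_gdl) || hb_drop_max_gdl <= 0) {
    stop("`hb_drop_max_gdl` must be > 0", call. = FALSE)
  }
  if (clavien_rank(min_severe_grade) < 1L) {
    stop("`min_severe_grade` must be a complication grade (not \"0\")", call. = FALSE)
  }
  if (!is.numeric(ln_min_count) || ln_min_count <= 0) {
    stop("`ln_min_count` must be > 0", call. = FALSE)
  }
  if (!is.numeric(quintile_failure_max) || quintile_failure_max <= 0 ||
      quintile_failure_max >= 1) {
    stop("`quintile_failure_max` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      ot_max_min = ot_max_min,
      hb_drop_max_gdl = hb_drop_max_gdl,
      min_severe_grade = as.character(min_severe_grade),
      psm_fails = isTRUE(psm_fails),
      ln_min_count = as.integer(ln_min_count),
      quintile_failure_max = quintile_failure_max
    ),
    class = "pentafecta_criteria"
  )
}

pentafecta_items <- c("ot", "hb_drop", "severe_complication", "psm", "ln_yield")

# n x 5 logical failure matrix for a whole cohort (vectorised core of
# evaluate_case).
failure_matrix <- function(cohort, criteria = pentafecta_criteria()) {
  stopifnot(inherits(criteria, "pentafecta_criteria"))
  needed <- c("operative_time_min", "hb_drop_gdl", "max_clavien", "psm", "ln_count")
  for (col in needed) {
    if (is.null(cohort[[col]])) {
      stop(sprintf("missing field `%s`", col), call. = FALSE)
    }
    if (anyNA(cohort[[col]])) {
      stop(sprintf("missing value in field `%s`", col), call. = FALSE)
    }
  }
  cbind(
    ot = cohort$operative_time_min >= criteria$ot_max_min,
    hb_drop = cohort$hb_drop_gdl >= criteria$hb_drop_max_gdl,
    severe_complication =
      clavien_rank(cohort$max_clavien) >= clavien_rank(criteria$min_severe_grade),
    psm = criteria$psm_fails & as.logical(cohort$psm),
    ln_yield = cohort$ln_count <= criteria$ln_min_count
  )
}

#' Evaluate the five pentafecta items on a single case
#'
#' @param case A single-row data frame (or list) with fields
#'   `operative_time_min`, `hb_drop_gdl`, `max_clavien`, `psm`, `ln_count`.
#' @param criteria A [pentafecta_criteria()] object.
#' @return Named logical vector of per-item *failure* flags: `ot`,
#'   `hb_drop`, `severe_complication`, `psm`, `ln_yield`.
#' @examples
#' ok <- data.frame(operative_time_min = 299.9, hb_drop_gdl = 1.9,
#'                  max_clavien = "0", psm = FALSE, ln_count = 17L)
#' evaluate_case(ok)  # all FALSE
#' @export
evaluate_case <- function(case, criteria = pentafecta_criteria()) {
  case <- as.data.frame(case, stringsAsFactors = FALSE)
  if (nrow(case) != 1L) stop("`case` must describe exactly one case", call. = FALSE)
  failure_matrix(case, criteria)[1L, ]
}

#' Quintile failure-rate benchmark of the pentafecta items
#'
#' Splits a chronologically ordered cohort into five consecutive quintiles
#' (see [quintile_bounds()]), computes the per-quintile failure rate of
#' each pentafecta item, and marks an item as passed in a quintile when its
#' failure rate is strictly below `criteria$quintile_failure_max`.
#'
#' @param cohort A `surg_cohort` with at least 5 cases.
#' @param criteria A [pentafecta_criteria()] object.
#' @return A `quintile_benchmark`: list with `bounds` (5x2), `sizes`,
#'   `failure_rates` (5 quintiles x 5 items), `pass_matrix`,
#'   `items_satisfied` (per-quintile count of passed items),
#'   `benchmark_case_count` (see [benchmark_case_count()]), `threshold`
#'   and `criteria`.
#' @export
quintile_analysis <- function(cohort, criteria = pentafecta_criteria()) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  if (n < 5L) stop("quintile analysis needs a cohort of at least 5 cases", call. = FALSE)
  fails <- failure_matrix(cohort, criteria)
  q <- quintile_index(n)
  rates <- apply(fails, 2L, function(col) tapply(col, q, mean))
  rownames(rates) <- paste0("Q", 1:5)
  pass <- rates < criteria$quintile_failure_max
  qb <- structure(
    list(
      bounds = quintile_bounds(n),
      sizes = as.integer(table(q)),
      failure_rates = rates,
      pass_matrix = pass,
      items_satisfied = rowSums(pass),
      threshold = criteria$quintile_failure_max,
      criteria = criteria
    ),
    class = "quintile_benchmark"
  )
  qb$benchmark_case_count <- benchmark_case_count(qb)
  qb
}

#' @export
print.quintile_benchmark <- function(x, ...) {
  cat(sprintf("<quintile_benchmark> threshold = %.0f%% failure per quintile\n",
              100 * x$threshold))
  tab <- cbind(
    round(100 * x$failure_rates, 1),
    satisfied = x$items_satisfied
  )
  print(tab)
  bm <- x$benchmark_case_count
  cat("benchmark_case_count:",
      if (is.na(bm)) "not reached" else format(bm), "\n")
  invisible(x)
}

# End index of the last quintile failing the given per-quintile pass
# vector; 0 when everything passes, NA when the final quintile fails.
suffix_boundary <- function(pass, bounds) {
  failing <- which(!pass)
  if (!length(failing)) return(0L)
  if (max(failing) == nrow(bounds)) return(NA_integer_)
  unname(bounds[max(failing), "end"])
}

#' Composite pentafecta benchmark case count
#'
#' The number of cases after which all five items are benchmarked: the end
#' index of the last quintile that fails any item, provided every later
#' quintile passes all five. Returns 0 when every quintile (including the
#' first) already passes everything — no learning effect detectable — and
#' `NA` when no all-passing suffix exists (the final quintile still fails
#' an item).
#'
#' @param qb A `quintile_benchmark` from [quintile_analysis()].
#' @return Integer case count, 0, or `NA_integer_`.
#' @export
benchmark_case_count <- function(qb) {
  stopifnot(inherits(qb, "quintile_benchmark"))
  suffix_boundary(apply(qb$pass_matrix, 1L, all), qb$bounds)
}

#' Per-item benchmark boundary
#'
#' Same rule as [benchmark_case_count()] restricted to one item: the end
#' index of the last quintile in which the item fails the failure-rate
#' threshold, provided all later quintiles pass it.
#'
#' @param qb A `quintile_benchmark`.
#' @param item One of `"ot"`, `"hb_drop"`, `"severe_complication"`,
#'   `"psm"`, `"ln_yield"`.
#' @return Integer case count, 0 (item never fails), or `NA_integer_`
#'   (item still failing in the final quintile).
#' @export
item_benchmark_index <- function(qb, item) {
  stopifnot(inherits(qb, "quintile_benchmark"))
  item <- match.arg(item, pentafecta_items)
  suffix_boundary(qb$pass_matrix[, item], qb$bounds)
}

#' Nonparametric comparison of an outcome across quintiles
#'
#' Kruskal-Wallis one-way analysis of variance for continuous outcomes and
#' the chi-square test on the 5 x 2 count table for binary ones, across the
#' five consecutive quintiles of the case series. The derived variables
#' `any_complication` and `clavien_gt2` may be requested by name.
#'
#' @param cohort A `surg_cohort` with at least 5 cases.
#' @param variable Column name (e.g. `"operative_time_min"`, `"psm"`) or
#'   one of the derived names `"any_complication"`, `"clavien_gt2"`.
#' @return List with `variable`, `method` (`"kruskal-wallis"` or
#'   `"chi-square"`), `statistic`, `df` and `p_value`.
#' @export
compare_quintiles <- function(cohort, variable) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  if (n < 5L) stop("need at least 5 cases (one per quintile)", call. = FALSE)
  x <- switch(variable,
    any_complication = cohort$max_clavien != "0",
    clavien_gt2 = is_high_grade(cohort$max_clavien),
    cohort[[variable]]
  )
  if (is.null(x)) stop(sprintf("unknown variable `%s`", variable), call. = FALSE)
  q <- factor(quintile_index(n), levels = 1:5)
  if (any(table(q) == 0L)) stop("every quintile must contain at least one case", call. = FALSE)
  if (is.logical(x)) {
    counts <- rbind(table(q[!x]), table(q[x]))  # 2 x 5: successes, events
    keep <- rowSums(counts) > 0
    if (sum(keep) < 2L) {
      # degenerate: the outcome is constant, no association possible
      res <- list(statistic = 0, df = 4L, p_value = 1)
    } else {
      ct <- suppressWarnings(stats::chisq.test(t(counts), correct = FALSE))
      res <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                  p_value = ct$p.value)
    }
    method <- "chi-square"
  } else if (is.numeric(x)) {
    if (length(unique(x)) == 1L) {
      # all observations tied: no rank variation, statistic is 0 by convention
      res <- list(statistic = 0, df = 4L, p_value = 1)
    } else {
      kw <- stats::kruskal.test(x, q)
      res <- list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                  p_value = kw$p.value)
    }
    method <- "kruskal-wallis"
  } else {
    stop(sprintf("variable `%s` must be numeric or logical", variable), call. = FALSE)
  }
  c(list(variable = variable, method = method), res)
}
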