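test_that("per-case evaluation applies strict thresholds", {
  ok <- data.frame(operative_time_min = 299.9, hb_drop_gdl = 1.9,
                   max_clavien = "0", psm = FALSE, ln_count = 17L)
  expect_false(any(evaluate_case(ok)))

  # boundary cases: printed "<300", "<2", ">16" are strict
  expect_true(evaluate_case(transform(ok, operative_time_min = 300))[["ot"]])
  expect_true(evaluate_case(transform(ok, hb_drop_gdl = 2))[["hb_drop"]])
  expect_true(evaluate_case(transform(ok, ln_count = 16L))[["ln_yield"]])
  expect_true(evaluate_case(transform(ok, psm = TRUE))[["psm"]])

  # Clavien II is not severe, 3a and above are
  expect_false(evaluate_case(transform(ok, max_clavien = "2"))[["severe_complication"]])
  for (g in c("3a", "3b", "4", "5")) {
    expect_true(evaluate_case(transform(ok, max_clavien = g))[["severe_complication"]])
  }

  expect_error(evaluate_case(ok[, setdiff(names(ok), "ln_count")]), "`ln_count`")
  expect_error(evaluate_case(transform(ok, hb_drop_gdl = NA_real_)), "`hb_drop_gdl`")
})

test_that("quintile bounds partition the series with late-biased remainders", {
  b <- quintile_bounds(100)
  expect_equal(b[, "start"], c(1, 21, 41, 61, 81), ignore_attr = TRUE)
  expect_equal(b[, "end"], c(20, 40, 60, 80, 100), ignore_attr = TRUE)

  b12 <- quintile_bounds(12)
  expect_equal(b12[, "end"] - b12[, "start"] + 1L, c(2, 2, 2, 3, 3),
               ignore_attr = TRUE)

  for (n in c(5, 7, 23, 99, 101, 103)) {
    b <- quintile_bounds(n)
    sizes <- b[, "end"] - b[, "start"] + 1L
    expect_equal(sum(sizes), n)
    expect_equal(b[1, "start"], 1, ignore_attr = TRUE)
    expect_equal(b[5, "end"], n, ignore_attr = TRUE)
    expect_true(all(b[-1, "start"] == b[-5, "end"] + 1L))
    expect_true(all(diff(sizes) >= 0))  # remainder goes to later quintiles
  }
  expect_error(quintile_bounds(4), "at least 5")
})

test_that("quintile failure rates match hand counts on the toy cohort", {
  qb <- quintile_analysis(toy_psm_cohort())
  expect_equal(qb$failure_rates[, "psm"], c(0.5, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_false(qb$pass_matrix[1, "psm"])  # 0.5 >= 0.2
  expect_true(all(qb$pass_matrix[2:5, "psm"]))
  expect_true(all(qb$failure_rates[, c("ot", "hb_drop", "severe_complication",
                                       "ln_yield")] == 0))
  expect_equal(qb$items_satisfied, c(4, 5, 5, 5, 5), ignore_attr = TRUE)
  expect_identical(qb$benchmark_case_count, 2L)  # quintile 1 ends at case 2

  perfect <- quintile_analysis(make_cohort(25))
  expect_true(all(perfect$failure_rates == 0))
  expect_true(all(perfect$pass_matrix))
  expect_identical(perfect$benchmark_case_count, 0L)
})

test_that("failure rates are recoverable as integer counts", {
  set.seed(404)
  for (i in 1:20) {
    coh <- generate_cohort(default_config(seed = 1000 + i))
    qb <- quintile_analysis(coh)
    counts <- qb$failure_rates * qb$sizes
    expect_equal(counts, round(counts), tolerance = 1e-9)
    # direct re-scan of one item
    q <- rep(1:5, each = 20)
    expect_equal(qb$failure_rates[, "ot"],
                 tapply(coh$operative_time_min >= 300, q, mean),
                 ignore_attr = TRUE)
  }
})

test_that("benchmark case count reads the pass pattern correctly", {
  # failures confined to quintiles 1-3 of a 100-case series -> 60
  coh <- make_cohort(100, ot = c(rep(400, 60), rep(250, 40)))
  qb <- quintile_analysis(coh)
  expect_identical(benchmark_case_count(qb), 60L)
  expect_identical(item_benchmark_index(qb, "ot"), 60L)
  expect_identical(item_benchmark_index(qb, "psm"), 0L)

  # a failing final quintile -> no benchmark
  qb_na <- quintile_analysis(make_cohort(100, ot = rep(400, 100)))
  expect_true(is.na(benchmark_case_count(qb_na)))

  # per-item boundary: severe complications failing in quintiles 1-2 only -> 40
  coh2 <- make_cohort(100, clavien = c(rep("3b", 40), rep("0", 60)))
  expect_identical(item_benchmark_index(quintile_analysis(coh2),
                                        "severe_complication"), 40L)
})

test_that("improving a case never worsens the benchmark", {
  set.seed(505)
  for (i in 1:40) {
    coh <- generate_cohort(default_config(seed = 2000 + i))
    qb0 <- quintile_analysis(coh)
    j <- sample(nrow(coh), 1)
    coh$operative_time_min[j] <- coh$operative_time_min[j] * 0.5
    coh$hb_drop_gdl[j] <- coh$hb_drop_gdl[j] * 0.5
    coh$max_clavien[j] <- "0"
    coh$psm[j] <- FALSE
    coh$ln_count[j] <- coh$ln_count[j] + 10L
    qb1 <- quintile_analysis(coh)
    expect_true(all(qb1$failure_rates <= qb0$failure_rates))
    bc <- function(x) ifelse(is.na(x), Inf, x)
    expect_lte(bc(qb1$benchmark_case_count), bc(qb0$benchmark_case_count))
  }
})

test_that("across-quintile tests match small-sample oracles", {
  # identical values everywhere: no rank variation
  flat <- compare_quintiles(make_cohort(10, ot = rep(330, 10)), "operative_time_min")
  expect_equal(flat$statistic, 0)

  # homogeneous 5 x 2 table: chi-square statistic 0
  coh <- make_cohort(100, psm = rep(c(rep(TRUE, 4), rep(FALSE, 16)), 5))
  hom <- compare_quintiles(coh, "psm")
  expect_equal(hom$statistic, 0, tolerance = 1e-12)
  expect_equal(hom$df, 4)

  # ordered 1..10 in quintiles of two: H computed by hand from rank sums
  # H = 12/(N(N+1)) * sum(R_j^2 / n_j) - 3(N+1) = 8.7272727...
  kw <- compare_quintiles(make_cohort(10, ot = 1:10), "operative_time_min")
  expect_equal(kw$statistic, 8.7272727273, tolerance = 1e-9)
  expect_equal(kw$df, 4)
  expect_equal(kw$p_value, stats::pchisq(8.7272727273, 4, lower.tail = FALSE),
               tolerance = 1e-9)

  # derived binary variables are accepted
  coh <- generate_cohort(default_config(seed = 3))
  r <- compare_quintiles(coh, "clavien_gt2")
  expect_identical(r$method, "chi-square")
  expect_error(compare_quintiles(coh, "not_a_column"), "unknown variable")
})

test_that("null p-values are approximately uniform", {
  set.seed(606)
  p <- vapply(1:200, function(i) {
    coh <- make_cohort(50, ot = stats::rlnorm(50, log(330), 0.2))
    compare_quintiles(coh, "operative_time_min")$p_value
  }, numeric(1))
  expect_gt(mean(p), 0.40)
  expect_lt(mean(p), 0.60)
  expect_gt(mean(p < 0.1), 0.04)
  expect_lt(mean(p < 0.1), 0.18)
})
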