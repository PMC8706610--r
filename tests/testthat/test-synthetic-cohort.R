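test_that("default configuration encodes the study conditions", {
  cfg <- default_config()
  expect_identical(cfg$n_cases, 100L)
  expect_identical(cfg$learning_break, 20L)
  expect_identical(cfg$mastery_break, 60L)
  qp <- cfg$quintile_probs
  expect_identical(dim(qp), c(5L, 5L))
  # expected positive-margin cases in a 100-case cohort: 20 per quintile
  expect_equal(sum(20 * qp["psm", ]), 10)
  # expected event totals per 100 cases
  expect_equal(sum(20 * qp["any_complication", ]), 26)
  expect_lt(abs(sum(20 * qp["clavien_gt2", ]) - 12), 1)
  # high-grade draws are nested within any-complication draws
  expect_true(all(qp["clavien_gt2", ] <= qp["any_complication", ]))
})

test_that("configuration validation names the offending field", {
  cfg <- default_config()
  bad <- cfg; bad$n_cases <- 3L
  expect_error(validate_config(bad), "`n_cases`")
  bad <- cfg; bad$learning_break <- 100L
  expect_error(validate_config(bad), "`learning_break`")
  bad <- cfg; bad$mastery_break <- 10L
  expect_error(validate_config(bad), "`mastery_break`")
  bad <- cfg; bad$quintile_probs["psm", 1] <- 1.4
  expect_error(validate_config(bad), "`quintile_probs`")
  bad <- cfg; bad$quintile_probs["clavien_gt2", 3] <- 0.9
  expect_error(validate_config(bad), "clavien_gt2")
  bad <- cfg; bad$ot_mid <- c(400, 0.17)  # names dropped
  expect_error(validate_config(bad), "`ot_mid`")
})

test_that("cohort generation is reproducible and structurally sound", {
  cfg <- default_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cfg, seed = 12)))

  expect_identical(nrow(a), 100L)
  expect_identical(a$case_index, 1:100)
  expect_true(all(a$operative_time_min > 0))
  expect_true(all(a$hb_drop_gdl > 0))
  expect_true(all(a$max_clavien %in% c("0", "1", "2", "3a", "3b", "4", "5")))
  expect_true(all(a$ln_count >= 0))
  expect_true(all(a$los_days >= 1))
})

test_that("degenerate event probabilities are honoured", {
  cfg <- default_config(seed = 5)
  cfg$quintile_probs["psm", ] <- 0
  coh <- generate_cohort(cfg)
  expect_identical(sum(coh$psm), 0L)

  cfg$quintile_probs["any_complication", ] <- 0
  cfg$quintile_probs["clavien_gt2", ] <- 0
  coh <- generate_cohort(cfg)
  expect_true(all(coh$max_clavien == "0"))
})

test_that("cohort summaries match hand arithmetic", {
  one <- make_cohort(1, ot = 330)
  s <- summarize_cohort(one)
  expect_equal(unlist(s$continuous["operative_time_min", ]),
               c(median = 330, q25 = 330, q75 = 330))

  two <- make_cohort(2, ot = c(300, 378))
  expect_equal(summarize_cohort(two)$continuous["operative_time_min", "median"], 339)

  flagged <- make_cohort(4, clavien = c("0", "2", "3b", "0"),
                         psm = c(TRUE, FALSE, FALSE, FALSE))
  s <- summarize_cohort(flagged)
  expect_equal(s$binary["any_complication", "count"], 2)
  expect_equal(s$binary["clavien_gt2", "count"], 1)
  expect_equal(s$binary["psm", "rate"], 0.25)

  expect_error(summarize_cohort(make_cohort(1)[0, ]), "at least one")
})

test_that("the learning structure is monotone: early cases run longer", {
  diffs <- vapply(1:25, function(s) {
    coh <- generate_cohort(default_config(seed = s))
    mean(coh$operative_time_min[1:20]) - mean(coh$operative_time_min[21:100])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})
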