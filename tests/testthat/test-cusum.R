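test_that("continuous CUSUM follows the recursion and telescopes", {
  cs <- cusum_continuous(c(4, 6, 5))
  expect_equal(cs$values, c(-1, 0, 0))
  expect_equal(cs$reference, 5)
  expect_identical(cs$kind, "continuous")

  expect_equal(cusum_continuous(rep(7.3, 12))$values, rep(0, 12))

  set.seed(101)
  for (i in 1:50) {
    obs <- stats::rlnorm(sample(1:80, 1), log(300), 0.4)
    cs <- cusum_continuous(obs)
    # telescoping: final value = sum(obs) - n * mean(obs) = 0
    expect_lt(abs(cs$values[length(obs)]), 1e-9)
    # shift invariance: adding a constant (and re-centring on the new mean)
    # leaves the trajectory unchanged
    shifted <- cusum_continuous(obs + 123.4)
    expect_equal(shifted$values, cs$values, tolerance = 1e-10)
    # explicit reference follows the closed form
    ref <- 310
    expect_equal(cusum_continuous(obs, ref)$values, cumsum(obs) - seq_along(obs) * ref)
  }

  expect_error(cusum_continuous(numeric(0)), "at least one")
  expect_error(cusum_continuous(c(1, NA)), "missing")
})

test_that("binary CUSUM matches its closed form f - n*s", {
  lim <- make_limits(s = 0.1, h = 1)
  expect_equal(cusum_binary(rep(FALSE, 10), lim)$values[10], -1.0)
  expect_equal(cusum_binary(rep(TRUE, 4), lim)$values, c(0.9, 1.8, 2.7, 3.6))
  alt <- cusum_binary(rep(c(TRUE, FALSE), 3), make_limits(s = 0.5, h = 1))
  expect_equal(alt$values, c(0.5, 0, 0.5, 0, 0.5, 0))

  set.seed(202)
  for (i in 1:50) {
    f <- stats::runif(sample(1:120, 1)) < 0.3
    s <- stats::runif(1, 0.02, 0.6)
    v <- cusum_binary(f, make_limits(s = s))$values
    expect_equal(v, cumsum(f) - seq_along(f) * s, tolerance = 1e-12)
  }
})

test_that("SPRT limits match the Wald boundary formulas", {
  lim <- sprt_limits(p0 = 0.05, p1 = 0.20, alpha = 0.05, beta = 0.05)
  # frozen values from an independent direct evaluation of the formulas
  expect_equal(lim$s, 0.110291596130601, tolerance = 1e-12)
  expect_equal(lim$h_upper, 1.889708403869399, tolerance = 1e-12)
  expect_equal(lim$h_lower, -1.889708403869399, tolerance = 1e-12)
  expect_equal(lim$boundary_spacing, abs(lim$h_lower))

  # symmetric errors give symmetric boundaries
  lim2 <- sprt_limits(0.1, 0.3, alpha = 0.02, beta = 0.02)
  expect_equal(abs(lim2$h_lower), lim2$h_upper)

  # as p1 -> p0 the decrement tends to p0
  lim3 <- sprt_limits(0.1, 0.1 + 1e-6, 0.05, 0.05)
  expect_equal(lim3$s, 0.1, tolerance = 1e-3)

  expect_error(sprt_limits(0.3, 0.2), "p0 < p1")
  expect_error(sprt_limits(0.05, 0.2, alpha = 0.7), "alpha")
  expect_error(sprt_limits(0.05, 0.2, beta = 0), "beta")
})

test_that("competence and inadequacy signals fire at the closed-form indices", {
  # all-success stream drifts down by s per case; two control lines are
  # crossed once n*s >= 2|h_lower|
  lim <- make_limits(s = 0.1, h = 1)
  det <- detect_competence(cusum_binary(rep(FALSE, 40), lim))
  expect_identical(det$competence, 20L)
  expect_true(is.na(det$inadequacy))

  for (pars in list(c(0.05, 0.20, 0.05, 0.05), c(0.1, 0.3, 0.1, 0.1),
                    c(0.02, 0.1, 0.05, 0.2))) {
    lw <- sprt_limits(pars[1], pars[2], pars[3], pars[4])
    det <- detect_competence(cusum_binary(rep(FALSE, 500), lw))
    expect_identical(det$competence, as.integer(ceiling(2 * abs(lw$h_lower) / lw$s)))
  }

  # all-failure: no competence, inadequacy at the first n with n(1-s) >= h_upper
  lw <- sprt_limits(0.05, 0.20, 0.05, 0.05)
  det <- detect_competence(cusum_binary(rep(TRUE, 50), lw))
  expect_true(is.na(det$competence))
  expect_identical(det$inadequacy, as.integer(ceiling(lw$h_upper / (1 - lw$s))))

  # empty stream: nothing detected
  det <- detect_competence(cusum_binary(logical(0), lw))
  expect_true(is.na(det$competence) && is.na(det$inadequacy))

  expect_error(detect_competence(cusum_continuous(1:3)), "binary")
})

test_that("plateau rule agrees with a brute-force window scan", {
  expect_identical(detect_plateau(c(320, 290, 280, 270, 260)), 2L)
  expect_true(is.na(detect_plateau(c(400, 350, 300, 300, 310))))
  expect_identical(detect_plateau(c(250, 400), run_length = 1), 1L)
  # ties at the threshold count as NOT below it (strict inequality)
  expect_true(is.na(detect_plateau(rep(300, 10))))

  set.seed(303)
  for (i in 1:200) {
    x <- stats::rlnorm(sample(1:200, 1), log(300), 0.3)
    len <- sample(1:6, 1)
    expect_identical(detect_plateau(x, 300, len), plateau_brute(x, 300, len))
  }

  expect_error(detect_plateau(numeric(0)), "at least one")
  expect_error(detect_plateau(1:5, run_length = 0), "positive")
})
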