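#' Continuous (retrospective) CUSUM trajectory
#'
#' Computes the cumulative sum of deviations of an ordered outcome series
#' from a reference value. With the default retrospective reference (the
#' arithmetic mean of the full series) the trajectory starts at
#' `obs[1] - mean(obs)` and telescopes back to zero at the final case, so
#' rising segments mark runs of above-average outcomes (e.g. slow cases
#' early in a learning curve) and falling segments mark below-average runs.
#'
#' The recursion is the classic unreset two-sided form
#' `C[x] = C[x-1] + (obs[x] - reference)`: no resetting after a signal and
#' no one-sided truncation, so the curve is a single uninterrupted
#' trajectory over the whole series.
#'
#' @param observations Numeric vector of outcomes in chronological case
#'   order (e.g. operative time in minutes).
#' @param reference Reference value subtracted at each step. Defaults to
#'   `mean(observations)` (the retrospective convention); supply a fixed
#'   target (e.g. 300 min) for a prospective-style chart.
#' @return A `cusum_series` object: list with `values` (one per case),
#'   `reference`, and `kind = "continuous"`.
#' @examples
#' cs <- cusum_continuous(c(4, 6, 5))
#' cs$values  # -1, 0, 0
#' @export
cusum_continuous <- function(observations, reference = NULL) {
  if (length(observations) == 0L) {
    stop("`observations` must contain at least one value", call. = FALSE)
  }
  if (!is.numeric(observations) || anyNA(observations)) {
    stop("`observations` must be numeric with no missing values", call. = FALSE)
  }
  if (is.null(reference)) reference <- mean(observations)
  stopifnot(is.numeric(reference), length(reference) == 1L, is.finite(reference))
  new_cusum_series(
    values = cumsum(observations - reference),
    reference = reference,
    kind = "continuous"
  )
}

#' Binary competence CUSUM
#'
#' Running sum over a sequence of per-case failure indicators that adds the
#' increment `(1 - s)` on each failure and subtracts the decrement `s` on
#' each success, where `s` is the per-case decrement carried by the control
#' limits. After `n` cases with `f` failures the value is exactly
#' `f - n * s`, so the trajectory drifts downwards while the observed
#' failure rate stays below `s` and upwards when it exceeds it. Crossings
#' of the attached control limits are assessed with [detect_competence()].
#'
#' @param failures Logical (or 0/1) vector, `TRUE` when the case failed the
#'   outcome under surveillance, in chronological order. May be empty, in
#'   which case the trajectory is empty and nothing can be detected.
#' @param limits A `control_limits` object from [sprt_limits()].
#' @return A `cusum_series` object with `kind = "binary"`, `reference = s`,
#'   and the control limits attached as `$limits`.
#' @examples
#' lim <- sprt_limits(0.05, 0.20, 0.05, 0.05)
#' cusum_binary(rep(FALSE, 10), lim)$values[10]  # -10 * s
#' @export
cusum_binary <- function(failures, limits) {
  validate_control_limits(limits)
  if (anyNA(failures)) stop("`failures` must not contain missing values", call. = FALSE)
  f <- as.logical(failures)
  if (length(f) && !all(f %in% c(TRUE, FALSE))) {
    stop("`failures` must be logical or 0/1", call. = FALSE)
  }
  s <- limits$s
  out <- new_cusum_series(
    values = cumsum(ifelse(f, 1 - s, -s)),
    reference = s,
    kind = "binary"
  )
  out$limits <- limits
  out
}

new_cusum_series <- function(values, reference, kind) {
  structure(
    list(values = as.numeric(values), reference = reference, kind = kind),
    class = "cusum_series"
  )
}

#' @export
print.cusum_series <- function(x, ...) {
  cat(sprintf(
    "<cusum_series> kind=%s, n=%d, reference=%.4g, final=%.4g\n",
    x$kind, length(x$values), x$reference,
    if (length(x$values)) x$values[length(x$values)] else NA_real_
  ))
  invisible(x)
}

#' Wald SPRT control limits for a binary competence CUSUM
#'
#' Derives the per-case decrement and the acceptance/rejection boundaries of
#' a binary CUSUM from a sequential probability ratio test between an
#' acceptable failure probability `p0` and an unacceptable one `p1`, at
#' type-I error `alpha` (falsely declaring inadequacy) and type-II error
#' `beta` (falsely declaring competence). With
#' `denom = log(p1/p0) + log((1-p0)/(1-p1))`:
#'
#' * `s       = log((1-p0)/(1-p1)) / denom`
#' * `h_upper =  log((1-beta)/alpha) / denom` (inadequacy boundary)
#' * `h_lower = -log((1-alpha)/beta) / denom` (competence boundary)
#'
#' Successive competence lines sit at `h_lower, 2*h_lower, ...`
#' (`boundary_spacing = |h_lower|`); competence is conventionally declared
#' after two of them are crossed downwards.
#'
#' @param p0,p1 Acceptable and unacceptable failure probabilities,
#'   `0 < p0 < p1 < 1`.
#' @param alpha,beta Type-I and type-II error rates, each in (0, 0.5).
#' @return A `control_limits` object: list with `p0`, `p1`, `alpha`,
#'   `beta`, `s`, `h_upper`, `h_lower`, `boundary_spacing`.
#' @export
sprt_limits <- function(p0 = 0.05, p1 = 0.20, alpha = 0.05, beta = 0.05) {
  for (nm in c("p0", "p1", "alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (!(p0 > 0 && p0 < p1 && p1 < 1)) {
    stop("need 0 < p0 < p1 < 1", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 0.5)) stop("`alpha` must be in (0, 0.5)", call. = FALSE)
  if (!(beta > 0 && beta < 0.5)) stop("`beta` must be in (0, 0.5)", call. = FALSE)
  denom <- log(p1 / p0) + log((1 - p0) / (1 - p1))
  h_lower <- -log((1 - alpha) / beta) / denom
  structure(
    list(
      p0 = p0, p1 = p1, alpha = alpha, beta = beta,
      s = log((1 - p0) / (1 - p1)) / denom,
      h_upper = log((1 - beta) / alpha) / denom,
      h_lower = h_lower,
      boundary_spacing = abs(h_lower)
    ),
    class = "control_limits"
  )
}

validate_control_limits <- function(limits) {
  if (!inherits(limits, "control_limits")) {
    stop("`limits` must be a control_limits object (see sprt_limits())", call. = FALSE)
  }
  stopifnot(
    limits$s > 0, limits$s < 1,
    limits$h_lower < 0, limits$h_upper > 0
  )
  invisible(limits)
}

#' @export
print.control_limits <- function(x, ...) {
  cat(sprintf(
    "<control_limits> p0=%.3g p1=%.3g alpha=%.3g beta=%.3g | s=%.4f h=[%.3f, %.3f]\n",
    x$p0, x$p1, x$alpha, x$beta, x$s, x$h_lower, x$h_upper
  ))
  invisible(x)
}

#' Detect competence and inadequacy signals on a binary CUSUM
#'
#' Competence is declared at the first case whose CUSUM value has crossed
#' two successive lower control lines in a downward fashion, i.e. the first
#' index with `value <= 2 * h_lower`. An inadequacy signal is the first
#' index with `value >= h_upper`. Either signal may be absent (`NA`).
#'
#' @param series A binary-kind `cusum_series` with control limits attached
#'   (from [cusum_binary()]).
#' @return List with integer elements `competence` and `inadequacy`
#'   (1-based case indices, `NA` when never signalled).
#' @export
detect_competence <- function(series) {
  if (!inherits(series, "cusum_series") || series$kind != "binary" ||
      is.null(series$limits)) {
    stop("`series` must be a binary cusum_series with control limits attached",
         call. = FALSE)
  }
  v <- series$values
  first_at <- function(hit) if (any(hit)) which(hit)[1L] else NA_integer_
  list(
    competence = first_at(v <= 2 * series$limits$h_lower),
    inadequacy = first_at(v >= series$limits$h_upper)
  )
}

#' Operative-time plateau rule
#'
#' Finds the first case that begins a run of `run_length` consecutive
#' observations strictly below `threshold`. The defaults encode the plateau
#' definition "more than three consecutive procedures below 300 minutes":
#' a run of at least 4, with ties at exactly the threshold counting as not
#' below it (strict `<`). Set `run_length = 3` to reproduce a "three or
#' more" reading.
#'
#' @param observations Numeric vector in chronological case order.
#' @param threshold Plateau threshold; default 300 (minutes).
#' @param run_length Required run length; default 4.
#' @return 1-based index of the first case of the first qualifying run, or
#'   `NA_integer_` if no such run exists.
#' @examples
#' detect_plateau(c(320, 290, 280, 270, 260))  # 2
#' @export
detect_plateau <- function(observations, threshold = 300, run_length = 4L) {
  if (length(observations) == 0L) {
    stop("`observations` must contain at least one value", call. = FALSE)
  }
  if (!is.numeric(observations) || anyNA(observations)) {
    stop("`observations` must be numeric with no missing values", call. = FALSE)
  }
  run_length <- as.integer(run_length)
  if (is.na(run_length) || run_length < 1L) {
    stop("`run_length` must be a positive integer", call. = FALSE)
  }
  below <- observations < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit)) starts[hit[1L]] else NA_integer_
}
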