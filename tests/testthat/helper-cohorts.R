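# Builders for small deterministic cohorts used across tests.

make_cohort <- function(n,
                        ot = rep(250, n),
                        hb = rep(1.5, n),
                        clavien = rep("0", n),
                        psm = rep(FALSE, n),
                        ln = rep(20L, n),
                        los = rep(10L, n),
                        readmitted = rep(FALSE, n)) {
  structure(
    data.frame(
      case_index = seq_len(n),
      operative_time_min = ot,
      hb_drop_gdl = hb,
      max_clavien = clavien,
      psm = psm,
      ln_count = as.integer(ln),
      los_days = as.integer(los),
      readmitted = readmitted,
      stringsAsFactors = FALSE
    ),
    class = c("surg_cohort", "data.frame")
  )
}

# 10 perfect cases except a positive margin in case 1: PSM failure rates
# by quintile are (0.5, 0, 0, 0, 0) by hand count.
toy_psm_cohort <- function() {
  make_cohort(10, psm = c(TRUE, rep(FALSE, 9)))
}

# Hand-made control limits for closed-form checks (s and h chosen directly).
make_limits <- function(s = 0.1, h = 1) {
  structure(
    list(p0 = NA_real_, p1 = NA_real_, alpha = NA_real_, beta = NA_real_,
         s = s, h_upper = h, h_lower = -h, boundary_spacing = h),
    class = "control_limits"
  )
}

# Brute-force plateau oracle: scan every window of `len` consecutive
# observations strictly below `thr`.
plateau_brute <- function(x, thr = 300, len = 4L) {
  n <- length(x)
  if (n < len) return(NA_integer_)
  for (i in seq_len(n - len + 1L)) {
    if (all(x[i:(i + len - 1L)] < thr)) return(i)
  }
  NA_integer_
}
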