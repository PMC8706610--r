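#!/usr/bin/env Rscript
# Stage 2: CUSUM learning-curve assessment on the generated cohort.
#  - retrospective continuous CUSUM of operative time and Hb drop
#  - operative-time plateau rule (>3 consecutive cases under 300 min)
#  - binary competence CUSUM of severe (Clavien >II) complications with
#    Wald SPRT control limits
# Trajectories go to results/ as CSV; charts as PNG.

library(cusumbench)

cohort <- read_cohort("results/cohort.csv")

cusum_ot <- cusum_continuous(cohort$operative_time_min)
cusum_hb <- cusum_continuous(cohort$hb_drop_gdl)
plateau <- detect_plateau(cohort$operative_time_min, threshold = 300, run_length = 4)

limits <- sprt_limits(p0 = 0.05, p1 = 0.20, alpha = 0.05, beta = 0.05)
severe <- cohort$max_clavien %in% c("3a", "3b", "4", "5")
lc <- cusum_binary(severe, limits)
signals <- detect_competence(lc)

for (x in list(list(cusum_ot, "cusum_operative_time"),
               list(cusum_hb, "cusum_hb_drop"),
               list(lc, "cusum_severe_complications"))) {
  write.csv(data.frame(case_index = seq_along(x[[1]]$values), value = x[[1]]$values),
            sprintf("results/%s.csv", x[[2]]), row.names = FALSE)
}
ggplot2::ggsave("results/cusum_operative_time.png",
                plot_cusum(cusum_ot, "CUSUM of operative time"),
                width = 7, height = 4.5, dpi = 150)
ggplot2::ggsave("results/cusum_severe_complications.png",
                plot_cusum(lc, "Competence CUSUM, severe complications"),
                width = 7, height = 4.5, dpi = 150)

cat(sprintf("Operative-time plateau (first run of 4 cases < 300 min): case %s\n",
            ifelse(is.na(plateau), "never", plateau)))
cat(sprintf("Continuous CUSUM of OT peaks at case %d (value %.0f min)\n",
            which.max(cusum_ot$values), max(cusum_ot$values)))
cat(sprintf(
  "Severe-complication competence CUSUM (s = %.3f, lines at %.2f, %.2f):\n",
  limits$s, limits$h_lower, 2 * limits$h_lower))
cat(sprintf("  competence signal at case %s; inadequacy signal at case %s\n",
            ifelse(is.na(signals$competence), "none", signals$competence),
            ifelse(is.na(signals$inadequacy), "none", signals$inadequacy)))
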