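#!/usr/bin/env Rscript
# Statistical stage on the minute-level AMSA table: per-minute descriptives,
# one-way repeated-measures ANOVA over the knot minutes, Holm-Sidak paired
# comparisons against the end of untreated VF (minute 8), the minute-1
# intrinsic-variability correlations, a simple regression of AMSA on time
# during low-flow support, and a trajectory figure.

library(vfwave)

in_dir <- "results/amsa"
out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

minutes <- read.csv(file.path(in_dir, "amsa_minutes.csv"))
tab <- as_cohort_table(minutes[, c("subject_id", "minute", "amsa_mvhz")])

des <- descriptives(tab)
write.csv(des, file.path(out_dir, "descriptives.csv"), row.names = FALSE)

knot_minutes <- as.character(c(1, 6, 8, 14, 18, 19, 22))
knot_tab <- cohort_table(tab$values[, knot_minutes])
an <- rm_anova(knot_tab)
cat(sprintf("RM-ANOVA over knot minutes: F(%d,%d) = %.2f, p = %.3g (n = %d)\n",
            an$df_effect, an$df_error, an$F, an$p, an$n))

pw <- pairwise_vs_reference(knot_tab, reference = "8")
write.csv(pw, file.path(out_dir, "pairwise_vs_minute8.csv"),
          row.names = FALSE)
cat("Holm-Sidak comparisons vs minute 8:\n")
print(pw, digits = 3)

vc <- baseline_variability_correlations(tab, "1", c("8", "11", "14", "17"))
write.csv(vc, file.path(out_dir, "variability_correlations.csv"),
          row.names = FALSE)
cat("minute-1 anchor correlations:\n")
print(vc, digits = 3)

# AMSA drift over low-flow support (minutes 9-18), per the regression analysis
low_flow <- minutes[minutes$minute %in% 9:18, ]
lr <- simple_linregress(low_flow$minute, low_flow$amsa_mvhz)
cat(sprintf("AMSA vs time during low-flow support: slope = %.3f mV*Hz/min, r = %.3f, p = %.3g\n",
            lr$slope, lr$r, lr$p))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(des, aes(as.integer(timepoint), mean)) +
    geom_ribbon(aes(ymin = mean - sem, ymax = mean + sem), alpha = 0.25) +
    geom_line() + geom_point() +
    labs(x = "Minute from VF onset", y = "AMSA (mV·Hz)",
         title = "Cohort mean ± SEM minute AMSA") +
    theme_minimal()
  ggsave(file.path(out_dir, "amsa_trajectory.pdf"), p, width = 7, height = 4)
}
cat(sprintf("results written under %s\n", out_dir))
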