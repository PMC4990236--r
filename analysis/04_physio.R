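#!/usr/bin/env Rscript
# Physiology stage: derive coronary perfusion pressure, Fick oxygen
# delivery/consumption/extraction, lactate flux, and the veno-arterial PCO2
# gradient from a per-timepoint panel. The study's real panel is not
# redistributable, so a small synthetic panel (labelled as such) with
# physiologically plausible values for baseline, untreated VF at minute 10,
# and late low-flow support illustrates the stage; any CSV with the same
# columns runs identically through read_physio_table().

library(vfwave)

out_dir <- "results/physio"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# synthetic demonstration panel: LAD flow as % of baseline
set.seed(20160822)
n <- 8
panel <- do.call(rbind, lapply(list(
  list(tp = "BL",   map = 92, rap = 5,  flow = 100, cao2 = 12.5, ext = 0.40,
       lac_a = 1.1, dlac = 0.05,  paco2 = 40, dpco2 = 6),
  list(tp = "VF10", map = 48, rap = 38, flow = 30,  cao2 = 12.0, ext = 0.85,
       lac_a = 2.2, dlac = -0.9,  paco2 = 42, dpco2 = 24),
  list(tp = "VF16", map = 50, rap = 40, flow = 30,  cao2 = 11.8, ext = 0.82,
       lac_a = 3.0, dlac = -1.2,  paco2 = 44, dpco2 = 28)),
  function(tpl) {
    data.frame(
      subject_id = sprintf("s%02d", 1:n), timepoint = tpl$tp,
      map_mmHg = rnorm(n, tpl$map, 3), rap_mmHg = rnorm(n, tpl$rap, 2),
      lad_flow = pmax(rnorm(n, tpl$flow, 5), 0),
      cao2_mldl = rnorm(n, tpl$cao2, 0.5),
      cvo2_mldl = rnorm(n, tpl$cao2 * (1 - tpl$ext), 0.4),
      lac_a_mM = rnorm(n, tpl$lac_a, 0.2),
      lac_v_mM = rnorm(n, tpl$lac_a - tpl$dlac, 0.2),
      paco2_mmHg = rnorm(n, tpl$paco2, 2),
      pvco2_mmHg = rnorm(n, tpl$paco2 + tpl$dpco2, 3))
  }))
write.csv(panel, file.path(out_dir, "synthetic_panel.csv"), row.names = FALSE)

derived <- derive_physio(read_physio_table(file.path(out_dir,
                                                     "synthetic_panel.csv")))
write.csv(derived, file.path(out_dir, "derived_quantities.csv"),
          row.names = FALSE)

by_tp <- aggregate(
  derived[, c("cpp_mmHg", "extraction_fraction", "lactate_flux",
              "pco2_gradient_mmHg")],
  list(timepoint = derived$timepoint), mean)
cat("timepoint means of derived quantities",
    "(lactate flux: positive = consumption):\n")
print(by_tp, digits = 3)

# percent-of-baseline normalization of the Fick products
bl <- derived[derived$timepoint == "BL", ]
for (tp in c("VF10", "VF16")) {
  rows <- derived[derived$timepoint == tp, ]
  m <- match(rows$subject_id, bl$subject_id)
  cat(sprintf("%s: MDO2 %.0f%% of baseline, MVO2 %.0f%% of baseline\n", tp,
              mean(percent_of_baseline(rows$mdo2, bl$mdo2[m])),
              mean(percent_of_baseline(rows$mvo2, bl$mvo2[m]))))
}
cat(sprintf("results written under %s\n", out_dir))
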