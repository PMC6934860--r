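#!/usr/bin/env Rscript
# Flow-cytometry efflux assay: PI-negative gating, per-tube MFIs,
# inhibitor retention ratios and transporter ranking for the three
# retention patterns of the study design.

suppressPackageStartupMessages(library(spheroMDR))
dir.create("results", showWarnings = FALSE)

cfg <- default_cohort_config(seed = 1)
rows <- list()
for (nm in names(cfg$subjects)) {
  sub <- cfg$subjects[[nm]]
  fs <- flow_spec(n_events = cfg$flow$n_events,
                  dead_fraction = cfg$flow$dead_fraction,
                  baseline_mfi = cfg$flow$baseline_mfi,
                  retention_ratio = sub$retention,
                  log_sd = cfg$flow$log_sd,
                  replicates = cfg$flow$replicates)
  rep_out <- analyze_flow(make_flow_events(fs, seed = 3))
  cat("\n==", nm, "==\n")
  print(rep_out)
  rows[[nm]] <- data.frame(cell_line = nm, rep_out$ratios,
                           true_ratio = sub$retention[
                             rep_out$ratios$transporter])
}
write.csv(do.call(rbind, rows), "results/flow_retention.csv",
          row.names = FALSE)
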