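#!/usr/bin/env Rscript
# Response-locked classification images and impact curves.
#
# For each simulated observer: the target-field CI over correct trials,
# its center (bars 8-9) and surround (bars 7,10) impact curves, the
# non-target-field CI (expected flat), sliding 500-ms cue-onset epochs
# (shift 250 ms), and the peak impact (mean over 300-400 ms before the
# response) per epoch and cue condition.

suppressPackageStartupMessages(library(rlci))

trials <- read.csv("results/trials.csv")
curves <- list()
peak_rows <- list()

for (oid in unique(trials$observer_id)) {
  stim_path <- file.path("scratch", paste0("stimuli_", oid, ".rds"))
  if (!file.exists(stim_path)) stop("run analysis/01_simulate.R first")
  st <- readRDS(stim_path)
  tr <- trials[trials$observer_id == oid, ]

  cv <- impact_curves(response_locked_ci(tr, st, field = "target"))
  curves[[oid]] <- cv
  write.csv(cv, sprintf("results/impact_%s.csv", oid), row.names = FALSE)

  cv_nt <- impact_curves(response_locked_ci(tr, st, field = "non_target"))
  cat(sprintf("%s: target peak impact %+.4f, non-target %+.4f\n", oid,
              peak_impact(cv)["center"], peak_impact(cv_nt)["center"]))

  for (cond in c("valid", "invalid")) {
    sub <- tr[!is.na(tr$condition) & tr$condition == cond, ]
    for (ep in epoch_cis(sub, st)) {
      if (is.null(ep$ci)) next
      pk <- peak_impact(impact_curves(ep$ci))
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        observer_id = oid, condition = cond,
        epoch_start_ms = ep$epoch_start_ms, epoch_end_ms = ep$epoch_end_ms,
        n_trials = ep$n_trials,
        peak_center = pk["center"], peak_surround = pk["surround"])
    }
  }
}

grand <- aggregate_impact_curves(curves)
write.csv(grand, "results/impact_grand_average.csv", row.names = FALSE)
pk <- do.call(rbind, peak_rows)
rownames(pk) <- NULL
write.csv(pk, "results/peak_impact_by_epoch.csv", row.names = FALSE)
cat("wrote results/impact_grand_average.csv and results/peak_impact_by_epoch.csv\n")

i <- which.max(grand$center)
j <- which(grand$center == min(grand$center[grand$lag_ms <= 1200]))[1]
cat(sprintf("grand center curve: positive peak %+.4f at %.0f ms, negative lobe %+.4f at %.0f ms before the response\n",
            grand$center[i], grand$lag_ms[i], grand$center[j], grand$lag_ms[j]))

pdf("results/impact_curves.pdf", width = 7, height = 5)
plot_impact_curves(grand, main = "Grand-average impact curves (target field)")
dev.off()
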