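#!/usr/bin/env Rscript
# Reaction-time analysis of the simulated sessions.
#
# Epochs the trials by cue onset (100-ms bins), stimulus-locked and
# response-locked, taking per-observer harmonic means first and then the
# across-observer mean and SEM. The headline contrast is the cueing
# advantage: valid-cue responses are faster than invalid-cue responses,
# most prominently when the cue arrives 500-1000 ms before the response.

suppressPackageStartupMessages(library(rlci))

trials <- read.csv("results/trials.csv")
trials$condition <- factor(trials$condition, c("valid", "invalid", "no_cue"))

for (lock in c("stimulus", "response")) {
  tab <- rt_by_cue_onset(trials, lock = lock)
  out <- sprintf("results/rt_%s_locked.csv", lock)
  write.csv(tab, out, row.names = FALSE)
  cat("wrote", out, "\n")
}

ok <- !trials$excluded & !is.na(trials$condition)
hm <- tapply(trials$rt_ms[ok], trials$condition[ok], harmonic_mean_rt)
cat(sprintf("harmonic-mean RT: valid %.0f ms, invalid %.0f ms, no-cue %.0f ms\n",
            hm["valid"], hm["invalid"], hm["no_cue"]))
cat(sprintf("cueing advantage (invalid - valid): %.0f ms\n",
            hm["invalid"] - hm["valid"]))

resp <- rt_by_cue_onset(trials, lock = "response")
win <- resp$epoch_start_ms >= 500 & resp$epoch_end_ms <= 1000
for (cc in c("valid", "invalid")) {
  m <- mean(resp$mean_rt_ms[win & resp$condition == cc])
  cat(sprintf("  response-locked 500-1000 ms epochs, %s cue: %.0f ms\n", cc, m))
}
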