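#!/usr/bin/env Rscript
# Surgical decision algorithm applied to every subject's latest follow-up:
# subjective + objective worsening -> discuss surgery (11 subjects, 42.3%);
# one of the two -> clinic reassessment (7); neither -> continue monitoring
# (8, of which three clinical decliners and one isolated qMRI decliner were
# attributed by the treating team to confounding conditions).

library(dcmmonitor)
dir.create("results", showWarnings = FALSE)

ev <- reference_events()
dec <- decide_cohort(ev)
print(dec$counts)
print(dec$decisions)
write.csv(dec$decisions, "results/decisions.csv", row.names = FALSE)

w <- wilson_cc_interval(unname(dec$counts["progression"]), nrow(dec$decisions))
cat(sprintf("\nProgression at latest follow-up: %d/%d = %.1f%% (95%% CI %.1f-%.1f%%)\n",
            w$k, w$n, w$point, w$lower, w$upper))
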