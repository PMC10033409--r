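#!/usr/bin/env Rscript
# Fits the simulated TCSPC decays, converts amplitude-weighted lifetimes to
# FRET efficiencies against the donor-only lifetime, and calls the three
# conformational states from the buffer / agonist / agonist+effector contrast.

suppressPackageStartupMessages(library(icl3kit))
dir.create("results", showWarnings = FALSE)

tau_donor <- 4.0   # ns, donor-only reference
states <- c(buffer = "closed_inactive", agonist = "intermediate",
            agonist_plus_effector = "open_effector")

rows <- do.call(rbind, lapply(names(states), function(cond) {
  tr <- read_decay_trace(sprintf("results/simulated/decay_%s.csv",
                                 states[[cond]]))
  f <- fit_multiexponential(tr, n = 1)
  data.frame(condition = cond,
             tau_avg_ns = f$tau_avg,
             chi2_reduced = f$chi2_reduced,
             n_components = f$n_effective,
             efficiency = as.numeric(fret_efficiency(f$tau_avg, tau_donor)))
}))
calls <- classify_conformational_state(
  rows[, c("condition", "efficiency")])
rows$call <- calls$call
write.csv(rows, "results/lifetime_fret_states.csv", row.names = FALSE)

cat("per-condition lifetime fits and state calls:\n")
print(rows, row.names = FALSE, digits = 4)
cat(sprintf("\nagonist efficiency swing vs buffer: %+.3f\n",
            rows$efficiency[rows$condition == "agonist"] -
              rows$efficiency[rows$condition == "buffer"]))

## implied donor-acceptor distances under the three-state model (R0 = 50 A)
implied <- vapply(c(37, 29, 43), distance_to_efficiency, numeric(1),
                  forster_radius = 50)
write.csv(data.frame(state = unname(states), distance_A = c(37, 29, 43),
                     model_efficiency = implied),
          "results/three_state_model.csv", row.names = FALSE)
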