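#!/usr/bin/env Rscript
# Generates every synthetic input the downstream analyses consume and writes
# them in the plain-text dialects the package readers understand. All
# generators are seeded, so this script is fully reproducible.

suppressPackageStartupMessages(library(icl3kit))
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)

seed <- 20260101L

## Receptor panel: bimodal ICL3 lengths (modes 20/80), regime-dependent
## coupling promiscuity (second family with p = 0.5 short / 0.1 long)
panel <- gen_receptor_panel(n = 200, seed = seed)
seqs <- Biostrings::AAStringSet(vapply(panel, `[[`, character(1), "sequence"))
names(seqs) <- names(panel)
Biostrings::writeXStringSet(seqs, "results/simulated/panel.fasta")
annot <- do.call(rbind, lapply(panel, function(r) {
  do.call(rbind, lapply(names(r$segments), function(el)
    data.frame(receptor_id = r$receptor_id, element = el,
               start = r$segments[[el]][1], end = r$segments[[el]][2],
               coupling = paste(r$coupling, collapse = "/"),
               class = r$receptor_class)))
}))
write.table(annot, "results/simulated/panel_annot.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## Interface alignments: one consensus per primary-coupling group, planted
## conservation levels
aln <- gen_interface_alignment(c(Gs = 25, Gi = 25, Gq = 25),
                               c(Gs = 0.85, Gi = 0.8, Gq = 0.75),
                               n_positions = 30, seed = seed + 1)
write.table(data.frame(receptor_id = aln$receptor_ids,
                       group = unname(aln$group), aln$residues,
                       check.names = FALSE),
            "results/simulated/interface_alignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## TCSPC decays for the three conformational states (R0 = 50 A, donor 4 ns)
for (st in c("closed_inactive", "intermediate", "open_effector")) {
  d <- gen_decay(state = st, forster_radius = 50, tau_donor = 4,
                 photons = 1e6, window = 25, bins = 512, seed = seed + 2)
  write.csv(data.frame(time_ns = d$bin_centers, counts = d$counts),
            sprintf("results/simulated/decay_%s.csv", st), row.names = FALSE)
}

## Metastable dihedral trajectory with a planted 3-state slow coordinate
traj <- gen_metastable_trajectory(k_states = 3,
                                  stay_probabilities = c(0.98, 0.97, 0.98),
                                  frames = 6000, with_frames = FALSE,
                                  seed = seed + 3)
write.csv(cbind(label = traj$labels, traj$angles),
          "results/simulated/dihedral_trajectory.csv", row.names = FALSE)

## Dose-response data from the wild-type preset (EC50 10 nM)
dd <- gen_dose_response(preset = "fig4c-wt", replicates = 4,
                        noise_sd_fraction = 0.05, seed = seed + 4)
write.csv(dd, "results/simulated/dose_response_fig4c_wt.csv", row.names = FALSE)

## Luciferase kinetic traces (2.4-fold response and a flat control)
kin <- gen_kinetic_trace(baseline = 1000, fold_change = 2.4, noise_sd = 5,
                         seed = seed + 5)
ctl <- gen_kinetic_trace(baseline = 1000, fold_change = 1.0, noise_sd = 5,
                         seed = seed + 6)
write.csv(data.frame(time_s = kin$time, lum = kin$lum,
                     phase = ifelse(seq_along(kin$time) <= kin$drug_index,
                                    "pre", "post")),
          "results/simulated/kinetic_signal.csv", row.names = FALSE)
write.csv(data.frame(time_s = ctl$time, lum = ctl$lum,
                     phase = ifelse(seq_along(ctl$time) <= ctl$drug_index,
                                    "pre", "post")),
          "results/simulated/kinetic_control.csv", row.names = FALSE)

cat("simulated inputs written to results/simulated/\n")
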