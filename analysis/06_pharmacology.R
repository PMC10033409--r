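#!/usr/bin/env Rscript
# Pharmacology workflow: saturation binding, one/two-site competition with
# Cheng-Prusoff conversion, Hill dose-response fitting on the simulated
# wild-type data, and kinetic-trace processing with the replicate Z filter.

suppressPackageStartupMessages(library(icl3kit))
dir.create("results", showWarnings = FALSE)

## saturation binding (simulated noiseless design, pM scale)
L <- rep(10^seq(0.5, 3.5, length.out = 10), each = 2)
bound <- withr::with_seed(21, 100 * L / (50 + L) + rnorm(length(L), 0, 4))
sat <- fit_saturation(L, bound)
cat(sprintf("saturation: Bmax = %.1f, Kd = %.1f pM\n", sat$Bmax, sat$Kd))

## competition: two-site curve, fitted and converted to Ki
A <- seq(-10, -4, by = 0.25)
Y <- icl3kit:::.two_site_curve(A, 100, 0, 0.4, -8, -5.5)
comp <- fit_competition(A, Y, sites = 2, tracer_L = 50e-12,
                        tracer_KD = 25e-12)
cat(sprintf("competition: IC50_1 = %.3g M, IC50_2 = %.3g M, F1 = %.2f\n",
            comp$IC50_1, comp$IC50_2, comp$F1))
cat(sprintf("weighted IC50 = %.3g M -> Ki = %.3g M (Cheng-Prusoff)\n",
            comp$IC50, comp$Ki))

## Hill fit of the replicate-averaged simulated wild-type dose-response
dd <- read.csv("results/simulated/dose_response_fig4c_wt.csv")
avg <- aggregate(response ~ conc, dd, mean)
hill <- fit_hill(avg$conc, avg$response)
cat(sprintf("dose-response: EC50 = %.2f nM, nH = %.2f, efficacy = %.2f\n",
            hill$EC50 * 1e9, hill$NH, hill$efficacy))
write.csv(data.frame(parameter = c("Bmax_sat", "Kd_sat_pM", "IC50_1_M",
                                   "IC50_2_M", "F1", "Ki_M", "EC50_nM",
                                   "nH", "efficacy"),
                     value = c(sat$Bmax, sat$Kd, comp$IC50_1, comp$IC50_2,
                               comp$F1, comp$Ki, hill$EC50 * 1e9, hill$NH,
                               hill$efficacy)),
          "results/pharmacology_fits.csv", row.names = FALSE)

## kinetic traces: smooth, normalize to the last pre-drug point, read the
## plateau, and subtract the control plateau for the specific signal
sig <- read.csv("results/simulated/kinetic_signal.csv")
ctl <- read.csv("results/simulated/kinetic_control.csv")
di_sig <- max(which(sig$phase == "pre"))
di_ctl <- max(which(ctl$phase == "pre"))
rc <- process_kinetic_trace(ctl$time_s, ctl$lum, di_ctl, control_value = 0)
rs <- process_kinetic_trace(sig$time_s, sig$lum, di_sig,
                            control_value = rc$plateau)
cat(sprintf("kinetics: signal plateau %.2f-fold, control %.2f-fold, specific %.2f\n",
            rs$plateau, rc$plateau, rs$specific_signal))
write.csv(data.frame(time_s = sig$time_s, normalized = rs$normalized),
          "results/kinetic_normalized.csv", row.names = FALSE)

## replicate QC: leave-one-out Z filter applied only to flagged replicates
reps <- c(2.38, 2.41, 2.45, 2.36, 3.9, 2.40)
flags <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)  # operator-flagged well
qc <- zscore_outlier_filter(reps, flags)
cat(sprintf("replicate QC: removed %s (|Z| = %.1f), retained n = %d, mean %.2f\n",
            if (length(qc$removed)) paste(qc$removed, collapse = ",") else "none",
            if (length(qc$removed)) abs(qc$z[qc$removed[1]]) else NA,
            length(qc$retained), mean(qc$retained)))
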