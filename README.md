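# icl3kit

Quantitative analysis of how the third intracellular loop (ICL3)
autoregulates G-protein-coupled receptor (GPCR) signalling.

## Scientific problem

ICL3 connects transmembrane helices TM5 and TM6, directly borders the G
protein coupling cavity, and is the most variable element of the receptor
fold — from a handful of residues to hundreds. Rather than being a passive
linker, ICL3 acts as an autoregulatory lid: in the β2-adrenergic-like
receptor it exchanges between a closed/inactive conformation that occludes
the transducer cavity (donor–acceptor distance ≈ 37 Å in intramolecular
FRET), an agonist-induced intermediate that packs closer (≈ 29 Å, the
high-FRET state), and an open, effector-engaged conformation (≈ 43 Å).
Receptor families also split into two selectivity regimes demarcated by
ICL3 length: short loops leave selectivity to the G protein interface,
long loops (≥ 46 residues by default) gate coupling through ICL3 itself.

`icl3kit` provides the full analysis chain needed to test this model
quantitatively:

* **Receptor topology** — ICL3 extraction, N/C loop numbering, and
  round-half-up rescaling of mutation positions onto a 22-residue
  normalized frame for cross-receptor meta-analysis.
* **Selectivity landscape** — diagonal-normalized BLOSUM62 interface
  conservation per coupling group, short/long regime classification,
  Gs/Gq/Gi coupling-overlap (Venn) tallies, and the cognate-vs-secondary
  log10(Emax/EC50) coupling gap.
* **FRET lifetime analysis** — Poisson-weighted multi-exponential TCSPC
  fits, amplitude-weighted lifetimes τ_avg = Σατ/Σα, efficiencies
  E = 1 − τ_DA/τ_D, the Förster relation E = 1/(1 + (r/R0)^6), and
  three-state conformational calls from condition contrasts.
* **Ensemble analysis** — tICA on sin/cos dihedral features, free-energy
  surfaces F = −kT·ln(n/n_max), mini-batch k-means basin decomposition
  with one-basin splitting, and per-subsegment centre-of-mass distance
  profiles from specs like `"241-HVQ/NLS/QVE/QDG/RT-254"`.
* **Pharmacology** — saturation, one/two-site competition with
  Cheng–Prusoff Ki = IC50/(1 + L/KD), 4-parameter Hill dose-response with
  log10(Emax/EC50) efficacy, kinetic-trace normalization and plateau
  reads, and flag-gated leave-one-out Z > 3 replicate filtering.
* **Synthetic data** — seeded, config-carrying generators for every input
  above, used to validate each method against planted ground truth.

See `vignettes/icl3-analysis.Rmd` for models, assumptions and parameter
rationale.

## Worked example

Extract the reference loop, simulate a wild-type dose-response, and fit it:

```r
library(icl3kit)

seg <- extract_icl3(b2ar_like_record())
c(seg$start, seg$end, seg$length)
#> [1] 236 257  22

d <- gen_dose_response(preset = "fig4c-wt", replicates = 4,
                       noise_sd_fraction = 0.05, seed = 11)
avg <- aggregate(response ~ conc, d, mean)
fit_hill(avg$conc, avg$response)
#> <hill_fit> EC50 = 8.899e-09 M, NH = 1.01 , Emax = 0.9881 ,
#>   Emin = -0.02214 , log10(Emax/EC50) = 8.045
```

The planted EC50 is 10 nM; the 4-replicate average at 5% noise recovers
8.9 nM with a Hill slope of 1.01. Lifetime analysis closes the loop from
photon counts back to distance:

```r
dd <- gen_decay(state = "intermediate", forster_radius = 50, tau_donor = 4,
                photons = 1e6, window = 25, seed = 1)
f <- fit_multiexponential(dd, n = 1)
c(tau_avg = f$tau_avg,
  E = as.numeric(fret_efficiency(f$tau_avg, 4)),
  E_model = distance_to_efficiency(29, 50))
#>   tau_avg         E   E_model
#> 0.1466343 0.9633414 0.9633274
```

The fitted efficiency of the 29 Å intermediate matches the Förster-model
value to four decimals. Cross-receptor position mapping:

```r
rescale_position(c(1, 30, 60), 60, 22)   # 60-aa loop onto the 22-aa frame
#> [1]  1 11 22
classify_regime(c(22, 80))
#> [1] "interface_specificity" "gated_by_ICL3"
```

## Analysis workflow

Numbered drivers under `analysis/` run the full pipeline on simulated
inputs and write tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R      # seeded inputs -> results/simulated/
Rscript analysis/02_receptor_topology.R    # segments + mutation meta-analysis
Rscript analysis/03_selectivity_landscape.R
Rscript analysis/04_lifetime_fret.R        # decays -> efficiencies -> state calls
Rscript analysis/05_ensemble_landscape.R   # tICA, FES, basins, loop distances
Rscript analysis/06_pharmacology.R         # binding, competition, Hill, kinetics
```

## License

MIT (see `LICENSE`).
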