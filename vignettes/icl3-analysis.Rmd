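---
title: "Methods: quantifying ICL3-mediated autoregulation of GPCR signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ICL3-mediated autoregulation of GPCR signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icl3kit)
```

This vignette documents the models, assumptions and tunable parameters behind
`icl3kit`, a toolkit for studying how the third intracellular loop (ICL3) of
G-protein-coupled receptors autoregulates signalling. The package covers six
connected analyses: loop topology and cross-receptor position mapping,
the receptor-family selectivity landscape, time-resolved FRET lifetime
analysis, conformational-ensemble decomposition, pharmacological curve
fitting, and seeded synthetic-data generation for end-to-end validation.

## 1. Loop topology and the normalized coordinate frame

ICL3 connects transmembrane helices TM5 and TM6 and varies enormously in
length across receptors. To compare mutational data across loops of
different lengths, the package uses two coordinate systems.

**N/C numbering.** A loop of length $L$ is split into an N-terminal half
(positions $N_1 \dots N_n$ counted inward from TM5) and a C-terminal half
($C_n \dots C_1$ counted inward from TM6), with $n = \lfloor L/2 \rfloor$.
For odd $L$ the unpaired middle residue is assigned to the N side. The map
is a bijection: `map_to_nc_coordinate()` and `nc_to_position()` invert each
other for every position of every length (property-tested for
$L = 1 \dots 60$).

**22-residue normalization.** Aggregation across receptors rescales a
position $p$ in a loop of length $L_s$ onto a target frame of length
$L_t = 22$ (the length of the β~2~-adrenergic-like reference loop used
throughout) with round-half-up linear rescaling

$$p' = \Big\lfloor (p - \tfrac12)\,\frac{L_t}{L_s} + \tfrac12 + \tfrac12 \Big\rfloor$$

clamped to $[1, L_t]$. This map is monotone, hits both endpoints, reaches
every target slot, and distributes source positions near-uniformly across
target slots — all verified by tests. `aggregate_mutation_effects()` uses it
to pool per-position effect sizes (ΔEmax, ΔpEC50, …) from heterologous
receptors; chimera records are excluded by default
(`include_chimera = FALSE`) because a grafted loop's positions are not
comparable.

```{r topology}
seg <- extract_icl3(b2ar_like_record())
c(seg$start, seg$end, seg$length)
map_to_nc_coordinate(12, 22)
rescale_position(c(1, 30, 60), 60, 22)
```

## 2. Selectivity landscape

Receptors split into two selectivity regimes demarcated by ICL3 length
(`classify_regime()`, default threshold **46 residues**, with lengths
$\ge 46$ classed `gated_by_ICL3`). The threshold is an exposed parameter
precisely because the demarcation between 45 and 46 is ambiguous at the
boundary; analyses should report sensitivity to it when boundary-length
receptors matter.

Within each primary-coupling group (Gs/Gi/Gq/G12), G protein interface
conservation is scored by `interface_conservation()`: each receptor's mean
pairwise similarity to its group members, position-averaged. Similarity is
diagonal-normalized BLOSUM62,

$$s(a,b) = \min\!\left(1,\; \frac{M_{ab} - \min M}{\min(M_{aa}, M_{bb}) - \min M}\right),$$

so self-similarity is exactly 1 for every residue; strict identity scoring
is available via `similarity = "identity"`. Gap pairs score 0 and are
counted by default (`gaps = "exclude"` drops them).

`coupling_overlap()` tallies Venn regions of Gs/Gq/Gi coupling per regime
plus a promiscuity index (fraction coupling to ≥ 2 families), and
`cognate_secondary_gap()` ranks transducer families per receptor by
$\log_{10}(E_{max}/EC_{50})$ with ties broken in the fixed order
Gs > Gi > Gq > G12.

## 3. FRET lifetime analysis

Time-correlated single-photon-counting decays are modelled as sums of
exponentials $I(t) = \sum_i A_i e^{-t/\tau_i}$ and fitted by
Poisson-weighted least squares (`fit_multiexponential()`, built on
`minpack.lm::nls.lm`). Amplitudes and lifetimes are log-parameterized for
positivity, five multi-start restarts guard against local minima, and
components are reported sorted by descending lifetime with normalized
amplitudes. The reduced chi-square should sit near 1 for Poisson-consistent
data; values far above ~1.25 suggest a missing component.

The amplitude-weighted lifetime
$\tau_{avg} = \sum_i \alpha_i \tau_i / \sum_i \alpha_i$ converts to FRET
efficiency against a donor-only reference,
$E = 1 - \tau_{DA}/\tau_D$ (donor default $\tau_D = 4.0$ ns in the
generators), and distance maps through the Förster relation
$E = 1/(1 + (r/R_0)^6)$.

The loop adopts three conformational states with distinct donor–acceptor
distances: closed/inactive (~37 Å), an agonist-induced intermediate
(~29 Å, highest efficiency), and an effector-engaged open state (~43 Å,
lowest efficiency). `classify_conformational_state()` calls these from a
buffer / agonist / agonist+effector efficiency contrast, using a minimum
efficiency swing `delta_cutoff = 0.02` (roughly half the ~4% agonist swing)
to avoid calling noise.

```{r fret}
d <- gen_decay(state = "intermediate", forster_radius = 50, tau_donor = 4,
               photons = 1e6, window = 25, seed = 1)
f <- fit_multiexponential(d, n = 1)
c(tau_avg = f$tau_avg,
  E = as.numeric(fret_efficiency(f$tau_avg, 4)),
  E_model = distance_to_efficiency(29, 50))
```

## 4. Ensemble decomposition

Backbone dihedrals are featurized as interleaved, mean-centred
$(\sin\theta, \cos\theta)$ pairs to remove periodicity. `fit_tica()` solves
the symmetrized time-lagged covariance generalized eigenproblem
$C(\tau)\,v = \lambda\,C(0)\,v$ via Cholesky whitening with a small ridge
(`ridge = 1e-6`) for numerical stability. For a planted two-state Markov
chain with transition probabilities $p_{12}, p_{21}$, the leading
eigenvalue at lag $\ell$ has the analytic value
$(1 - p_{12} - p_{21})^\ell$, which the test suite recovers within 0.05.

The 2D tICA projection is histogrammed into a free-energy surface
$F = -k_BT \ln(n_{bin}/n_{max})$ (`free_energy_surface()`, default 100
bins, $k_BT = 1$; empty bins are NA-masked, the occupied minimum is exactly
0). Basins are found with a hand-written mini-batch k-means
(`cluster_states()`: k-means++ initialization, per-centre learning-rate
updates, default batch 1024 / 100 iterations), with `subcluster_states()`
providing the second pass that splits one basin — e.g. four basins plus one
split gives a five-state decomposition.

Loop geometry is quantified on coordinate frames: `parse_segment_spec()`
parses specifications such as `"241-HVQ/NLS/QVE/QDG/RT-254"` (five
subsegments, 14 residues, anchored at 241–254), and
`segment_distance_profile()` reports per-subsegment centre-of-mass distance
quartiles to a reference selection (e.g. an ICL1-like anchor, residues
61–66).

## 5. Pharmacology

All curve fits use `minpack.lm::nlsLM`.

* **Saturation binding** $B = B_{max} L/(K_d + L)$; fits with $K_d$
  outside the sampled ligand range are flagged.
* **Competition** one- and two-site models on $\log_{10}$ competitor
  concentration; the two-site model nests the one-site model exactly at
  fractional occupancy $F_1 \in \{0, 1\}$, and a pinned $F_1$ triggers a
  "consider one-site" warning. The weighted-average IC50
  $F_1\,IC50_1 + (1-F_1)\,IC50_2$ is converted to affinity by
  **Cheng–Prusoff** $K_i = IC50 / (1 + L/K_D)$. Point weighting is linear
  by default with a `weighting = "log"` option.
* **Dose-response** 4-parameter Hill on $\log_{10}$ concentration,
  $E = E_{min} + (E_{max}-E_{min})/(1 + 10^{(\log EC_{50} - \log L)\,n_H})$,
  with efficacy summarized as $\log_{10}(E_{max}/EC_{50})$; EC50s outside
  the tested grid are flagged extrapolated.
* **Kinetic traces** are smoothed with trailing moving averages (3 points
  pre-drug, 8 post-drug), normalized to the last pre-drug point, and the
  plateau is read from the end of the trace subject to a stability
  criterion (last `stability_points = 3` smoothed values within
  `stability_tol = 5%` of each other).
* **Replicate QC**: `zscore_outlier_filter()` removes a replicate only if
  it was independently flagged *and* its leave-one-out Z exceeds 3 —
  unflagged extreme values are never auto-removed.

```{r pharm}
d <- gen_dose_response(preset = "fig4c-wt", replicates = 4,
                       noise_sd_fraction = 0.05, seed = 11)
avg <- aggregate(response ~ conc, d, mean)
fit_hill(avg$conc, avg$response)
```

## 6. Synthetic data: realism and limitations

Every generator is deterministic given `seed` (via `withr::with_seed`, so
the session RNG is untouched) and attaches its full configuration as a
`config` attribute.

* `gen_receptor_panel()` draws bimodal ICL3 lengths (modes 20/80, weights
  0.75/0.25) with regime-dependent coupling promiscuity (probability of a
  second family 0.5 short / 0.1 long). Record 1 is a fixed
  β~2~AR-like receptor (300 aa, ICL3 = residues 236–257, 22 aa, Gs).
* `gen_decay()` produces Poisson-count TCSPC histograms; state presets
  derive the lifetime from the three-state distances and the Förster
  relation. The bin window must cover ≥ 5× the longest lifetime.
* `gen_metastable_trajectory()` emits von Mises dihedrals
  (concentration κ = 8, well-separated means over 4 channels by default)
  from a hidden Markov chain, optionally with paired coordinate frames at
  state-specific loop distances (37/29/43 Å). The von Mises sampler is a
  hand-written Best–Fisher (1979) implementation.
* `gen_coordinate_frames()` plants exact centre-of-mass distances by
  re-centring jitter within each residue group.
* `gen_dose_response(preset = "fig4c-wt")` uses $E_{max}=1$, $E_{min}=0$,
  $EC_{50} = 10$ nM, $n_H = 1$ on a half-log grid from 10 pM to 100 µM,
  4 replicates, Gaussian noise at 5% of $E_{max}$.

Limitations: decays have no instrument response convolution by default
(`use_irf = TRUE` enables it), trajectories have no intra-state kinetics
beyond the Markov chain, and panel sequences are random outside the
annotated segments — the generators validate the *analysis* code, they do
not simulate photophysics or molecular dynamics.

## 7. Design decisions for open modelling questions

* The **45-vs-46** regime boundary is deliberately a default, not a
  constant; `classify_regime(threshold = )` makes sensitivity analyses
  one-liners.
* Conservation similarity is **per-pair diagonal-normalized** BLOSUM62
  rather than a single global min–max, so that identical alignment rows
  score exactly 1 — the property any conservation score should satisfy.
* Odd-length loops assign the middle residue to the **N side**; the
  choice is arbitrary but fixed and bijective.
* The plateau read prefers **stability over recency**: if the trace tail
  fails the stability criterion the plateau is still reported but flagged,
  rather than silently averaging a drifting tail.
* Problem sizes used in validation: 10^5–10^7 photons per decay,
  6,000–10,000 trajectory frames, 15-point half-log dose grids with 4
  replicates.
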