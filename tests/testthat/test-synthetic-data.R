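test_that("generators are byte-deterministic under a fixed seed", {
  expect_identical(gen_receptor_panel(n = 30, seed = 5),
                   gen_receptor_panel(n = 30, seed = 5))
  expect_identical(gen_interface_alignment(c(Gs = 3), c(Gs = 0.8), seed = 5),
                   gen_interface_alignment(c(Gs = 3), c(Gs = 0.8), seed = 5))
  expect_identical(gen_decay(alphas = 1, taus = 2, window = 15, seed = 5),
                   gen_decay(alphas = 1, taus = 2, window = 15, seed = 5))
  expect_identical(gen_metastable_trajectory(frames = 200, seed = 5),
                   gen_metastable_trajectory(frames = 200, seed = 5))
  expect_identical(gen_dose_response(seed = 5), gen_dose_response(seed = 5))
  expect_identical(gen_kinetic_trace(noise_sd = 3, seed = 5),
                   gen_kinetic_trace(noise_sd = 3, seed = 5))
  # different seeds change only the noise realization of a kinetic trace
  t1 <- gen_kinetic_trace(noise_sd = 3, seed = 1)
  t2 <- gen_kinetic_trace(noise_sd = 3, seed = 2)
  expect_identical(t1$time, t2$time)
  expect_false(identical(t1$lum, t2$lum))
  # generators do not disturb the session RNG state
  set.seed(123); before <- .Random.seed
  invisible(gen_dose_response(seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("receptor panels have the planted regime structure", {
  panel <- gen_receptor_panel(n = 200, seed = 1)
  lens <- vapply(panel, function(r) extract_icl3(r)$length, integer(1))
  reg <- classify_regime(lens)
  # recount oracle: regime counts equal direct thresholding of the lengths
  expect_equal(unname(table(reg)["gated_by_ICL3"]),
               table(lens >= 46)["TRUE"], ignore_attr = TRUE)
  # the fixture receptor is present with the 22-residue loop
  expect_equal(extract_icl3(panel$B2AR_like)$length, 22L)
  # every record satisfies its own invariants (extractable, coupled)
  expect_true(all(lengths(lapply(panel, `[[`, "coupling")) >= 1))

  # null scenario: equal second-family probabilities give equal promiscuity
  # within binomial error
  null_panel <- gen_receptor_panel(n = 600, p_short = 0.3, p_long = 0.3,
                                   seed = 2)
  ov <- coupling_overlap(null_panel)
  p1 <- ov$interface_specificity$promiscuity_index
  p2 <- ov$gated_by_ICL3$promiscuity_index
  se <- sqrt(0.3 * 0.7 * (1 / ov$interface_specificity$n +
                            1 / ov$gated_by_ICL3$n))
  expect_lt(abs(p1 - p2), 3 * se)

  expect_error(gen_receptor_panel(length_weights = c(0.5, 0.1)),
               "config error")
})

test_that("interface alignments express the planted conservation levels", {
  # level 1: every member identical to consensus -> score 1
  aln1 <- gen_interface_alignment(c(Gs = 5), c(Gs = 1), seed = 3)
  expect_equal(interface_conservation(aln1)$score, rep(1, 5))

  # level 0 under identity similarity: scores near 0 (random residues agree
  # only by chance)
  aln0 <- gen_interface_alignment(c(Gs = 6), c(Gs = 0), n_positions = 50,
                                  seed = 4)
  sc0 <- interface_conservation(aln0, similarity = "identity")
  expect_lt(mean(sc0$score), 0.15)

  # two groups at levels (0.9, 0.6): means ordered, and within 0.05 of an
  # independent brute-force recomputation
  aln <- gen_interface_alignment(c(Gs = 8, Gi = 8), c(Gs = 0.9, Gi = 0.6),
                                 n_positions = 40, seed = 5)
  sc <- interface_conservation(aln)
  mGs <- mean(sc$score[sc$group == "Gs"])
  mGi <- mean(sc$score[sc$group == "Gi"])
  expect_gt(mGs, mGi)
  bl <- icl3kit:::.blosum62_norm()
  oracle <- vapply(seq_along(aln$receptor_ids), function(i) {
    others <- setdiff(which(aln$group == aln$group[i]), i)
    mean(vapply(seq_len(ncol(aln$residues)), function(p)
      mean(bl[cbind(rep(aln$residues[i, p], length(others)),
                    aln$residues[others, p])]), numeric(1)))
  }, numeric(1))
  expect_lt(max(abs(sc$score - oracle)), 0.05)
  expect_error(gen_interface_alignment(c(Gs = 3), c(Gs = 1.2)), "config error")
})

test_that("decay generation matches its Poisson statistics and presets", {
  # noiseless single-exponential round-trips through the fit
  d <- gen_decay(alphas = 1, taus = 1.5, photons = 1e6, window = 12,
                 noise = FALSE)
  f <- fit_multiexponential(d, n = 1)
  expect_equal(f$components$lifetime_ns, 1.5, tolerance = 1e-4)

  # two seeds: different counts, same expected total within 3 sigma
  d1 <- gen_decay(alphas = 1, taus = 2, photons = 1e5, window = 15, seed = 1)
  d2 <- gen_decay(alphas = 1, taus = 2, photons = 1e5, window = 15, seed = 2)
  expect_false(identical(d1$counts, d2$counts))
  expect_lt(abs(sum(d1$counts) - 1e5), 3 * sqrt(1e5))
  expect_lt(abs(sum(d2$counts) - 1e5), 3 * sqrt(1e5))

  # state presets map through the Förster relation to the documented lifetime
  cfg <- attr(gen_decay(state = "intermediate", forster_radius = 50,
                        window = 25, seed = 1), "config")
  expect_equal(cfg$taus,
               4.0 * (1 - distance_to_efficiency(29, 50)), tolerance = 1e-12)
  expect_error(gen_decay(state = "intermediate"), "config error")
  expect_error(gen_decay(alphas = 1, taus = 10, window = 20), "config error")
})

test_that("metastable trajectories carry the planted chain and distances", {
  # 2-state chain: empirical transition counts match the generator within
  # binomial error
  tr <- gen_metastable_trajectory(k_states = 2,
                                  stay_probabilities = c(0.95, 0.90),
                                  frames = 5000, with_frames = FALSE, seed = 8)
  lab <- tr$labels
  for (s in 1:2) {
    from <- which(lab[-length(lab)] == s)
    p_stay <- mean(lab[from + 1] == s)
    p_true <- c(0.95, 0.90)[s]
    se <- sqrt(p_true * (1 - p_true) / length(from))
    expect_lt(abs(p_stay - p_true), 4 * se)
  }

  # near-absorbing chain: no transitions at a fixed seed
  tr1 <- gen_metastable_trajectory(k_states = 2,
                                   stay_probabilities = c(1 - 1e-9, 1 - 1e-9),
                                   frames = 2000, with_frames = FALSE, seed = 9)
  expect_equal(length(unique(tr1$labels)), 1L)

  # 3-state scenario: per-state ICL3 centre-of-mass distances centre on the
  # planted 37/29/43 A
  tr3 <- gen_metastable_trajectory(k_states = 3, frames = 300, seed = 10)
  d <- vapply(tr3$frames, com_distance, numeric(1),
              selection_a = 236:257, selection_b = 61:66)
  planted <- c(37, 29, 43)
  for (s in 1:3) {
    expect_equal(median(d[tr3$labels == s]), planted[s], tolerance = 0.01)
  }
  expect_error(gen_metastable_trajectory(k_states = 2,
                                         stay_probabilities = c(1, 0.5)),
               "config error")
})

test_that("dose-response and kinetic generators honour their contracts", {
  # zero noise: exact Hill round trip
  d0 <- gen_dose_response(noise_sd_fraction = 0, seed = 1)
  avg <- aggregate(response ~ conc, d0, mean)
  f <- fit_hill(avg$conc, avg$response)
  expect_equal(f$EC50, 10e-9, tolerance = 1e-6)
  expect_equal(f$NH, 1, tolerance = 1e-6)

  # scaling all responses scales Emax, leaves EC50 unchanged
  f2 <- fit_hill(avg$conc, 3 * avg$response)
  expect_equal(f2$Emax, 3 * f$Emax, tolerance = 1e-6)
  expect_equal(f2$EC50, f$EC50, tolerance = 1e-6)

  expect_error(gen_dose_response(concentrations = numeric(0)), "config error")
  expect_error(gen_dose_response(preset = NULL, Emax = 1), "config error")

  # fold change 1 -> specific signal 0 after control subtraction
  k1 <- gen_kinetic_trace(fold_change = 1, noise_sd = 0)
  r1 <- process_kinetic_trace(k1$time, k1$lum, k1$drug_index,
                              control_value = 1)
  expect_equal(r1$specific_signal, 0, tolerance = 1e-12)
  expect_error(gen_kinetic_trace(fold_change = -1), "config error")
  expect_error(gen_kinetic_trace(drug_time = 2000, total_time = 900),
               "config error")
})
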