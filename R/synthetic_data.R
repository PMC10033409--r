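#' @name synthetic_data
#' @title Seeded synthetic-data generators
#' @description
#' Every input the analysis pipeline consumes can be emulated by a seeded
#' generator so the full pipeline is testable offline: receptor panels with
#' bimodal ICL3 lengths and regime-dependent coupling promiscuity,
#' group-structured interface alignments with tunable conservation,
#' Poisson-noise multi-exponential TCSPC decays tied to the three
#' conformational-state probe distances, metastable dihedral trajectories
#' with a planted slow coordinate plus paired coordinate frames, and
#' Hill/competition/kinetic datasets with stated noise. All generators are
#' byte-deterministic under a fixed seed and embed their configuration in a
#' `config` attribute.
NULL

.AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# the 36-residue construct string spanning 228-263; positions 236-257 are the
# 22-residue core loop used for the truncation fixture
.B2AR_ICL3_REGION <- "RQLQKIDKSEGRFHVQNLSQVEQDGRTGHGLRRSSK"

#' The 22-residue beta2AR-like ICL3 fixture record
#'
#' A receptor record whose ICL3 occupies residues 236-257 (sequence
#' `SEGRFHVQNLSQVEQDGRTGHG`, length 22), with TM5/TM6 annotations flanking it,
#' mirroring the beta2 adrenergic receptor loop used throughout the analyses.
#'
#' @param receptor_id Identifier (default `"B2AR_like"`).
#' @return A [receptor_record()].
#' @export
b2ar_like_record <- function(receptor_id = "B2AR_like") {
  seqv <- rep("A", 300)
  seqv[228:263] <- strsplit(.B2AR_ICL3_REGION, "")[[1]]
  receptor_record(receptor_id, paste(seqv, collapse = ""),
                  segments = list(TM5 = c(210L, 235L), ICL3 = c(236L, 257L),
                                  TM6 = c(258L, 285L)),
                  coupling = "Gs", receptor_class = "classA")
}

#' Generate a receptor panel with bimodal ICL3 lengths
#'
#' ICL3 lengths are drawn from a two-component normal mixture (default modes
#' 20 and 80 residues, weights 0.75/0.25, reflecting the roughly 3:1 split of
#' short- versus long-loop receptors). Each receptor gets a primary transducer
#' family (uniform over Gs/Gi/Gq) and, with regime-dependent probability
#' (default 0.5 for the short regime, 0.1 for the long), one additional
#' secondary family — short-loop receptors are the promiscuous ones. Record 1
#' is the [b2ar_like_record()] fixture.
#'
#' @param n Panel size (including the fixture).
#' @param length_modes,length_weights,length_sds Mixture parameters.
#' @param p_short,p_long Second-family probabilities per regime.
#' @param threshold Regime demarcation length (default 46).
#' @param seed Integer seed.
#' @return Named list of [receptor_record()]s with a `config` attribute.
#' @export
gen_receptor_panel <- function(n = 200L, length_modes = c(20, 80),
                               length_weights = c(0.75, 0.25),
                               length_sds = c(8, 15),
                               p_short = 0.5, p_long = 0.1,
                               threshold = 46L, seed = 1L) {
  if (abs(sum(length_weights) - 1) > 1e-8) {
    stop("config error: mixture weights must sum to 1")
  }
  fams <- c("Gs", "Gi", "Gq")
  panel <- withr::with_seed(seed, {
    out <- list(b2ar_like_record())
    for (i in seq_len(n - 1L)) {
      comp <- sample.int(2L, 1L, prob = length_weights)
      L <- max(5L, as.integer(round(stats::rnorm(1, length_modes[comp],
                                                 length_sds[comp]))))
      primary <- sample(fams, 1L)
      p2 <- if (L >= threshold) p_long else p_short
      coup <- primary
      if (stats::runif(1) < p2) coup <- c(coup, sample(setdiff(fams, primary), 1L))
      # layout: 10 aa N-term | TM5 (20 aa) | ICL3 (L aa) | TM6 (20 aa) | 10 aa
      seq_len_total <- 60L + L
      seqv <- sample(.AA20, seq_len_total, replace = TRUE)
      id <- sprintf("R%03d", i)
      out[[i + 1L]] <- receptor_record(
        id, paste(seqv, collapse = ""),
        segments = list(TM5 = c(11L, 30L), ICL3 = c(31L, 30L + L),
                        TM6 = c(31L + L, 50L + L)),
        coupling = coup, receptor_class = "classA")
    }
    out
  })
  names(panel) <- vapply(panel, `[[`, character(1), "receptor_id")
  attr(panel, "config") <- list(generator = "gen_receptor_panel", n = n,
                                length_modes = length_modes,
                                length_weights = length_weights,
                                length_sds = length_sds, p_short = p_short,
                                p_long = p_long, threshold = threshold,
                                seed = seed)
  panel
}

#' Generate a group-structured interface alignment
#'
#' Each primary-coupling group gets a random consensus interface row; each
#' member receptor copies the consensus and mutates every position
#' independently with probability `1 - level` (to a uniformly random
#' different residue), so higher levels yield higher conservation scores.
#'
#' @param group_sizes Named integer vector, members per group
#'   (e.g. `c(Gs = 10, Gi = 10)`).
#' @param conservation_levels Named numeric vector in \[0, 1\], one per group.
#' @param n_positions Interface positions (default 30).
#' @param seed Integer seed.
#' @return An [interface_alignment()] with a `config` attribute.
#' @export
gen_interface_alignment <- function(group_sizes, conservation_levels,
                                    n_positions = 30L, seed = 1L) {
  stopifnot(all(names(group_sizes) %in% names(conservation_levels)))
  if (any(conservation_levels < 0 | conservation_levels > 1)) {
    stop("config error: conservation levels must lie in [0, 1]")
  }
  res <- withr::with_seed(seed, {
    rows <- list(); ids <- character(); grp <- character()
    for (g in names(group_sizes)) {
      consensus <- sample(.AA20, n_positions, replace = TRUE)
      lvl <- conservation_levels[[g]]
      for (m in seq_len(group_sizes[[g]])) {
        row <- consensus
        mut <- stats::runif(n_positions) < (1 - lvl)
        if (any(mut)) {
          row[mut] <- vapply(row[mut], function(a)
            sample(setdiff(.AA20, a), 1L), character(1))
        }
        id <- paste0(g, "_", m)
        rows[[id]] <- row; ids <- c(ids, id); grp <- c(grp, g)
      }
    }
    m <- do.call(rbind, rows)
    rownames(m) <- ids
    list(m = m, group = stats::setNames(grp, ids))
  })
  aln <- interface_alignment(res$m, res$group,
                             positions = paste0("p", seq_len(n_positions)))
  attr(aln, "config") <- list(generator = "gen_interface_alignment",
                              group_sizes = group_sizes,
                              conservation_levels = conservation_levels,
                              n_positions = n_positions, seed = seed)
  aln
}

#' Generate a Poisson-noise multi-exponential TCSPC decay
#'
#' Either from explicit `(alpha, tau)` components or from a conformational
#' state preset, in which case the sensor lifetime is derived from the
#' state's probe distance via the Förster relation applied to a configured
#' donor-only lifetime: `tau = tau_donor * (1 - E(distance, R0))`. Expected
#' bin counts follow the normalized multi-exponential, optionally convolved
#' with a Gaussian IRF, and observed counts are Poisson draws.
#'
#' @param alphas,taus Component amplitudes and lifetimes (ns); ignored when
#'   `state` is given.
#' @param state Optional preset name, see [three_state_distance()].
#' @param forster_radius R0 in Angström (required with `state`).
#' @param tau_donor Donor-only lifetime (ns, default 4.0 — typical for the
#'   green dye class; recorded in metadata).
#' @param photons Expected total photon count.
#' @param bins Number of time bins.
#' @param window Acquisition window (ns); must cover >= 5x the longest
#'   lifetime.
#' @param irf_width Optional Gaussian IRF sigma (ns).
#' @param noise Poisson-sample the counts (`TRUE`, default) or return the
#'   expected (noiseless) histogram rounded to integers.
#' @param seed Integer seed.
#' @return A [decay_trace()] with a `config` attribute.
#' @export
gen_decay <- function(alphas = NULL, taus = NULL, state = NULL,
                      forster_radius = NULL, tau_donor = 4.0,
                      photons = 1e6, bins = 512L, window = 50,
                      irf_width = NULL, noise = TRUE, seed = 1L) {
  if (!is.null(state)) {
    if (is.null(forster_radius)) stop("config error: forster_radius required with a state preset")
    E <- distance_to_efficiency(three_state_distance(state), forster_radius)
    alphas <- 1
    taus <- tau_donor * (1 - E)
  }
  stopifnot(length(alphas) == length(taus), all(taus > 0), photons >= 1)
  if (window < 5 * max(taus)) {
    stop("config error: window must cover >= 5x the longest lifetime")
  }
  t <- seq(window / bins / 2, window - window / bins / 2, length.out = bins)
  expected <- .decay_model(t, alphas / sum(alphas), taus)
  if (!is.null(irf_width)) {
    kt <- seq(-4 * irf_width, 4 * irf_width, by = window / bins)
    k <- stats::dnorm(kt, 0, irf_width)
    expected <- stats::filter(c(rep(0, length(kt) %/% 2), expected,
                                rep(0, length(kt) %/% 2)),
                              k / sum(k), sides = 2)
    expected <- as.numeric(expected)[length(kt) %/% 2 + seq_len(bins)]
  }
  expected <- expected / sum(expected) * photons
  counts <- if (noise) withr::with_seed(seed, stats::rpois(bins, expected))
            else round(expected)
  tr <- decay_trace(t, counts, meta = list(state = state))
  attr(tr, "config") <- list(generator = "gen_decay", alphas = alphas,
                             taus = taus, state = state,
                             forster_radius = forster_radius,
                             tau_donor = tau_donor, photons = photons,
                             bins = bins, window = window,
                             irf_width = irf_width, noise = noise, seed = seed)
  tr
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  theta <- out + mu
  # wrap to (-pi, pi]
  theta <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  theta[theta == -pi] <- pi
  theta
}

#' Generate synthetic coordinate frames with planted loop distances
#'
#' Minimal C-alpha-like frames holding an ICL1-like reference (residues
#' 61-66) at the origin and the 22-residue ICL3 (residues 236-257, one-letter
#' names from the beta2AR-like loop) whose centre of mass sits at a planted
#' distance along x. Per-subsegment distances of the canonical five-segment
#' spec (`"241-HVQ/NLS/QVE/QDG/RT-254"`) can be planted individually; jitter
#' is re-centred within each planted selection so the planted centre-of-mass
#' distances are exact.
#'
#' @param n_frames Number of frames.
#' @param icl3_distance Default ICL3 centre-of-mass distance (Angström); may
#'   be a vector of length `n_frames` for per-frame (e.g. per-state) values.
#' @param segment_distances Optional named vector (names among
#'   `HVQ, NLS, QVE, QDG, RT`) overriding the planted distance for those
#'   subsegments.
#' @param jitter_sd Positional jitter sd in Angström (default 1).
#' @param seed Integer seed.
#' @return List of [coordinate_frame()]s with a `config` attribute.
#' @export
gen_coordinate_frames <- function(n_frames, icl3_distance = 37,
                                  segment_distances = NULL,
                                  jitter_sd = 1, seed = 1L) {
  icl3_resid <- 236:257
  icl3_names <- strsplit(substr(.B2AR_ICL3_REGION, 9, 30), "")[[1]]
  ref_resid <- 61:66
  ref_names <- strsplit("FAILKT", "")[[1]]
  spec <- parse_segment_spec("241-HVQ/NLS/QVE/QDG/RT-254")
  dist_per_frame <- rep_len(icl3_distance, n_frames)
  frames <- withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(fi) {
      d0 <- dist_per_frame[fi]
      # groups of residues sharing one planted COM distance
      groups <- list(default = icl3_resid)
      if (!is.null(segment_distances)) {
        for (sg in names(segment_distances)) {
          rr <- spec$start[spec$segment == sg]:spec$end[spec$segment == sg]
          groups[[sg]] <- rr
          groups$default <- setdiff(groups$default, rr)
        }
      }
      nref <- length(ref_resid)
      ref_xyz <- matrix(stats::rnorm(3 * nref, 0, jitter_sd), nref, 3)
      ref_xyz <- sweep(ref_xyz, 2, colMeans(ref_xyz))  # COM exactly at origin
      pos <- matrix(0, length(icl3_resid), 3)
      for (g in names(groups)) {
        rr <- groups[[g]]
        if (!length(rr)) next
        d <- if (g == "default") d0 else segment_distances[[g]]
        idx <- match(rr, icl3_resid)
        jit <- matrix(stats::rnorm(3 * length(rr), 0, jitter_sd), length(rr), 3)
        jit <- sweep(jit, 2, colMeans(jit))
        pos[idx, ] <- cbind(d, 0, 0)[rep(1, length(rr)), , drop = FALSE] + jit
      }
      coordinate_frame(x = c(ref_xyz[, 1], pos[, 1]),
                       y = c(ref_xyz[, 2], pos[, 2]),
                       z = c(ref_xyz[, 3], pos[, 3]),
                       resid = c(ref_resid, icl3_resid),
                       resname = c(ref_names, icl3_names))
    })
  })
  attr(frames, "config") <- list(generator = "gen_coordinate_frames",
                                 n_frames = n_frames,
                                 icl3_distance = icl3_distance,
                                 segment_distances = segment_distances,
                                 jitter_sd = jitter_sd, seed = seed)
  frames
}

#' Generate a metastable dihedral trajectory with a planted slow coordinate
#'
#' A hidden Markov chain over `k_states` metastable states emits
#' von Mises-distributed backbone dihedral angles around state-specific
#' means, giving a trajectory whose slowest collective coordinate is the
#' planted state sequence — the structure tICA + clustering is expected to
#' recover. Paired coordinate frames place the ICL3-like segment at a
#' state-specific distance (defaults 37/29/43 Angström for three states) from
#' the ICL1-like reference.
#'
#' @param k_states Number of metastable states (>= 2).
#' @param stay_probabilities Per-state self-transition probabilities in
#'   (0, 1); off-diagonal mass split evenly.
#' @param emission_means Optional k x channels matrix of mean angles
#'   (radians); default: well-separated means over 4 channels.
#' @param emission_concentration von Mises concentration kappa (default 8).
#' @param frames Number of frames.
#' @param frame_interval Frame spacing in ns (default 0.2).
#' @param state_distances ICL3 centre-of-mass distance per state (Angström);
#'   default `c(37, 29, 43)` truncated/recycled to `k_states`.
#' @param with_frames Also generate paired coordinate frames? (default TRUE;
#'   turn off for long trajectories where only angles are needed)
#' @param seed Integer seed.
#' @return List: `angles` (frames x channels), `labels` (true states),
#'   `frame_interval`, `frames` (list of coordinate frames or NULL),
#'   `transition_matrix`; plus a `config` attribute.
#' @export
gen_metastable_trajectory <- function(k_states = 3L,
                                      stay_probabilities = rep(0.98, k_states),
                                      emission_means = NULL,
                                      emission_concentration = 8,
                                      frames = 5000L, frame_interval = 0.2,
                                      state_distances = c(37, 29, 43),
                                      with_frames = TRUE, seed = 1L) {
  stopifnot(k_states >= 2L, length(stay_probabilities) == k_states)
  if (any(stay_probabilities <= 0 | stay_probabilities >= 1)) {
    stop("config error: stay probabilities must lie in (0, 1)")
  }
  if (is.null(emission_means)) {
    ch <- 4L
    emission_means <- outer(seq_len(k_states), seq_len(ch), function(s, c)
      -pi + 2 * pi * ((s - 1) / k_states + 0.1 * c / ch))
    emission_means <- emission_means - 2 * pi * floor((emission_means + pi) / (2 * pi))
  }
  emission_means <- as.matrix(emission_means)
  if (nrow(emission_means) != k_states) {
    stop("config error: emission_means must have k_states rows")
  }
  P <- matrix(0, k_states, k_states)
  for (s in seq_len(k_states)) {
    P[s, ] <- (1 - stay_probabilities[s]) / (k_states - 1)
    P[s, s] <- stay_probabilities[s]
  }
  res <- withr::with_seed(seed, {
    labels <- integer(frames)
    labels[1] <- sample.int(k_states, 1L)
    for (i in 2:frames) {
      labels[i] <- sample.int(k_states, 1L, prob = P[labels[i - 1], ])
    }
    ang <- matrix(0, frames, ncol(emission_means))
    for (s in seq_len(k_states)) {
      idx <- which(labels == s)
      for (j in seq_len(ncol(emission_means))) {
        ang[idx, j] <- .rvonmises(length(idx), emission_means[s, j],
                                  emission_concentration)
      }
    }
    list(labels = labels, angles = ang)
  })
  state_distances <- rep_len(state_distances, k_states)
  coord_frames <- NULL
  if (with_frames) {
    coord_frames <- gen_coordinate_frames(
      frames, icl3_distance = state_distances[res$labels],
      seed = seed + 1L)
  }
  out <- list(angles = res$angles, labels = res$labels,
              frame_interval = frame_interval, frames = coord_frames,
              transition_matrix = P)
  attr(out, "config") <- list(generator = "gen_metastable_trajectory",
                              k_states = k_states,
                              stay_probabilities = stay_probabilities,
                              emission_concentration = emission_concentration,
                              n_frames = frames,
                              frame_interval = frame_interval,
                              state_distances = state_distances, seed = seed)
  out
}

#' Dose-response generator presets
#'
#' `"fig4c-wt"`: the wild-type receptor agonist-dose versus InsP1-accumulation
#' curve preset (Emax 1, Emin 0, EC50 10 nM, Hill slope 1).
#'
#' @param name Preset name.
#' @return List with `Emax`, `Emin`, `EC50` (molar), `NH`.
#' @export
dose_response_preset <- function(name = "fig4c-wt") {
  presets <- list(`fig4c-wt` = list(Emax = 1, Emin = 0, EC50 = 10e-9, NH = 1))
  if (!name %in% names(presets)) stop("unknown preset: ", name)
  presets[[name]]
}

#' Generate replicated Hill dose-response data
#'
#' Hill-model responses on a log-spaced concentration grid plus Gaussian
#' noise with standard deviation `noise_sd_fraction * Emax`.
#'
#' @param preset Preset name (see [dose_response_preset()]) or `NULL` to use
#'   the explicit parameters.
#' @param Emax,Emin,EC50,NH Explicit Hill parameters (EC50 molar).
#' @param concentrations Concentration grid (molar); default 10 pM to
#'   100 uM in half-log steps.
#' @param replicates Replicates per concentration (default 4).
#' @param noise_sd_fraction Noise sd as a fraction of Emax (default 0.05).
#' @param seed Integer seed.
#' @return data.frame (`conc`, `replicate`, `response`) with a `config`
#'   attribute.
#' @export
gen_dose_response <- function(preset = "fig4c-wt", Emax = NULL, Emin = NULL,
                              EC50 = NULL, NH = NULL,
                              concentrations = 10^seq(-11, -4, by = 0.5),
                              replicates = 4L, noise_sd_fraction = 0.05,
                              seed = 1L) {
  if (!length(concentrations)) stop("config error: empty concentration grid")
  if (!is.null(preset)) {
    p <- dose_response_preset(preset)
  } else {
    p <- list(Emax = Emax, Emin = Emin, EC50 = EC50, NH = NH)
    if (any(vapply(p, is.null, logical(1)))) {
      stop("config error: supply a preset or all four Hill parameters")
    }
  }
  mu <- .hill_curve(log10(concentrations), p$Emax, p$Emin, log10(p$EC50), p$NH)
  df <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      data.frame(conc = concentrations, replicate = r,
                 response = mu + stats::rnorm(length(mu), 0,
                                              noise_sd_fraction * p$Emax))
    }))
  })
  attr(df, "config") <- c(list(generator = "gen_dose_response",
                               preset = preset, replicates = replicates,
                               noise_sd_fraction = noise_sd_fraction,
                               seed = seed), p)
  df
}

#' Generate a luciferase complementation kinetic trace
#'
#' Flat pre-drug baseline followed by an exponential approach to
#' `baseline * fold_change` after drug addition, with additive Gaussian
#' noise.
#'
#' @param baseline Pre-drug luminescence level.
#' @param fold_change Plateau / baseline ratio (>= 0).
#' @param rise_constant Exponential time constant (s).
#' @param drug_time Drug-addition time (s); must lie within the trace.
#' @param total_time Trace duration (s).
#' @param dt Sampling interval (s).
#' @param noise_sd Additive noise sd (counts).
#' @param seed Integer seed.
#' @return List (`time`, `lum`, `drug_index`) with a `config` attribute.
#' @export
gen_kinetic_trace <- function(baseline = 1000, fold_change = 2.4,
                              rise_constant = 30, drug_time = 300,
                              total_time = 900, dt = 5, noise_sd = 0,
                              seed = 1L) {
  if (fold_change < 0) stop("config error: negative fold_change")
  time <- seq(0, total_time, by = dt)
  if (drug_time <= 0 || drug_time >= total_time) {
    stop("config error: drug_time must lie within the trace")
  }
  mu <- ifelse(time <= drug_time, baseline,
               baseline * (1 + (fold_change - 1) *
                             (1 - exp(-(time - drug_time) / rise_constant))))
  lum <- withr::with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  out <- list(time = time, lum = lum,
              drug_index = max(which(time <= drug_time)))
  attr(out, "config") <- list(generator = "gen_kinetic_trace",
                              baseline = baseline, fold_change = fold_change,
                              rise_constant = rise_constant,
                              drug_time = drug_time, total_time = total_time,
                              dt = dt, noise_sd = noise_sd, seed = seed)
  out
}
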