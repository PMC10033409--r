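#' Fit a saturation-binding curve
#'
#' `bound = Bmax * L / (Kd + L)` by nonlinear least squares, used to obtain
#' the tracer's equilibrium dissociation constant from specific binding at
#' increasing tracer concentrations. The fit is flagged when the recovered Kd
#' falls outside 100x the tested concentration range.
#'
#' @param L Tracer concentrations (same unit as the Kd you want, e.g. pM).
#' @param bound Specific binding signal.
#' @return List of class `saturation_fit`: `Bmax`, `Kd`, `fitted`, `flag`.
#' @export
fit_saturation <- function(L, bound) {
  stopifnot(length(L) == length(bound))
  if (length(unique(L)) < 4L) stop("need >= 4 tracer concentrations")
  start <- list(Bmax = max(bound), Kd = stats::median(L))
  fit <- minpack.lm::nlsLM(bound ~ Bmax * L / (Kd + L), start = start,
                           lower = c(Bmax = 0, Kd = .Machine$double.eps),
                           data = data.frame(L = L, bound = bound))
  p <- stats::coef(fit)
  flag <- if (p[["Kd"]] < min(L[L > 0]) / 100 || p[["Kd"]] > max(L) * 100)
    "Kd_outside_data_range" else NA_character_
  structure(list(Bmax = p[["Bmax"]], Kd = p[["Kd"]],
                 fitted = stats::fitted(fit), flag = flag),
            class = "saturation_fit")
}

.one_site_curve <- function(A, Bmax, Bmin, logIC50) {
  (Bmax - Bmin) / (1 + 10^(A - logIC50)) + Bmin
}

.two_site_curve <- function(A, Bmax, Bmin, F1, logIC50_1, logIC50_2) {
  F1 * (Bmax - Bmin) / (1 + 10^(A - logIC50_1)) +
    (1 - F1) * (Bmax - Bmin) / (1 + 10^(A - logIC50_2)) + Bmin
}

#' Fit a one- or two-site competition (displacement) binding curve
#'
#' One-site: `Y = (Bmax - Bmin) / (1 + 10^(A - log10 IC50)) + Bmin` with `A`
#' the log10 competitor concentration. The two-site model splits the specific
#' window across two affinities with fraction `F1` on site 1; the weighted
#' average IC50 (`F1 * IC50_1 + (1 - F1) * IC50_2` on the linear scale by
#' default, `weighting = "log"` for the geometric analogue) is reported for
#' comparison and Cheng-Prusoff conversion. When tracer concentration and
#' tracer KD are supplied (same molar units as `10^A`), the inhibition
#' constant Ki is attached via [cheng_prusoff()].
#'
#' @param A log10 competitor concentrations (molar).
#' @param Y Percent tracer bound.
#' @param sites 1 or 2.
#' @param tracer_L,tracer_KD Optional tracer concentration and KD (molar).
#' @param weighting `"linear"` (default) or `"log"` weighted-average IC50 for
#'   two-site fits.
#' @return List of class `competition_fit` with plateaus, `sites`, `IC50`
#'   (molar; the weighted average for two-site), site-wise parameters for
#'   two-site fits, `Ki` (if tracer given), `fitted`, `flag`.
#' @export
fit_competition <- function(A, Y, sites = 1L, tracer_L = NULL, tracer_KD = NULL,
                            weighting = c("linear", "log")) {
  stopifnot(length(A) == length(Y), sites %in% 1:2)
  weighting <- match.arg(weighting)
  d <- data.frame(A = A, Y = Y)
  flag <- NA_character_
  if (sites == 1L) {
    fit <- minpack.lm::nlsLM(
      Y ~ .one_site_curve(A, Bmax, Bmin, logIC50), data = d,
      start = list(Bmax = max(Y), Bmin = min(Y), logIC50 = stats::median(A)))
    p <- stats::coef(fit)
    IC50 <- 10^p[["logIC50"]]
    out <- list(Bmax = p[["Bmax"]], Bmin = p[["Bmin"]], sites = 1L,
                IC50 = IC50)
  } else {
    fit <- minpack.lm::nlsLM(
      Y ~ .two_site_curve(A, Bmax, Bmin, F1, logIC50_1, logIC50_2), data = d,
      start = list(Bmax = max(Y), Bmin = min(Y), F1 = 0.5,
                   logIC50_1 = stats::quantile(A, 0.33, names = FALSE),
                   logIC50_2 = stats::quantile(A, 0.67, names = FALSE)),
      lower = c(Bmax = -Inf, Bmin = -Inf, F1 = 0, logIC50_1 = -Inf,
                logIC50_2 = -Inf),
      upper = c(Bmax = Inf, Bmin = Inf, F1 = 1, logIC50_1 = Inf,
                logIC50_2 = Inf))
    p <- stats::coef(fit)
    F1 <- p[["F1"]]
    ic1 <- 10^p[["logIC50_1"]]; ic2 <- 10^p[["logIC50_2"]]
    if (F1 < 1e-3 || F1 > 1 - 1e-3) {
      flag <- "F1_pinned_consider_one_site"
      warning("two-site fit pinned F1 at a boundary; a one-site model is ",
              "likely adequate")
    }
    IC50 <- if (weighting == "linear") F1 * ic1 + (1 - F1) * ic2
            else 10^(F1 * log10(ic1) + (1 - F1) * log10(ic2))
    out <- list(Bmax = p[["Bmax"]], Bmin = p[["Bmin"]], sites = 2L,
                F1 = F1, IC50_1 = ic1, IC50_2 = ic2, IC50 = IC50)
  }
  out$fitted <- stats::fitted(fit)
  out$flag <- flag
  if (!is.null(tracer_L) && !is.null(tracer_KD)) {
    out$Ki <- cheng_prusoff(out$IC50, tracer_L, tracer_KD)
    out$tracer_L <- tracer_L
    out$tracer_KD <- tracer_KD
  }
  structure(out, class = "competition_fit")
}

#' Cheng-Prusoff conversion of IC50 to the inhibition constant Ki
#'
#' `Ki = IC50 / (1 + L / KD)` where `L` is the tracer concentration and `KD`
#' its equilibrium dissociation constant; Ki <= IC50 always.
#'
#' @param IC50 Half-maximal displacement concentration (molar).
#' @param L Tracer concentration (molar).
#' @param KD Tracer dissociation constant (molar).
#' @return Ki in the units of `IC50`.
#' @export
#' @examples
#' cheng_prusoff(300e-9, 50e-12, 25e-12)  # 100 nM
cheng_prusoff <- function(IC50, L, KD) {
  if (any(c(IC50, L, KD) <= 0)) stop("input error: all inputs must be > 0")
  IC50 / (1 + L / KD)
}

.hill_curve <- function(logL, Emax, Emin, logEC50, NH) {
  (Emax - Emin) / (1 + 10^((logEC50 - logL) * NH)) + Emin
}

#' Fit a four-parameter Hill dose-response curve
#'
#' `E = (Emax - Emin) / (1 + 10^((log10 EC50 - log10 L) * NH)) + Emin`, fit on
#' log10 concentration by nonlinear least squares. Also reports the efficacy
#' metric `log10(Emax / EC50)` used to compare agonist signalling across
#' receptors. The fit is flagged when the recovered EC50 lies outside 100x
#' the tested concentration range (extrapolation).
#'
#' @param L Agonist concentrations (molar), >= 5 distinct values spanning the
#'   transition.
#' @param E Responses.
#' @return List of class `hill_fit`: `Emax`, `Emin`, `EC50` (molar), `NH`,
#'   `efficacy`, `fitted`, `flag`.
#' @export
fit_hill <- function(L, E) {
  stopifnot(length(L) == length(E), all(L > 0))
  if (length(unique(L)) < 5L) stop("need >= 5 concentrations")
  d <- data.frame(logL = log10(L), E = E)
  fit <- minpack.lm::nlsLM(
    E ~ .hill_curve(logL, Emax, Emin, logEC50, NH), data = d,
    start = list(Emax = max(E), Emin = min(E),
                 logEC50 = stats::median(d$logL), NH = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  EC50 <- 10^p[["logEC50"]]
  flag <- if (EC50 < min(L) / 100 || EC50 > max(L) * 100)
    "EC50_extrapolated" else NA_character_
  efficacy <- if (p[["Emax"]] > 0) log10(p[["Emax"]] / EC50) else NA_real_
  structure(list(Emax = p[["Emax"]], Emin = p[["Emin"]], EC50 = EC50,
                 NH = p[["NH"]], efficacy = efficacy,
                 fitted = stats::fitted(fit), flag = flag),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit> EC50 =", signif(x$EC50, 4), "M, NH =", signif(x$NH, 3),
      ", Emax =", signif(x$Emax, 4), ", Emin =", signif(x$Emin, 4),
      ", log10(Emax/EC50) =", signif(x$efficacy, 4), "\n")
  invisible(x)
}

#' Acceptor/donor emission FRET ratio
#'
#' @param acceptor,donor Emission counts; `donor > 0`.
#' @return `acceptor / donor`.
#' @export
fret_ratio <- function(acceptor, donor) {
  if (any(donor <= 0)) stop("input error: donor emission must be > 0")
  acceptor / donor
}

#' Differential (treated minus reference) assay metric
#'
#' The common difference construction behind the ΔFRET readout (isoproterenol
#' minus buffer FRET ratios), the InsP1 HTRF signal (with-drug minus no-drug
#' average ratios) and normalized cAMP differences:
#' `mean(treated) - mean(reference)`.
#'
#' @param treated,reference Numeric measurement vectors (>= 1 each). For the
#'   HTRF modes these are acceptor/donor ratios, see [fret_ratio()].
#' @param mode Label recorded on the result: `"FRET_ratio"`, `"InsP1"` or
#'   `"cAMP_norm"`.
#' @return Numeric difference with attribute `mode`.
#' @export
delta_metric <- function(treated, reference,
                         mode = c("FRET_ratio", "InsP1", "cAMP_norm")) {
  mode <- match.arg(mode)
  if (!length(treated) || !length(reference)) stop("input error: empty arm")
  out <- mean(treated) - mean(reference)
  attr(out, "mode") <- mode
  out
}

#' Percent bound from a pulldown depletion measurement
#'
#' `100 * (total_peak - mean(supernatant_peaks)) / total_peak`: the fraction
#' of fluorescent receptor depleted from the supernatant after bead
#' precipitation. Values outside \[0, 100\] are flagged, not clamped.
#'
#' @param total_peak Peak fluorescence of the total-receptor sample (> 0).
#' @param supernatant_peaks Peak fluorescence counts of the supernatant
#'   replicates.
#' @return Percent bound; attribute `flag` set when outside \[0, 100\].
#' @export
percent_bound <- function(total_peak, supernatant_peaks) {
  if (total_peak <= 0) stop("input error: total_peak must be > 0")
  pb <- 100 * (total_peak - mean(supernatant_peaks)) / total_peak
  if (pb < 0 || pb > 100) attr(pb, "flag") <- "outside_0_100"
  pb
}

.moving_average <- function(v, width) {
  # trailing window, shortened at the left edge
  out <- numeric(length(v))
  cs <- cumsum(v)
  for (i in seq_along(v)) {
    lo <- max(1L, i - width + 1L)
    out[i] <- (cs[i] - if (lo > 1L) cs[lo - 1L] else 0) / (i - lo + 1L)
  }
  out
}

#' Process a luciferase complementation kinetic trace
#'
#' Smooths the pre-drug equilibration with a 3-point moving average and the
#' post-drug phase with an 8-point moving average, normalizes the whole trace
#' to the last smoothed pre-drug point, and reads out the plateau as the
#' maximum smoothed post-drug value that appears stable over time (its
#' following `stability_points` smoothed values deviate by less than
#' `stability_tol`). The specific signal is the plateau minus the supplied
#' control value. Normalization makes the result invariant to overall scaling
#' of the raw luminescence.
#'
#' @param time Time points (s), strictly increasing.
#' @param lum Luminescence counts.
#' @param drug_index Index of the last pre-drug point.
#' @param control_value Control plateau to subtract (default 0).
#' @param pre_window,post_window Moving-average widths (defaults 3 and 8).
#' @param stability_tol Relative deviation tolerated after the plateau
#'   candidate (default 0.05).
#' @param stability_points Number of following points examined (default 3).
#' @return List of class `kinetic_result`: `normalized` (full smoothed,
#'   normalized trace), `plateau`, `specific_signal`, `windows`, `flag`.
#' @export
process_kinetic_trace <- function(time, lum, drug_index, control_value = 0,
                                  pre_window = 3L, post_window = 8L,
                                  stability_tol = 0.05,
                                  stability_points = 3L) {
  stopifnot(length(time) == length(lum), all(diff(time) > 0))
  n <- length(lum)
  if (drug_index < 1L || drug_index >= n) stop("drug_index out of range")
  if (n - drug_index < post_window) {
    stop("input error: need >= ", post_window, " points after drug addition")
  }
  sm <- numeric(n)
  sm[1:drug_index] <- .moving_average(lum[1:drug_index], pre_window)
  sm[(drug_index + 1L):n] <- .moving_average(lum[(drug_index + 1L):n], post_window)
  baseline <- sm[drug_index]
  if (baseline == 0) stop("input error: zero pre-drug baseline")
  norm <- sm / baseline
  post <- norm[(drug_index + 1L):n]
  stable <- vapply(seq_along(post), function(i) {
    tail_idx <- i + seq_len(stability_points)
    tail_idx <- tail_idx[tail_idx <= length(post)]
    if (!length(tail_idx)) return(TRUE)
    all(abs(post[tail_idx] - post[i]) < stability_tol * abs(post[i]))
  }, logical(1))
  flag <- NA_character_
  if (any(stable)) {
    plateau <- max(post[stable])
  } else {
    plateau <- max(post)
    flag <- "no_stable_plateau"
  }
  structure(list(normalized = norm, plateau = plateau,
                 specific_signal = plateau - control_value,
                 windows = c(pre = pre_window, post = post_window),
                 drug_index = drug_index, flag = flag),
            class = "kinetic_result")
}

#' Z-score outlier filter for flagged biological replicates
#'
#' Only replicates flagged beforehand (e.g. for poorly matched cell density or
#' expression) are eligible for removal; a flagged value is omitted when its
#' absolute Z-score exceeds 3, computed leave-one-out against the remaining
#' replicates. Unflagged values are always retained. Zero variance among the
#' comparators triggers a warning and no removal.
#'
#' @param values Numeric replicate values.
#' @param flags Logical vector: was this replicate flagged as suspect?
#' @param z_cutoff Absolute Z-score threshold (default 3).
#' @return List: `retained` values, `removed` (indices into `values`),
#'   `z` (Z-scores for flagged entries, NA otherwise).
#' @export
zscore_outlier_filter <- function(values, flags, z_cutoff = 3) {
  stopifnot(length(values) == length(flags), is.logical(flags))
  z <- rep(NA_real_, length(values))
  removed <- integer()
  for (i in which(flags)) {
    comp <- values[-i]
    if (length(comp) < 2L) next
    s <- stats::sd(comp)
    if (s == 0) {
      warning("zero variance among comparators; no removal for index ", i)
      next
    }
    z[i] <- (values[i] - mean(comp)) / s
    if (abs(z[i]) > z_cutoff) removed <- c(removed, i)
  }
  retained <- if (length(removed)) values[-removed] else values
  list(retained = retained, removed = removed, z = z)
}
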