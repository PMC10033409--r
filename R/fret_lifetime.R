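#' Construct a TCSPC decay trace
#'
#' @param bin_centers Strictly increasing, uniformly spaced bin centres (ns).
#' @param counts Non-negative integer photon counts per bin.
#' @param irf Optional instrument response counts per bin (same length).
#' @param meta Optional condition label / metadata list.
#' @return An object of class `decay_trace`.
#' @export
decay_trace <- function(bin_centers, counts, irf = NULL, meta = NULL) {
  stopifnot(length(bin_centers) == length(counts), all(counts >= 0))
  d <- diff(bin_centers)
  if (any(d <= 0) || diff(range(d)) > 1e-8 * mean(d)) {
    stop("bin_centers must be strictly increasing and uniform")
  }
  if (!is.null(irf)) stopifnot(length(irf) == length(counts))
  structure(list(bin_centers = bin_centers, counts = counts, irf = irf,
                 meta = meta), class = "decay_trace")
}

#' Read a decay trace from CSV
#'
#' Expects columns `time_ns`, `counts` and optionally `irf_counts`.
#' @param file CSV path.
#' @return A [decay_trace()].
#' @export
read_decay_trace <- function(file) {
  df <- utils::read.csv(file)
  stopifnot(all(c("time_ns", "counts") %in% names(df)))
  decay_trace(df$time_ns, df$counts,
              irf = if ("irf_counts" %in% names(df)) df$irf_counts else NULL)
}

# model curve: sum_i A_i exp(-t / tau_i), optionally convolved with a
# supplied IRF histogram (discrete linear convolution, IRF normalized)
.decay_model <- function(t, A, tau, irf = NULL) {
  m <- rowSums(vapply(seq_along(A), function(i) A[i] * exp(-t / tau[i]),
                      numeric(length(t))))
  if (!is.null(irf)) {
    k <- irf / sum(irf)
    full <- stats::convolve(m, rev(k), type = "open")
    m <- full[seq_along(t)]
  }
  m
}

#' Fit an n-exponential model to a TCSPC decay
#'
#' Fits `Decay(t) = sum_i A_i exp(-t/tau_i)` by Poisson-weighted least squares
#' (weights `1/max(counts, 1)`), with amplitudes and lifetimes constrained
#' positive through a log parameterization. Initial lifetimes are log-spaced
#' over the decay window with equal amplitudes; 5 seeded multi-start restarts
#' perturb the starting point and the best chi-square is kept. Components are
#' reported sorted by descending lifetime with normalized amplitudes.
#'
#' @param trace A [decay_trace()].
#' @param n Number of exponential components (1, 2 or 3).
#' @param use_irf Convolve the model with the trace's IRF, if present.
#' @param n_starts Number of multi-start restarts (default 5).
#' @return Object of class `lifetime_fit`: `components` (data.frame
#'   `amplitude` (normalized), `lifetime_ns`, `A` in count units), `n`,
#'   `n_effective`, `chi2_reduced`, `tau_avg`, `fitted`, `trace`.
#' @export
fit_multiexponential <- function(trace, n = 3L, use_irf = FALSE, n_starts = 5L) {
  stopifnot(inherits(trace, "decay_trace"), n %in% 1:3)
  t <- trace$bin_centers
  y <- trace$counts
  if (sum(y > 0) < 10L * n) {
    stop("fit error: need at least ", 10L * n, " bins with nonzero counts")
  }
  irf <- if (use_irf) trace$irf else NULL
  w <- 1 / pmax(y, 1)
  span <- max(t) - min(t[y > 0])
  tau0 <- exp(seq(log(span / 50), log(span / 2), length.out = n))
  A0 <- rep(max(y) / n, n)

  resid_fn <- function(par) {
    A <- exp(par[seq_len(n)])
    tau <- exp(par[n + seq_len(n)])
    sqrt(w) * (y - .decay_model(t, A, tau, irf))
  }

  best <- NULL
  starts <- withr::with_seed(1734, {
    lapply(seq_len(n_starts), function(s) {
      jit <- if (s == 1L) rep(0, 2 * n) else stats::rnorm(2 * n, 0, 0.4)
      c(log(A0), log(tau0)) + jit
    })
  })
  for (p0 in starts) {
    res <- try(minpack.lm::nls.lm(par = p0, fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("fit error: multi-exponential fit did not converge")

  A <- exp(best$par[seq_len(n)])
  tau <- exp(best$par[n + seq_len(n)])
  ord <- order(-tau)
  A <- A[ord]; tau <- tau[ord]
  alpha <- A / sum(A)

  # effective component count: drop near-zero amplitudes and lifetimes that
  # coincide within 1% relative tolerance
  keep <- alpha > 1e-4
  taus_kept <- tau[keep]
  dup <- length(taus_kept) > 1 &&
    any(abs(diff(taus_kept)) / taus_kept[-length(taus_kept)] < 0.01)
  n_eff <- sum(keep) - if (isTRUE(dup)) 1L else 0L
  if (n_eff < n) {
    warning("degenerate component(s): effective component count is ", n_eff)
  }

  fitted <- .decay_model(t, A, tau, irf)
  dof <- sum(y > 0) - 2L * n
  chi2 <- sum(w * (y - fitted)^2) / max(dof, 1L)
  fit <- structure(list(
    components = data.frame(amplitude = alpha, lifetime_ns = tau, A = A),
    n = as.integer(n), n_effective = as.integer(n_eff),
    chi2_reduced = chi2, fitted = fitted, trace = trace),
    class = "lifetime_fit")
  fit$tau_avg <- amplitude_weighted_lifetime(fit)
  fit
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat("<lifetime_fit>", x$n, "components, tau_avg =",
      signif(x$tau_avg, 4), "ns, reduced chi2 =", signif(x$chi2_reduced, 4), "\n")
  print(x$components[, c("amplitude", "lifetime_ns")])
  invisible(x)
}

#' Amplitude-weighted average lifetime
#'
#' `tau_avg = sum(alpha_i * tau_i) / sum(alpha_i)` over the components of a
#' multi-exponential decay fit.
#'
#' @param fit A `lifetime_fit`, or a numeric vector of amplitudes (then
#'   `lifetimes` must be supplied).
#' @param lifetimes Component lifetimes (ns) when `fit` is an amplitude vector.
#' @return Average lifetime in ns.
#' @export
#' @examples
#' amplitude_weighted_lifetime(c(0.5, 0.3, 0.2), c(3, 1, 0.3))  # 1.86
amplitude_weighted_lifetime <- function(fit, lifetimes = NULL) {
  if (inherits(fit, "lifetime_fit")) {
    a <- fit$components$amplitude
    tau <- fit$components$lifetime_ns
  } else {
    a <- fit; tau <- lifetimes
    stopifnot(length(a) == length(tau))
  }
  if (sum(a) <= 0) stop("undefined: all amplitudes are zero")
  sum(a * tau) / sum(a)
}

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_fret / tau_donor`, where `tau_fret` is the amplitude-weighted
#' average lifetime of the doubly labelled sensor and `tau_donor` that of the
#' donor-only control. Negative efficiencies (no transfer, or noise) are
#' returned as-is with an attribute flag.
#'
#' @param tau_fret,tau_donor Average lifetimes (ns); `tau_donor > 0`.
#' @return Efficiency (dimensionless, < 1), with attribute
#'   `flag = "negative_efficiency"` when below 0.
#' @export
fret_efficiency <- function(tau_fret, tau_donor) {
  if (any(tau_donor <= 0)) stop("input error: tau_donor must be > 0")
  e <- 1 - tau_fret / tau_donor
  if (any(e < 0)) attr(e, "flag") <- "negative_efficiency"
  e
}

#' Förster relation: inter-probe distance to FRET efficiency
#'
#' `E = 1 / (1 + (r / R0)^6)`; strictly decreasing in distance, `E = 0.5` at
#' the Förster radius. Used to connect the three conformational-state probe
#' distances (~37, ~29, ~43 Angström for closed/intermediate/open) to the
#' sensor's low/high/low FRET signature.
#'
#' @param distance Inter-probe distance (Angström), > 0.
#' @param forster_radius Förster radius R0 (Angström), > 0. No default: R0 is
#'   a property of the dye pair and must be supplied.
#' @return Efficiency in (0, 1).
#' @export
distance_to_efficiency <- function(distance, forster_radius) {
  if (any(distance <= 0) || any(forster_radius <= 0)) {
    stop("input error: distance and forster_radius must be > 0")
  }
  1 / (1 + (distance / forster_radius)^6)
}

#' Three-state conformational presets
#'
#' Donor-acceptor probe distances of the three ICL3 conformational states:
#' closed inactive (~37 Angström, low FRET), agonist-stimulated intermediate
#' (~29 Angström, high FRET) and open effector-bound (~43 Angström, low FRET).
#'
#' @param state One of `"closed_inactive"`, `"intermediate"`, `"open_effector"`.
#' @return Probe distance in Angström.
#' @export
three_state_distance <- function(state = c("closed_inactive", "intermediate",
                                           "open_effector")) {
  state <- match.arg(state)
  c(closed_inactive = 37, intermediate = 29, open_effector = 43)[[state]]
}

#' Classify ICL3 conformational states from condition-wise FRET readouts
#'
#' Implements the three-state readout logic: the untreated (buffer) condition
#' defines the closed inactive reference; an agonist condition whose
#' efficiency rises above buffer by more than `delta_cutoff` is called the
#' intermediate (high-FRET) state; an agonist-plus-effector condition whose
#' efficiency falls back to (or below) the buffer level is called the open
#' effector-bound state.
#'
#' @param readouts data.frame with columns `condition` (one of `"buffer"`,
#'   `"agonist"`, `"agonist_plus_effector"`) and `efficiency`.
#' @param delta_cutoff Minimum efficiency change treated as a real transition
#'   (default 0.02, about half the agonist-induced swing of the sensor).
#' @return data.frame: condition, efficiency, call, delta_vs_buffer.
#' @export
classify_conformational_state <- function(readouts, delta_cutoff = 0.02) {
  stopifnot(is.data.frame(readouts),
            all(c("condition", "efficiency") %in% names(readouts)))
  if (!"buffer" %in% readouts$condition) {
    stop("input error: a buffer reference condition is required")
  }
  e_buf <- mean(readouts$efficiency[readouts$condition == "buffer"])
  call_one <- function(cond, e) {
    d <- e - e_buf
    if (cond == "buffer") return("closed_inactive")
    if (cond == "agonist") {
      return(if (d > delta_cutoff) "intermediate" else "closed_inactive")
    }
    if (cond == "agonist_plus_effector") {
      return(if (d <= delta_cutoff) "open_effector" else "intermediate")
    }
    stop("unknown condition: ", cond)
  }
  data.frame(condition = readouts$condition,
             efficiency = readouts$efficiency,
             call = mapply(call_one, readouts$condition, readouts$efficiency,
                           USE.NAMES = FALSE),
             delta_vs_buffer = readouts$efficiency - e_buf,
             stringsAsFactors = FALSE)
}
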