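#' Sin/cos featurization of periodic dihedral angles
#'
#' Each backbone dihedral channel (radians) expands to a `(sin, cos)` pair to
#' remove the -pi/pi periodicity, and columns are mean-centred. Feature
#' columns are ordered `sin(ch1), cos(ch1), sin(ch2), cos(ch2), ...`.
#'
#' @param angles Frames x channels numeric matrix of angles in radians.
#' @return Frames x (2*channels) mean-centred feature matrix.
#' @export
featurize_dihedrals <- function(angles) {
  angles <- as.matrix(angles)
  if (nrow(angles) < 2L) stop("need at least 2 frames")
  if (any(!is.finite(angles))) stop("input error: non-finite angles")
  p <- ncol(angles)
  out <- matrix(0, nrow(angles), 2L * p)
  out[, seq(1L, 2L * p, by = 2L)] <- sin(angles)
  out[, seq(2L, 2L * p, by = 2L)] <- cos(angles)
  colnames(out) <- as.vector(rbind(paste0("sin_", seq_len(p)),
                                   paste0("cos_", seq_len(p))))
  scale(out, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

#' Time-lagged independent component analysis (tICA)
#'
#' Finds the slowest-decorrelating linear combinations of the features by
#' solving the generalized eigenproblem of the symmetrized time-lagged
#' covariance `C(lag)` against the instantaneous covariance `C(0)`
#' (ridge-regularized), via Cholesky whitening. Eigenvalues are the lag
#' autocorrelations of the components, sorted descending.
#'
#' @param features Frames x features matrix (e.g. [featurize_dihedrals()]
#'   output).
#' @param lag Lag in frames (>= 1, < number of frames). With the 2 ns lag used
#'   for dihedral trajectories, `lag = 2 / frame_interval_ns`.
#' @param dim Number of components to project onto (default 2).
#' @param ridge Diagonal regularization added to C(0) (default 1e-6).
#' @return Object of class `tica_projection`: `components` (features x dim
#'   loading matrix), `eigenvalues` (all, descending), `projection`
#'   (frames x dim), `lag`.
#' @export
fit_tica <- function(features, lag, dim = 2L, ridge = 1e-6) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (lag < 1L || lag >= n) stop("input error: need frames > lag >= 1")
  X <- scale(X, center = TRUE, scale = FALSE)
  idx0 <- seq_len(n - lag)
  idx1 <- idx0 + lag
  m <- n - lag
  C0 <- crossprod(X) / (n - 1)
  Ct <- crossprod(X[idx0, , drop = FALSE], X[idx1, , drop = FALSE]) / (m - 1)
  Ct <- (Ct + t(Ct)) / 2
  C0r <- C0 + diag(ridge * mean(diag(C0)) + .Machine$double.eps, ncol(X))
  U <- tryCatch(chol(C0r), error = function(e)
    stop("numerical error: instantaneous covariance not positive definite; ",
         "increase `ridge` or remove redundant features"))
  Uinv <- backsolve(U, diag(ncol(X)))
  M <- t(Uinv) %*% Ct %*% Uinv
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  comps <- Uinv %*% eig$vectors
  dim <- min(dim, ncol(comps))
  structure(list(components = comps[, seq_len(dim), drop = FALSE],
                 eigenvalues = eig$values,
                 projection = X %*% comps[, seq_len(dim), drop = FALSE],
                 lag = as.integer(lag)),
            class = "tica_projection")
}

#' Free-energy surface from the population density of a 2D projection
#'
#' Bins the projected samples on a regular 2D grid and converts counts to
#' free energies via the inverse population density,
#' `F(bin) = -kT * log(count / max_count)`, so the most populated bin sits at
#' exactly 0 and empty bins are masked (`NA`). Free-energy differences are
#' invariant to the total sample count.
#'
#' @param projection Frames x 2 matrix (e.g. `fit_tica(...)$projection`).
#' @param bins Number of bins per axis (default 100).
#' @param kT Thermal energy unit (default 1, i.e. kT units). Use
#'   `kT = 0.616` for kcal/mol at 310 K.
#' @return Object of class `free_energy_surface`: `x_edges`, `y_edges`,
#'   `free_energy` (bins x bins matrix, `NA` where empty), `counts`.
#' @export
free_energy_surface <- function(projection, bins = 100L, kT = 1) {
  P <- as.matrix(projection)
  stopifnot(ncol(P) == 2L)
  if (!nrow(P)) stop("input error: zero samples")
  xr <- range(P[, 1]); yr <- range(P[, 2])
  # widen degenerate ranges so a single point still occupies one bin
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  xe <- seq(xr[1], xr[2], length.out = bins + 1L)
  ye <- seq(yr[1], yr[2], length.out = bins + 1L)
  ix <- pmin(findInterval(P[, 1], xe, all.inside = TRUE), bins)
  iy <- pmin(findInterval(P[, 2], ye, all.inside = TRUE), bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  fe <- matrix(NA_real_, bins, bins)
  occ <- counts > 0L
  fe[occ] <- -kT * log(counts[occ] / max(counts))
  structure(list(x_edges = xe, y_edges = ye, free_energy = fe,
                 counts = counts, kT = kT),
            class = "free_energy_surface")
}

# squared Euclidean distances between rows of X and rows of C
.sqdist <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
}

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- .sqdist(X, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      d2 <- pmax(d2, 0)
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
      d2 <- pmin(d2, .sqdist(X, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

#' Mini-batch k-means clustering of projected snapshots
#'
#' Decomposes the sampled projection space into discrete states with
#' mini-batch k-means (k-means++ seeding; per-centre learning-rate updates
#' `eta = 1/count` over random mini-batches), followed by a full assignment
#' pass. Deterministic for a fixed seed. The default ensemble workflow uses a
#' two-pass decomposition (see [subcluster_states()]): one cluster per
#' free-energy basin, then subclusters within one basin.
#'
#' @param projection Frames x d matrix.
#' @param k Number of clusters (1 <= k <= frames).
#' @param seed Integer RNG seed; required for reproducibility.
#' @param batch_size Mini-batch size (default 1024, capped at n).
#' @param n_iter Number of mini-batch iterations (default 100).
#' @return Object of class `cluster_model`: `centers` (k x d), `labels`
#'   (1-based, length frames), `inertia`, `seed`, `empty` (logical per
#'   centre: received no frames in the final assignment).
#' @export
cluster_states <- function(projection, k, seed, batch_size = 1024L,
                           n_iter = 100L) {
  X <- as.matrix(projection)
  n <- nrow(X)
  if (k < 1L || k > n) stop("input error: need 1 <= k <= frames")
  withr::with_seed(seed, {
    centers <- .kmeanspp_init(X, k)
    counts <- rep(0, k)
    b <- min(batch_size, n)
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, b)
      B <- X[idx, , drop = FALSE]
      lab <- max.col(-.sqdist(B, centers), ties.method = "first")
      for (j in seq_len(b)) {
        c_j <- lab[j]
        counts[c_j] <- counts[c_j] + 1
        eta <- 1 / counts[c_j]
        centers[c_j, ] <- (1 - eta) * centers[c_j, ] + eta * B[j, ]
      }
    }
  })
  labels <- max.col(-.sqdist(X, centers), ties.method = "first")
  inertia <- sum((X - centers[labels, , drop = FALSE])^2)
  empty <- tabulate(labels, nbins = k) == 0L
  if (any(empty)) warning(sum(empty), " empty cluster(s)")
  structure(list(centers = centers, labels = labels, inertia = inertia,
                 seed = seed, k = as.integer(k), empty = empty),
            class = "cluster_model")
}

#' Split one cluster of a fitted model into subclusters
#'
#' Second pass of the basin decomposition: frames of one parent cluster are
#' re-clustered, and the combined labelling is returned (parent labels kept,
#' the split cluster's frames relabelled `k+1 .. k+n_sub-1` beyond the first
#' subcluster). With 4 basin clusters and one basin split in two this yields
#' the 5-state decomposition used for loop-distance statistics.
#'
#' @param model A `cluster_model` from [cluster_states()].
#' @param projection The same projection matrix the model was fit on.
#' @param which_cluster Parent cluster to split (1-based).
#' @param n_sub Number of subclusters (default 2).
#' @param seed Integer RNG seed.
#' @return List: `labels` (combined, 1-based over `k + n_sub - 1` states),
#'   `parent`, `sub_model`.
#' @export
subcluster_states <- function(model, projection, which_cluster, n_sub = 2L,
                              seed) {
  stopifnot(inherits(model, "cluster_model"),
            which_cluster >= 1L, which_cluster <= model$k)
  X <- as.matrix(projection)
  sel <- model$labels == which_cluster
  if (sum(sel) < n_sub) stop("cluster too small to split")
  sub <- cluster_states(X[sel, , drop = FALSE], n_sub, seed)
  labels <- model$labels
  relab <- c(which_cluster, model$k + seq_len(n_sub - 1L))
  labels[sel] <- relab[sub$labels]
  list(labels = labels, parent = which_cluster, sub_model = sub)
}

#' Construct a coordinate frame
#'
#' Minimal per-particle representation of one structural snapshot.
#'
#' @param x,y,z Coordinates in Angström.
#' @param resid Integer residue numbers.
#' @param resname Residue names (one-letter codes for the synthetic frames).
#' @param mass Particle masses (> 0); default unit masses.
#' @return data.frame of class `coordinate_frame`.
#' @export
coordinate_frame <- function(x, y, z, resid, resname = NA_character_,
                             mass = 1) {
  df <- data.frame(x = x, y = y, z = z, resid = as.integer(resid),
                   resname = resname, mass = mass, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  if (any(df$mass <= 0)) stop("masses must be > 0")
  class(df) <- c("coordinate_frame", "data.frame")
  df
}

.com <- function(frame, resids) {
  sel <- frame[frame$resid %in% resids, , drop = FALSE]
  if (!nrow(sel)) stop("selection error: empty residue selection")
  w <- sel$mass / sum(sel$mass)
  c(sum(w * sel$x), sum(w * sel$y), sum(w * sel$z))
}

#' Centre-of-mass distance between two residue selections
#'
#' Euclidean distance between the mass-weighted centroids of two residue
#' selections of one frame, e.g. the whole ICL3 (residues 236-257) against
#' ICL1 (61-66) or ICL2 (136-146).
#'
#' @param frame A [coordinate_frame()].
#' @param selection_a,selection_b Integer vectors of residue numbers.
#' @return Distance in Angström.
#' @export
com_distance <- function(frame, selection_a, selection_b) {
  sqrt(sum((.com(frame, selection_a) - .com(frame, selection_b))^2))
}

#' Parse a slash-delimited loop segment specification
#'
#' A spec like `"241-HVQ/NLS/QVE/QDG/RT-254"` names consecutive two- to
#' three-residue subsegments spanning an anchored residue range; the
#' concatenated subsegment letters must exactly fill the anchor span.
#'
#' @param spec Character scalar specification.
#' @return data.frame of class `segment_spec`: `segment` (letters), `start`,
#'   `end` (residue numbers).
#' @export
#' @examples
#' parse_segment_spec("241-HVQ/NLS/QVE/QDG/RT-254")
parse_segment_spec <- function(spec) {
  m <- regmatches(spec, regexec("^([0-9]+)-([A-Za-z/]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4L) stop("validation error: cannot parse segment spec '", spec, "'")
  a <- as.integer(m[2]); b <- as.integer(m[4])
  parts <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  lens <- nchar(parts)
  if (sum(lens) != b - a + 1L) {
    stop("validation error: subsegment letters (", sum(lens),
         " aa) do not fill the anchor span ", a, "-", b,
         " (", b - a + 1L, " aa)")
  }
  ends <- a - 1L + cumsum(lens)
  starts <- ends - lens + 1L
  structure(data.frame(segment = parts, start = starts, end = ends,
                       stringsAsFactors = FALSE),
            class = c("segment_spec", "data.frame"))
}

#' Per-subsegment centre-of-mass distance profiles across frames
#'
#' For each subsegment of a parsed spec (see [parse_segment_spec()]), computes
#' the centre-of-mass distance to a reference selection in every frame, and
#' summarizes each distribution by its quartiles. When frames carry one-letter
#' residue names, the subsegment letters are validated against them.
#'
#' @param frames List of [coordinate_frame()]s.
#' @param spec A spec string or `segment_spec`.
#' @param reference_selection Integer vector of reference residue numbers
#'   (e.g. `61:66` for an ICL1-like reference).
#' @return List: `distances` (long data.frame: frame, segment, distance) and
#'   `summary` (per-segment q25 / median / q75).
#' @export
segment_distance_profile <- function(frames, spec, reference_selection) {
  if (is.character(spec)) spec <- parse_segment_spec(spec)
  stopifnot(inherits(spec, "segment_spec"), length(frames) >= 1L)
  f1 <- frames[[1]]
  if (!all(is.na(f1$resname))) {
    for (i in seq_len(nrow(spec))) {
      resids <- spec$start[i]:spec$end[i]
      letters_frame <- f1$resname[match(resids, f1$resid)]
      want <- strsplit(spec$segment[i], "")[[1]]
      if (anyNA(letters_frame) || !all(letters_frame == want)) {
        stop("validation error: residues ", spec$start[i], "-", spec$end[i],
             " do not match subsegment '", spec$segment[i], "'")
      }
    }
  }
  rows <- do.call(rbind, lapply(seq_along(frames), function(fi) {
    data.frame(frame = fi, segment = spec$segment,
               distance = vapply(seq_len(nrow(spec)), function(i)
                 com_distance(frames[[fi]], spec$start[i]:spec$end[i],
                              reference_selection), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(rows, rows$segment), function(d) {
    q <- stats::quantile(d$distance, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(segment = d$segment[1], q25 = q[1], median = q[2], q75 = q[3])
  }))
  summ <- summ[match(spec$segment, summ$segment), ]
  rownames(summ) <- NULL
  list(distances = rows, summary = summ)
}
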