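test_that("dihedral featurization removes periodicity and centres columns", {
  a <- matrix(c(-179, 10, 181, 10) * pi / 180, 2, 2, byrow = TRUE)
  f <- featurize_dihedrals(a)
  expect_equal(f[1, ], f[2, ], tolerance = 1e-12)  # -179 deg == 181 deg

  set.seed(4)
  x <- matrix(runif(4000, -pi, pi), 1000, 4)
  f <- featurize_dihedrals(x)
  expect_equal(dim(f), c(1000L, 8L))
  expect_true(all(abs(colMeans(f)) < 1e-12))

  const <- cbind(x[, 1], rep(0.5, 1000))
  fc <- featurize_dihedrals(const)
  expect_equal(stats::sd(fc[, 3]), 0)
  expect_equal(stats::sd(fc[, 4]), 0)

  expect_error(featurize_dihedrals(matrix(c(1, NA), 2, 1)), "non-finite")
  expect_error(featurize_dihedrals(matrix(1, 1, 2)), "at least 2 frames")
})

test_that("tICA recovers the planted slow mode of a 2-state Markov chain", {
  # white noise: no slow process, all eigenvalues near 0
  set.seed(10)
  w <- matrix(rnorm(1e4 * 5), ncol = 5)
  tw <- fit_tica(w, lag = 3)
  expect_lt(max(abs(tw$eigenvalues)), 0.1)

  # planted chain: leading eigenvalue matches (1 - p12 - p21)^lag
  lag <- 5L
  traj <- gen_metastable_trajectory(k_states = 2,
                                    stay_probabilities = c(0.99, 0.98),
                                    frames = 10000, with_frames = FALSE,
                                    seed = 5)
  X <- featurize_dihedrals(traj$angles)
  tic <- fit_tica(X, lag = lag)
  analytic <- (1 - 0.01 - 0.02)^lag
  expect_equal(tic$eigenvalues[1], analytic, tolerance = 0.05 / analytic)
  expect_true(all(diff(tic$eigenvalues) <= 1e-10))
  expect_lt(max(abs(tic$eigenvalues)), 1 + 1e-6)

  # the first tIC separates the states with > 95% accuracy
  km <- stats::kmeans(tic$projection[, 1], centers = 2, nstart = 5)
  acc <- max(mean(km$cluster == traj$labels),
             mean(3L - km$cluster == traj$labels))
  expect_gt(acc, 0.95)

  # duplicated feature columns: regularized solution projects identically
  Xd <- cbind(X, X)
  ticd <- fit_tica(Xd, lag = lag, ridge = 1e-8)
  r <- abs(stats::cor(tic$projection[, 1], ticd$projection[, 1]))
  expect_gt(r, 0.999)

  # affine rescaling of individual columns leaves the projection invariant
  # (up to sign) at full rank
  Xs <- sweep(X, 2, seq(0.5, 4, length.out = ncol(X)), `*`)
  tics <- fit_tica(Xs, lag = lag, ridge = 0)
  tic0 <- fit_tica(X, lag = lag, ridge = 0)
  expect_gt(abs(stats::cor(tic0$projection[, 1], tics$projection[, 1])), 0.9999)

  expect_error(fit_tica(X[1:4, ], lag = 10), "input error")
})

test_that("free-energy surfaces follow the inverse population density", {
  # all samples in one bin: single occupied bin at F = 0
  one <- matrix(0.5, 50, 2)
  fes1 <- free_energy_surface(one, bins = 10)
  occ <- which(!is.na(fes1$free_energy))
  expect_equal(length(occ), 1L)
  expect_equal(fes1$free_energy[occ], 0)

  # two-Gaussian mixture 0.7/0.3, well separated: basin dF = -ln(0.3/0.7)
  set.seed(12)
  n <- 1e5
  comp <- rbinom(n, 1, 0.3)
  pts <- cbind(rnorm(n, ifelse(comp == 1, 8, 0), 0.5),
               rnorm(n, 0, 0.5))
  fes <- free_energy_surface(pts, bins = 100)
  mid <- mean(range(fes$x_edges))
  xc <- (head(fes$x_edges, -1) + tail(fes$x_edges, -1)) / 2
  f_low <- min(fes$free_energy[xc < mid, ], na.rm = TRUE)
  f_high <- min(fes$free_energy[xc >= mid, ], na.rm = TRUE)
  expect_equal(f_high - f_low, -log(0.3 / 0.7), tolerance = 0.1 / 0.847)
  # occupied minimum is exactly 0
  expect_equal(min(fes$free_energy, na.rm = TRUE), 0)

  # duplicating every sample leaves the surface unchanged (count-scale
  # invariance)
  fes2 <- free_energy_surface(rbind(pts, pts, pts), bins = 100)
  expect_equal(fes2$free_energy, fes$free_energy, tolerance = 1e-12)

  # kT scales free energies linearly
  fes_kt <- free_energy_surface(pts, bins = 100, kT = 0.616)
  expect_equal(fes_kt$free_energy, 0.616 * fes$free_energy, tolerance = 1e-12)

  expect_error(free_energy_surface(matrix(numeric(0), 0, 2)), "input error")
})

test_that("mini-batch k-means is deterministic and finds planted blobs", {
  set.seed(20)
  X <- matrix(rnorm(400), 200, 2)
  m1 <- cluster_states(X, k = 1, seed = 7)
  expect_equal(as.numeric(m1$centers), colMeans(X), tolerance = 1e-6)

  truth <- rep(1:2, each = 300)
  blobs <- rbind(matrix(rnorm(600, 0, 0.3), 300, 2),
                 matrix(rnorm(600, 6, 0.3), 300, 2))
  m2 <- cluster_states(blobs, k = 2, seed = 11)
  acc <- max(mean(m2$labels == truth), mean(3L - m2$labels == truth))
  expect_gte(acc, 0.99)
  # independent cross-check against stats::kmeans centres
  km <- stats::kmeans(blobs, 2, nstart = 10)
  d <- icl3kit:::.sqdist(m2$centers, km$centers)
  expect_lt(min(d[1, 1] + d[2, 2], d[1, 2] + d[2, 1]), 0.1)

  # determinism contract
  m2b <- cluster_states(blobs, k = 2, seed = 11)
  expect_identical(m2$labels, m2b$labels)
  expect_identical(m2$centers, m2b$centers)

  expect_error(cluster_states(X, k = 500, seed = 1), "input error")

  # two-pass workflow: 4 basin clusters then one basin split in two -> 5 states
  m4 <- cluster_states(blobs, k = 4, seed = 3)
  sub <- subcluster_states(m4, blobs, which_cluster = 1, n_sub = 2, seed = 4)
  expect_equal(sort(unique(sub$labels)), 1:5)
  expect_equal(sub$labels[m4$labels != 1], m4$labels[m4$labels != 1])
})

test_that("centre-of-mass distances are exact and rigid-motion invariant", {
  fr <- coordinate_frame(x = c(0, 5), y = c(0, 0), z = c(0, 0),
                         resid = c(1, 2))
  expect_equal(com_distance(fr, 1, 2), 5)
  expect_equal(com_distance(fr, 2, 1), 5)  # symmetry

  # 4-particle toy with masses (12, 1, 12, 1): hand-computed centroids
  fr4 <- coordinate_frame(x = c(0, 1, 10, 11), y = 0, z = 0,
                          resid = c(1, 1, 2, 2), mass = c(12, 1, 12, 1))
  com_a <- (12 * 0 + 1 * 1) / 13
  com_b <- (12 * 10 + 1 * 11) / 13
  expect_equal(com_distance(fr4, 1, 2), com_b - com_a, tolerance = 1e-12)

  # rigid translation + rotation invariance
  set.seed(30)
  th <- runif(1, 0, 2 * pi); ax <- c(0, 0, 1)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(fr4[, c("x", "y", "z")]) %*% R + 7
  fr4r <- coordinate_frame(xyz[, 1], xyz[, 2], xyz[, 3], fr4$resid,
                           mass = fr4$mass)
  expect_equal(com_distance(fr4r, 1, 2), com_distance(fr4, 1, 2),
               tolerance = 1e-12)
  expect_error(com_distance(fr4, 1, 99), "selection error")
})

test_that("segment specs parse and distance profiles recover planted geometry", {
  spec <- parse_segment_spec("241-HVQ/NLS/QVE/QDG/RT-254")
  expect_equal(nrow(spec), 5L)
  expect_equal(spec$segment, c("HVQ", "NLS", "QVE", "QDG", "RT"))
  expect_equal(spec$start, c(241L, 244L, 247L, 250L, 253L))
  expect_equal(spec$end, c(243L, 246L, 249L, 252L, 254L))
  expect_equal(sum(nchar(spec$segment)), 254 - 241 + 1)
  expect_error(parse_segment_spec("241-HVQ/NLS-254"), "validation error")
  expect_error(parse_segment_spec("garbage"), "validation error")

  # single-subsegment spec: profile equals the plain com_distance series
  frames <- gen_coordinate_frames(20, icl3_distance = 15, seed = 2)
  prof1 <- segment_distance_profile(frames, "250-QDG-252", 61:66)
  direct <- vapply(frames, com_distance, numeric(1),
                   selection_a = 250:252, selection_b = 61:66)
  expect_equal(prof1$distances$distance, direct, tolerance = 1e-12)

  # planted QDG at 8 A and HVQ at 20 A: recovered medians keep the ordering
  fr <- gen_coordinate_frames(50, icl3_distance = 15,
                              segment_distances = c(QDG = 8, HVQ = 20),
                              seed = 6)
  prof <- segment_distance_profile(fr, "241-HVQ/NLS/QVE/QDG/RT-254", 61:66)
  med <- with(prof$summary, setNames(median, segment))
  expect_lt(med[["QDG"]], med[["HVQ"]])
  expect_equal(med[["QDG"]], 8, tolerance = 1e-9)   # planting is exact
  expect_equal(med[["HVQ"]], 20, tolerance = 1e-9)
  expect_true(all(prof$summary$q25 <= prof$summary$median))

  # residue-name validation catches a mismatched spec
  expect_error(segment_distance_profile(fr, "241-HVA/NLS/QVE/QDG/RT-254", 61:66),
               "validation error")
})

test_that("the full ensemble pipeline recovers planted metastable states", {
  traj <- gen_metastable_trajectory(k_states = 3,
                                    stay_probabilities = c(0.98, 0.97, 0.98),
                                    frames = 6000, with_frames = FALSE,
                                    seed = 21)
  X <- featurize_dihedrals(traj$angles)
  tic <- fit_tica(X, lag = 5)
  cm <- cluster_states(tic$projection, k = 3, seed = 9)
  # best accuracy over all label permutations >= 90%
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  acc <- max(vapply(perms, function(p) mean(p[cm$labels] == traj$labels),
                    numeric(1)))
  expect_gte(acc, 0.90)
})
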