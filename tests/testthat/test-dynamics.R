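make_base_traj <- function(n_res = 30, n_frames = 20, jitter = 0.3, seed = 6) {
  spec <- synthetic_spec(n_domains = 3, residues_per_domain = n_res / 3,
                         n_frames = n_frames, hinge_amplitude = 10,
                         jitter_sigma = jitter, seed = seed)
  make_hinge_trajectory(spec)
}

test_that("superposition removes random rigid transforms", {
  traj <- make_base_traj()
  n <- nrow(traj$topology)
  frames <- lapply(seq_len(n_frames(traj)), function(t) {
    X <- matrix(traj$coords[1, , ], n, 3) # every frame a moved copy of frame 1
    random_rigid_transform(X, seed = 100 + t)
  })
  moved <- traj_from_frames(frames, resid = traj$topology$resid)
  fitted <- superpose_trajectory(moved, reference = 1)
  r <- rmsd_series(fitted, reference = 1)
  expect_lt(max(r$whole), 1e-6)
})

test_that("fitting on the fixed base leaves a displaced domain visible", {
  # domain a displaced by 5 A, base unchanged: after fitting on the base the
  # base RMSD vanishes while the whole-protein RMSD does not
  spec <- synthetic_spec(n_domains = 4, residues_per_domain = 10, n_frames = 1,
                         jitter_sigma = 0, seed = 12)
  base <- make_hinge_trajectory(spec)$coords[1, , ]
  displaced <- base
  displaced[1:10, 1] <- displaced[1:10, 1] + 5
  moved <- random_rigid_transform(displaced, seed = 3)
  traj <- traj_from_frames(list(base, moved))
  part <- synthetic_partition(spec)
  bbp <- domain_residues(part, c("b", "bp"))
  fitted <- superpose_trajectory(traj, reference = 1, fit_residues = bbp)
  r <- rmsd_series(fitted, reference = 1,
                   selections = list(whole = NULL, base = bbp))
  expect_lt(r$base[2], 1e-6)
  expect_gt(r$whole[2], 1)
  expect_error(superpose_trajectory(traj, fit_residues = 1:2), "at least 3")
})

test_that("RMSD matches hand-computed values and the direct oracle", {
  X <- matrix(rnorm(300), 100, 3)
  Y <- X
  Y[7, ] <- Y[7, ] + c(2, 0, 0) # 1 of 100 atoms displaced by 2 A
  traj <- traj_from_frames(list(X, Y))
  r <- rmsd_series(traj, reference = 1)
  expect_equal(r$whole[1], 0)
  expect_equal(r$whole[2], 0.2)
  set.seed(5)
  Z <- X + matrix(rnorm(300, sd = 0.5), 100, 3)
  traj2 <- traj_from_frames(list(X, Z))
  r2 <- rmsd_series(traj2, reference = 1)
  expect_equal(r2$whole[2], sqrt(mean(rowSums((Z - X)^2))), tolerance = 1e-12)
})

test_that("RMSD after least-squares fitting never exceeds RMSD before", {
  traj <- make_base_traj(n_frames = 15, jitter = 0.5, seed = 30)
  before <- rmsd_series(traj, reference = 1)$whole
  after <- rmsd_series(superpose_trajectory(traj, reference = 1),
                       reference = 1)$whole
  expect_true(all(after <= before + 1e-9))
})

test_that("cross-correlation has unit diagonal and exact anti-correlation", {
  set.seed(11)
  n_frames <- 50
  disp <- rnorm(n_frames)
  frames <- lapply(seq_len(n_frames), function(t) {
    rbind(c(disp[t], 0, 0), c(-disp[t], 10, 0), c(disp[t] * 2, 0, 10))
  })
  traj <- traj_from_frames(frames)
  C <- cross_correlation_matrix(traj)
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
  expect_equal(C[1, 2], -1)
  expect_equal(C[1, 3], 1)
  expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
  expect_equal(C, t(C))
})

test_that("independent jitter decorrelates and matches bio3d's DCCM", {
  spec <- synthetic_spec(n_domains = 2, residues_per_domain = 8,
                         n_frames = 10000, hinge_amplitude = 0,
                         jitter_sigma = 0.5, seed = 44)
  traj <- make_hinge_trajectory(spec)
  C <- cross_correlation_matrix(traj)
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 0.05)
  # cross-check the implementation against bio3d's dccm on a small case
  small <- make_base_traj(n_frames = 40, jitter = 0.4, seed = 13)
  Cs <- cross_correlation_matrix(small)
  xyz <- mdrin:::.flatten_xyz(ca_coords(small))
  Cb <- bio3d::dccm(xyz)
  expect_equal(unclass(Cs), unclass(Cb), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("zero-variance atoms are flagged undefined in the DCCM", {
  frames <- lapply(1:20, function(t) rbind(c(rnorm(1), 0, 0), c(5, 5, 5)))
  traj <- traj_from_frames(frames)
  C <- cross_correlation_matrix(traj)
  expect_true(all(is.na(C[2, ])))
  expect_equal(C[1, 1], 1)
})

test_that("PCA satisfies its spectral invariants", {
  traj <- make_base_traj(n_frames = 60, jitter = 0.4, seed = 17)
  m <- pca_modes(traj)
  expect_true(all(diff(m$values) <= 1e-9))
  expect_true(all(m$values >= -1e-12))
  # orthonormality
  G <- crossprod(m$vectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # eigenvalue sum equals total coordinate variance
  X <- mdrin:::.flatten_xyz(ca_coords(traj))
  total_var <- sum(scale(X, scale = FALSE)^2) / (nrow(X) - 1)
  expect_equal(sum(m$values), total_var, tolerance = 1e-6)
  # projections: zero mean, diagonal covariance equal to eigenvalues
  expect_lt(max(abs(colMeans(m$projections))), 1e-8)
  pcov <- crossprod(m$projections) / (nrow(X) - 1)
  expect_equal(diag(pcov), m$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(pcov - diag(m$values))), 1e-6)
})

test_that("a motionless trajectory has all-zero eigenvalues", {
  X <- matrix(rnorm(60), 20, 3)
  traj <- traj_from_frames(list(X, X, X))
  m <- pca_modes(traj)
  expect_true(all(m$values < 1e-20))
  expect_equal(variance_fraction(m), rep(0, length(m$values)))
})

test_that("planted hinge mode is recovered by PC1", {
  spec <- synthetic_spec(n_domains = 4, residues_per_domain = 25,
                         n_frames = 500, hinge_amplitude = 20,
                         jitter_sigma = 0.05, seed = 23)
  traj <- make_hinge_trajectory(spec)
  part <- synthetic_partition(spec)
  aligned <- superpose_trajectory(
    traj, fit_residues = domain_residues(part, c("b", "bp")))
  m <- pca_modes(aligned)
  expect_gte(variance_fraction(m)[1], 0.95)
  expect_gte(abs(sum(m$vectors[, 1] * hinge_mode_vector(spec))), 0.99)
})

test_that("eigenvector overlap is the identity for a model with itself", {
  m <- pca_modes(make_base_traj(n_frames = 30, seed = 19))
  ov <- eigenvector_overlap(m, m, k = 4)
  expect_equal(ov, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  # swapped components give a permutation matrix
  m2 <- m
  m2$vectors[, c(1, 2)] <- m2$vectors[, c(2, 1)]
  ov2 <- eigenvector_overlap(m, m2, k = 2)
  expect_equal(ov2, rbind(c(0, 1), c(1, 0)), tolerance = 1e-8,
               ignore_attr = TRUE)
  m3 <- pca_modes(make_base_traj(n_res = 15, n_frames = 30, seed = 19))
  expect_error(eigenvector_overlap(m, m3), "dimensions differ")
})

test_that("FEL: Gaussian cloud has its minimum at the mean, flat disc stays flat", {
  set.seed(31)
  m <- list(projections = cbind(rnorm(20000, 3, 1), rnorm(20000, -2, 1)))
  class(m) <- "PcaModel"
  fel <- fel_projection(m, c(1, 2), grid_size = 80)
  idx <- which(fel$F == min(fel$F), arr.ind = TRUE)
  expect_equal(min(fel$F), 0)
  expect_lt(abs(fel$x[idx[1]] - 3), max(fel$bandwidth))
  expect_lt(abs(fel$y[idx[2]] + 2), max(fel$bandwidth))
  # uniform disc: interior free-energy range below 0.5 kT
  set.seed(32)
  r <- sqrt(runif(50000)) * 5
  th <- runif(50000, 0, 2 * pi)
  md <- list(projections = cbind(r * cos(th), r * sin(th)))
  class(md) <- "PcaModel"
  feld <- fel_projection(md, c(1, 2), grid_size = 60, bandwidth = 1.2)
  gx <- outer(feld$x, rep(1, 60))
  gy <- outer(rep(1, 60), feld$y)
  interior <- sqrt(gx^2 + gy^2) < 3
  expect_lt(diff(range(feld$F[interior])), 0.5)
})

test_that("FEL: two planted clusters give exactly two minima at the centers", {
  set.seed(33)
  a <- cbind(rnorm(5000, -5, 0.8), rnorm(5000, 0, 0.8))
  b <- cbind(rnorm(5000, 5, 0.8), rnorm(5000, 0, 0.8))
  m <- list(projections = rbind(a, b))
  class(m) <- "PcaModel"
  fel <- fel_projection(m, c(1, 2), grid_size = 80, bandwidth = 1)
  mins <- fel_local_minima(fel, f_max = 3)
  expect_equal(nrow(mins), 2)
  expect_lt(abs(abs(mins$x[1]) - 5), 1)
  expect_lt(abs(abs(mins$x[2]) - 5), 1)
  expect_lt(abs(mins$y[1]), 1)
  expect_equal(min(fel$F), 0)
  # order-free: shuffling frames leaves the surface unchanged
  set.seed(34)
  m2 <- list(projections = m$projections[sample(10000), ])
  class(m2) <- "PcaModel"
  fel2 <- fel_projection(m2, c(1, 2), grid_size = 80, bandwidth = 1)
  expect_equal(fel2$F, fel$F)
  expect_error(fel_projection(m, c(1, 2), bandwidth = 0), "bandwidth")
})
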