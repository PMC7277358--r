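test_that("covariance matrix matches hand computations", {
  st <- static_trajectory(4, 5)
  cv <- covariance_matrix(st, superpose = FALSE)
  expect_equal(max(abs(cv$C)), 0)

  # one atom alternating +/- delta along x: single nonzero entry delta^2
  ref <- make_chain_reference(4, atoms = "calpha")
  delta <- 0.1
  coords <- array(rep(ref$coords, each = 10), dim = c(10, 4, 3))
  coords[, 2, 1] <- ref$coords[2, 1] + delta * rep(c(1, -1), 5)
  traj <- trajectory(coords, topology = ref$topology)
  cv <- covariance_matrix(traj, superpose = FALSE)
  expected <- matrix(0, 12, 12)
  expected[4, 4] <- delta^2  # atom 2, x coordinate
  expect_equal(cv$C, expected, tolerance = 1e-12)

  # trace equals summed per-coordinate positional variance
  st2 <- sample_mode_trajectory(ref, eigenvalues = 0.05, sigma = 0.02,
                                n_frames = 200, seed = 5)
  cv2 <- covariance_matrix(st2$trajectory, superpose = FALSE)
  X <- st2$trajectory$coords
  v <- sum(apply(X, c(2, 3), function(x) mean((x - mean(x))^2)))
  expect_equal(sum(diag(cv2$C)), v, tolerance = 1e-10)
  expect_error(covariance_matrix(trajectory(coords[1, , , drop = FALSE],
                                            topology = ref$topology)),
               "2 frames")
})

test_that("eigendecomposition is sorted, orthonormal and reconstructive", {
  withr::with_seed(17, {
    u <- rnorm(12); u <- u / sqrt(sum(u^2))
    lam <- 0.3
    C1 <- lam * tcrossprod(u)
    ms <- eigendecompose(C1, mean_structure = matrix(0, 4, 3))
    expect_equal(ms$eigenvalues[1], lam)
    expect_true(all(abs(ms$eigenvalues[-1]) < 1e-12))
    # sign convention: largest-magnitude component positive
    su <- if (u[which.max(abs(u))] < 0) -u else u
    expect_equal(ms$vectors[, 1], su, tolerance = 1e-10)

    ident <- eigendecompose(diag(12), mean_structure = matrix(0, 4, 3))
    expect_equal(ident$eigenvalues, rep(1, 12))

    A <- matrix(rnorm(144), 12, 12)
    C2 <- crossprod(A) / 12
    ms2 <- eigendecompose(C2, mean_structure = matrix(0, 4, 3))
    expect_true(all(diff(ms2$eigenvalues) <= 0))
    expect_true(all(ms2$eigenvalues >= 0))
    expect_equal(crossprod(ms2$vectors), diag(12), tolerance = 1e-8)
    recon <- ms2$vectors %*% diag(ms2$eigenvalues) %*% t(ms2$vectors)
    expect_equal(recon, C2, tolerance = 1e-8)
    expect_error(eigendecompose(A, mean_structure = matrix(0, 4, 3)),
                 "not symmetric")
  })
})

test_that("variance fractions follow the eigenvalue spectrum", {
  # planted spectrum: 37% / 15% split over a 48% tail
  lam <- c(37, 15, rep(48 / 10, 10))
  ms <- structure(list(eigenvalues = lam,
                       vectors = diag(length(lam)),
                       mean = matrix(0, 4, 3),
                       weights = rep(1, 4)),
                  class = "mode_set")
  expect_equal(variance_fraction(ms, 1), 0.37)
  expect_equal(variance_fraction(ms, 2), 0.52)
  expect_equal(variance_fraction(ms, length(lam)), 1.0)
  fr <- vapply(seq_along(lam), variance_fraction, numeric(1), modes = ms)
  expect_true(all(diff(fr) >= 0))
  expect_error(variance_fraction(ms, 0), "k must be")
  zero <- ms; zero$eigenvalues <- rep(0, 12)
  expect_error(variance_fraction(zero, 1), "zero")
})

test_that("projections recover planted mode amplitudes", {
  ref <- make_chain_reference(20, atoms = "calpha", layout = "helix")
  st <- sample_mode_trajectory(ref, eigenvalues = 0.05, sigma = 0,
                               n_frames = 100, seed = 23)
  ms <- essential_dynamics(st$trajectory)
  pr <- project_trajectory(st$trajectory, ms, k = 1)
  # projecting the mean structure gives zero
  mt <- trajectory(array(rep(ms$mean, each = 2), dim = c(2, 20, 3)),
                   topology = ref$topology)
  pm <- project_trajectory(mt, ms, k = 2)
  expect_equal(max(abs(pm$proj)), 0, tolerance = 1e-8)
  # noiseless single-mode amplitudes recovered up to the mode sign
  a <- st$amplitudes[, 1]
  flip <- sign(sum(pr$proj[, 1] * a))
  expect_equal(flip * pr$proj[, 1], a - mean(a), tolerance = 1e-6)
})

test_that("self-projection variance equals the eigenvalue", {
  ref <- make_chain_reference(15, atoms = "calpha", layout = "helix")
  st <- sample_mode_trajectory(ref, eigenvalues = c(0.04, 0.01),
                               sigma = 0.005, n_frames = 2000, seed = 29)
  ms <- essential_dynamics(st$trajectory)
  pr <- project_trajectory(st$trajectory, ms, k = 2)
  v <- apply(pr$proj, 2, function(x) mean((x - mean(x))^2))
  expect_equal(v, ms$eigenvalues[1:2], tolerance = 0.02)
  # columns of a self-projection are uncorrelated
  expect_lt(abs(cor(pr$proj[, 1], pr$proj[, 2])), 0.05)
  # atom-count mismatch is an error, not silent mapping
  other <- make_chain_reference(9, atoms = "calpha")
  ot <- sample_mode_trajectory(other, eigenvalues = 0.01, n_frames = 5,
                               seed = 1)
  expect_error(project_trajectory(ot$trajectory, ms), "atom counts")
})

test_that("mode RMSF follows its closed form and the Parseval identity", {
  n <- 6
  vec <- numeric(3 * n); vec[7] <- 1  # all weight on atom 3, x
  ms <- structure(list(eigenvalues = c(0.04, rep(0, 3 * n - 1)),
                       vectors = cbind(vec, diag(3 * n)[, -7]),
                       mean = matrix(0, n, 3),
                       weights = rep(1, n)),
                  class = "mode_set")
  r <- mode_rmsf(ms, 1)
  expect_equal(r[3], 0.2)
  expect_equal(r[-3], rep(0, n - 1))
  # homogeneity: scaling eigenvalues by 4 doubles the RMSF
  ms4 <- ms; ms4$eigenvalues <- 4 * ms$eigenvalues
  expect_equal(mode_rmsf(ms4, 1), 2 * r)
  expect_error(mode_rmsf(ms, 99), "within")

  # sum over all modes equals the trajectory RMSF about the time mean
  ref <- make_chain_reference(8, atoms = "calpha", layout = "helix")
  st <- sample_mode_trajectory(ref, eigenvalues = c(0.03, 0.01),
                               sigma = 0.01, n_frames = 400, seed = 37)
  sup <- superpose_trajectory(st$trajectory, reference = "mean")
  msf <- essential_dynamics(st$trajectory)
  total <- mode_rmsf(msf, seq_along(msf$eigenvalues))
  direct <- rmsf(sup$trajectory, reference_mode = "time_average")
  expect_equal(unname(total), unname(direct), tolerance = 1e-6)
})

test_that("planted variance fractions are recovered from simulation", {
  ref <- make_chain_reference(30, atoms = "calpha", layout = "helix")
  plant <- calibrated_mode_plant(0.1, c(0.37, 0.15), 30)
  st <- sample_mode_trajectory(ref, eigenvalues = plant$eigenvalues,
                               sigma = plant$sigma,
                               n_frames = 2000, seed = 41)
  ms <- essential_dynamics(st$trajectory)
  expect_equal(variance_fraction(ms, 1), 0.37, tolerance = 0.1)
  expect_equal(variance_fraction(ms, 2) - variance_fraction(ms, 1), 0.15,
               tolerance = 0.15)
})

test_that("mode sets round-trip through the text serialization", {
  ref <- make_chain_reference(6, atoms = "calpha")
  st <- sample_mode_trajectory(ref, eigenvalues = c(0.02, 0.01),
                               sigma = 0.01, n_frames = 50, seed = 43)
  ms <- essential_dynamics(st$trajectory)
  pre <- withr::local_tempfile()
  write_mode_set(ms, pre)
  back <- read_mode_set(pre)
  expect_equal(back$eigenvalues, ms$eigenvalues, tolerance = 1e-14)
  expect_equal(back$vectors, unname(ms$vectors), tolerance = 1e-14)
  expect_equal(back$mean, unname(ms$mean), tolerance = 1e-14)
})
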