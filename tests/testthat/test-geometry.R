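test_that("Kabsch fit recovers planted rigid transforms", {
  ref <- make_chain_reference(10, atoms = "calpha", layout = "helix")
  P <- ref$coords

  id <- kabsch_fit(P, P)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, rep(0, 3), tolerance = 1e-12)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)

  R90 <- rotation_z(pi / 2)
  moved <- P %*% R90 + matrix(c(1, 2, 3), nrow(P), 3, byrow = TRUE)
  fit <- kabsch_fit(moved, P)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(fit, moved), P, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("post-fit RMSD matches the quaternion lower bound", {
  withr::with_seed(42, {
    for (n in c(4L, 10L, 30L)) {
      P <- matrix(rnorm(3 * n), n, 3)
      Q <- P %*% rotation_z(runif(1, 0, pi)) + rnorm(3) +
        matrix(rnorm(3 * n, sd = 0.05), n, 3)
      expect_equal(kabsch_fit(P, Q)$rmsd, quaternion_min_rmsd(P, Q),
                   tolerance = 1e-9)
    }
  })
})

test_that("fit RMSD is invariant to prior rigid transforms and sees noise", {
  withr::with_seed(7, {
    n <- 400
    P <- matrix(rnorm(3 * n), n, 3)
    sigma <- 0.05
    Q <- P + matrix(rnorm(3 * n, sd = sigma), n, 3)
    r1 <- kabsch_fit(P, Q)$rmsd
    # pre-rotating the mobile set must not change the fitted RMSD
    P2 <- P %*% rotation_z(1.1) + matrix(c(5, -3, 2), n, 3, byrow = TRUE)
    expect_equal(kabsch_fit(P2, Q)$rmsd, r1, tolerance = 1e-9)
    # and the fitted RMSD reflects the planted noise level sqrt(3)*sigma
    expect_equal(r1, sqrt(3) * sigma, tolerance = 0.05)
  })
  expect_error(kabsch_fit(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
               "collinear|degenerate")
})

test_that("pairwise RMSD follows its defining arithmetic", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(rmsd(a, a), 0)
  b <- rbind(c(0, 0, 0), c(2, 0, 0))  # displacements 0 and 1 nm
  expect_equal(rmsd(a, b), sqrt(0.5))
  expect_equal(rmsd(a, b), rmsd(b, a))
  shift <- a + matrix(c(0.3, 0.4, 0), 2, 3, byrow = TRUE)  # |t| = 0.5
  expect_equal(rmsd(a, shift), 0.5)
  expect_error(rmsd(a[0, ], b[0, ]), "zero atoms")
})

test_that("RMSD series is zero at its reference and after rigid motion", {
  ref <- make_chain_reference(8, atoms = "calpha", layout = "helix")
  tt <- 6
  coords <- array(0, dim = c(tt, 8, 3))
  withr::with_seed(3, {
    for (t in seq_len(tt)) {
      coords[t, , ] <- ref$coords %*% rotation_z(runif(1, 0, 2 * pi)) +
        matrix(runif(3, -2, 2), 8, 3, byrow = TRUE)
    }
  })
  traj <- trajectory(coords, topology = ref$topology)
  ser <- rmsd_series(traj, fit_sel = atom_selection(class = "calpha"))
  expect_equal(ser$values[1], 0, tolerance = 1e-10)
  expect_true(all(ser$values <= 1e-10))
  expect_error(rmsd_series(traj, reference = 99), "out of range")
})

test_that("unfitted RMSD under isotropic noise obeys the chi-square law", {
  ref <- make_chain_reference(10, atoms = "calpha")
  sigma <- 0.05
  tt <- 3000
  n <- 10
  withr::with_seed(21, {
    coords <- array(rep(ref$coords, each = tt) +
                      rnorm(tt * n * 3, sd = sigma),
                    dim = c(tt, n, 3))
  })
  coords[1, , ] <- ref$coords  # frame 1 is the exact reference
  traj <- trajectory(coords, topology = ref$topology)
  ser <- rmsd_series(traj, fit_sel = atom_selection(class = "calpha"),
                     fit = FALSE)
  # E[RMSD^2] = 3 sigma^2; n*RMSD^2/sigma^2 ~ chi-square(3n)
  expect_equal(mean(ser$values[-1]^2), 3 * sigma^2, tolerance = 0.05)
  z <- n * ser$values[-1]^2 / sigma^2
  expect_equal(var(z), 6 * n, tolerance = 0.15)
})

test_that("minimum distance matches a brute-force pair scan", {
  iface <- synthetic_k700_interface()
  top <- iface$topology
  a1 <- rbind(c(0, 0, 0), c(5, 5, 5))
  t2 <- topology(serial = 1:2, name = c("NZ", "P"), resname = c("LYS", "U"),
                 resid = c(700L, 1L), chain = c("A", "R"))
  expect_equal(min_distance(rbind(c(0, 0, 0), c(0.25, 0, 0)), t2, 1, 2),
               0.25)
  # invariance under a joint rigid transform
  sa <- select_atoms(top, "chain A and resid 700 and sidechain")
  sb <- select_atoms(top, "chain R")
  d0 <- min_distance(iface$coords, top, sa, sb)
  moved <- iface$coords %*% rotation_z(0.8) +
    matrix(c(1, -2, 0.5), nrow(iface$coords), 3, byrow = TRUE)
  expect_equal(min_distance(moved, top, sa, sb), d0, tolerance = 1e-12)
  expect_error(min_distance(iface$coords, top, sa, sa), "overlap")

  withr::with_seed(5, {
    for (rep in 1:3) {
      fr <- matrix(runif(600, 0, 3), 200, 3)
      topr <- topology(serial = 1:200, name = "CA", resname = "ALA",
                       resid = 1:200, chain = rep(c("A", "B"), each = 100))
      ia <- 1:100; ib <- 101:200
      expect_equal(min_distance(fr, topr, ia, ib),
                   brute_min_distance(fr, ia, ib), tolerance = 1e-12)
      cut <- runif(1, 0.2, 1)
      expect_identical(contact_count(fr, topr, ia, ib, cut),
                       brute_contact_count(fr, ia, ib, cut))
    }
  })
})

test_that("contact counting is boundary-inclusive and monotone in cutoff", {
  t2 <- topology(serial = 1:2, name = c("NZ", "P"), resname = c("LYS", "U"),
                 resid = c(700L, 1L), chain = c("A", "R"))
  near <- rbind(c(0, 0, 0), c(0.25, 0, 0))
  far <- rbind(c(0, 0, 0), c(0.35, 0, 0))
  expect_equal(contact_count(near, t2, 1, 2, 0.3), 1L)
  expect_equal(contact_count(far, t2, 1, 2, 0.3), 0L)
  at <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  expect_equal(contact_count(at, t2, 1, 2, 0.3), 1L)  # <= cutoff counts

  # a1,a2 at 0 and 0.1; b1,b2 at 0.2 and 0.3: all four pairs within 0.3
  t4 <- topology(serial = 1:4, name = c("C1", "C2", "P", "P2"),
                 resname = c("LYS", "LYS", "U", "U"),
                 resid = c(700L, 700L, 1L, 2L),
                 chain = c("A", "A", "R", "R"))
  line <- cbind(c(0, 0.1, 0.2, 0.3), 0, 0)
  expect_equal(contact_count(line, t4, 1:2, 3:4, 0.3), 4L)

  withr::with_seed(9, {
    fr <- matrix(runif(120), 40, 3)
    topr <- topology(serial = 1:40, name = "CA", resname = "ALA",
                     resid = 1:40, chain = rep(c("A", "B"), each = 20))
    cuts <- sort(runif(6, 0.05, 1.5))
    counts <- vapply(cuts, function(cc)
      contact_count(fr, topr, 1:20, 21:40, cc), integer(1))
    expect_true(all(diff(counts) >= 0))
  })
  expect_error(contact_count(line, t4, 1:2, 3:4, -1), "positive")
})

test_that("contact series drops to zero exactly after the planted crossing", {
  cutoff <- 0.3
  # crossing time 4761.9 ps falls strictly between frames
  sc <- sample_contact_trajectory(d0 = 0.2, speed = 2.1e-5, n_frames = 200,
                                  dt = 50, seed = 2)
  ser <- contact_series(sc$trajectory, sc$selA, sc$selB, cutoff)
  tstar <- contact_crossing_time(0.2, 2.1e-5, cutoff)
  expect_true(all(ser$values[ser$times <= tstar] > 0))
  expect_true(all(ser$values[ser$times > tstar] == 0))

  static <- sample_contact_trajectory(d0 = 0.25, speed = 0, n_frames = 50,
                                      seed = 2)
  sser <- contact_series(static$trajectory, static$selA, static$selB, cutoff)
  expect_true(all(sser$values == sser$values[1]))
})

test_that("p14-style sidechain contact call equals the brute-force scan", {
  prot <- make_chain_reference(81, chain = "B", resid_start = 20,
                               atoms = "full", hydrogens = TRUE)
  iface <- synthetic_k700_interface()
  # combine the p14-like chain with the RNA chain of the interface model
  rna_idx <- which(iface$topology$chain == "R")
  top <- topology(
    serial = seq_len(n_atoms(prot$topology) + length(rna_idx)),
    name = c(prot$topology$name, iface$topology$name[rna_idx]),
    element = c(prot$topology$element, iface$topology$element[rna_idx]),
    resname = c(prot$topology$resname, iface$topology$resname[rna_idx]),
    resid = c(prot$topology$resid, iface$topology$resid[rna_idx]),
    chain = c(prot$topology$chain, iface$topology$chain[rna_idx])
  )
  fr <- rbind(prot$coords, iface$coords[rna_idx, ] + 1.5)
  sc <- select_atoms(top, "chain B and resid 20-100 and sidechain")
  rn <- select_atoms(top, "chain R")
  expect_identical(contact_count(fr, top, sc, rn, 3),
                   brute_contact_count(fr, sc, rn, 3))
})

test_that("RMSF matches closed forms for planted fluctuations", {
  ref <- make_chain_reference(5, atoms = "calpha")
  st <- static_trajectory(5, 4)
  expect_equal(unname(rmsf(st)), rep(0, 5))

  # one atom oscillating +/- delta along x with equal occupancy
  delta <- 0.2
  coords <- array(rep(ref$coords, each = 10), dim = c(10, 5, 3))
  coords[, 3, 1] <- ref$coords[3, 1] + delta * rep(c(1, -1), 5)
  traj <- trajectory(coords, topology = ref$topology)
  r <- rmsf(traj, reference_mode = "time_average")
  expect_equal(unname(r[3]), delta, tolerance = 1e-12)
  expect_equal(unname(r[-3]), rep(0, 4))
  # against the initial frame the deviations are 0 or 2*delta
  r0 <- rmsf(traj, reference_mode = "initial_frame")
  expect_equal(unname(r0[3]), delta * sqrt(2), tolerance = 1e-12)

  sigma <- 0.04
  withr::with_seed(31, {
    noisy <- array(rep(ref$coords, each = 4000) +
                     rnorm(4000 * 5 * 3, sd = sigma),
                   dim = c(4000, 5, 3))
  })
  rn <- rmsf(trajectory(noisy, topology = ref$topology))
  expect_equal(unname(rn), rep(sigma * sqrt(3), 5), tolerance = 0.05)
  expect_error(rmsf(trajectory(coords[1, , , drop = FALSE],
                               topology = ref$topology)), "2 frames")
})

test_that("distributions are normalized probabilities with recoverable shift", {
  same <- scalar_series(rep(0.42, 100), seq_len(100), "nm")
  d <- distribution(same, bins = 5)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_equal(max(d$prob), 1)

  withr::with_seed(13, {
    a <- scalar_series(rnorm(5000, 0.5, 0.05), seq_len(5000), "nm")
    b <- scalar_series(rnorm(5000, 0.65, 0.05), seq_len(5000), "nm")
  })
  edges <- seq(0, 1.2, by = 0.01)
  da <- distribution(a, edges); db <- distribution(b, edges)
  expect_equal(sum(da$prob), 1, tolerance = 1e-12)
  expect_equal(distribution_mean(db) - distribution_mean(da), 0.15,
               tolerance = 0.02)
  expect_equal(mean_shift(a, b), 0.15, tolerance = 0.01)
  expect_error(distribution(a, c(0, 0, 1)), "increasing")
})
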