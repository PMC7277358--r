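# Synthetic ground-truth generators. Every generator is a pure function
# of its arguments including the seed (base R Mersenne-Twister via
# withr::with_seed); no global RNG state is touched.

#' Idealized chain reference structure
#'
#' Builds a synthetic polymer chain with exactly 0.38 nm between
#' consecutive C-alpha atoms (the canonical C-alpha spacing), either as
#' a planar zig-zag (`extended`) or a helical trace (`helix`). With
#' `atoms = "full"` each residue carries placeholder backbone and
#' side-chain atoms (N, CA, C, O, CB, CG, optionally HB/HG hydrogens)
#' so selections by atom class are meaningful; `atoms = "calpha"` gives
#' a C-alpha-only chain for covariance/correlation work.
#'
#' @param n_res number of residues (>= 2).
#' @param chain chain id.
#' @param resid_start first residue number (author numbering).
#' @param resids explicit residue numbers (overrides `resid_start`).
#' @param atoms `"full"` or `"calpha"`.
#' @param layout `"extended"` or `"helix"`.
#' @param hydrogens include placeholder side-chain hydrogens
#'   (`atoms = "full"` only).
#' @return list: `topology`, `coords` (N_atoms x 3, nm).
#' @export
make_chain_reference <- function(n_res, chain = "A", resid_start = 1L,
                                 resids = NULL,
                                 atoms = c("full", "calpha"),
                                 layout = c("extended", "helix"),
                                 hydrogens = FALSE) {
  if (n_res < 2) stop("a chain needs at least 2 residues")
  atoms <- match.arg(atoms)
  layout <- match.arg(layout)
  if (is.null(resids)) resids <- resid_start + seq_len(n_res) - 1L
  stopifnot(length(resids) == n_res)
  i <- seq_len(n_res) - 1L
  if (layout == "extended") {
    b <- 0.05
    a <- sqrt(0.38^2 - (2 * b)^2)
    ca <- cbind(i * a, b * (-1)^i, 0)
  } else {
    r <- 0.23
    dtheta <- 100 * pi / 180
    rise <- sqrt(0.38^2 - (2 * r * sin(dtheta / 2))^2)
    ca <- cbind(r * cos(i * dtheta), r * sin(i * dtheta), i * rise)
  }
  if (atoms == "calpha") {
    top <- topology(serial = seq_len(n_res), name = "CA", element = "C",
                    resname = "ALA", resid = resids, chain = chain)
    return(list(topology = top, coords = unname(ca)))
  }
  offs <- list(N = c(-0.12, 0.09, 0.02), CA = c(0, 0, 0),
               C = c(0.12, 0.09, -0.02), O = c(0.19, 0.17, -0.02),
               CB = c(0, -0.15, 0.05), CG = c(0.02, -0.28, 0.09))
  if (hydrogens) {
    offs$HB <- c(0.09, -0.17, 0.08)
    offs$HG <- c(0.05, -0.36, 0.14)
  }
  nm <- names(offs)
  coords <- do.call(rbind, lapply(seq_len(n_res), function(k) {
    sweep(do.call(rbind, offs), 2, ca[k, ], `+`)
  }))
  top <- topology(
    serial = seq_len(n_res * length(nm)),
    name = rep(nm, n_res),
    element = infer_element(rep(nm, n_res)),
    resname = "LYS", resid = rep(resids, each = length(nm)),
    chain = chain
  )
  list(topology = top, coords = unname(coords))
}

# Random proper rotation, axis-angle with angle up to max_angle (radians).
random_rotation <- function(max_angle = 0.3) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, max_angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rigid_body_basis <- function(ref_coords) {
  n <- nrow(ref_coords)
  cen <- sweep(ref_coords, 2, colMeans(ref_coords))
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- 1  # translations
  for (a in 1:3) {                                 # infinitesimal rotations
    e <- diag(3)[a, ]
    rot <- t(apply(cen, 1, function(p) c(e[2] * p[3] - e[3] * p[2],
                                         e[3] * p[1] - e[1] * p[3],
                                         e[1] * p[2] - e[2] * p[1])))
    B[, 3 + a] <- as.numeric(t(rot))
  }
  qr.Q(qr(B))
}

#' Random orthonormal mode directions
#'
#' K orthonormal columns over `n3` coordinates (QR of a Gaussian
#' matrix), signs fixed so the largest-magnitude component is positive.
#' When reference coordinates are supplied the modes are additionally
#' made orthogonal to the six rigid-body degrees of freedom
#' (translations and infinitesimal rotations about the reference), so
#' that superposition does not absorb planted internal motion.
#'
#' @param n3 coordinate count (3 x atoms).
#' @param k number of modes.
#' @param seed RNG seed.
#' @param ref_coords optional N x 3 reference used to project out the
#'   rigid-body subspace.
#' @export
random_modes <- function(n3, k, seed = 1L, ref_coords = NULL) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(n3 * k), n3, k)
    if (!is.null(ref_coords)) {
      stopifnot(3 * nrow(ref_coords) == n3)
      B <- rigid_body_basis(ref_coords)
      M <- M - B %*% crossprod(B, M)
    }
    Q <- qr.Q(qr(M))
    for (j in seq_len(k)) {
      if (Q[which.max(abs(Q[, j])), j] < 0) Q[, j] <- -Q[, j]
    }
    Q
  })
}

#' Calibrate mode eigenvalues and noise for target variance fractions
#'
#' Chooses planted eigenvalues and the isotropic noise level so that the
#' leading modes carry exactly the requested fractions of the variance
#' an essential-dynamics analysis can observe. The accounting: each
#' planted mode direction also receives the noise variance `sigma^2`,
#' and rigid-body superposition removes about six degrees of freedom of
#' noise, so for K modes over N atoms the residual fraction spreads
#' over `3N - 6 - K` directions. Used to emulate a system whose first
#' two eigenvectors carry 37% and 15% of the overall motion.
#'
#' @param total_var observable total variance V (nm^2).
#' @param fractions target per-mode variance fractions, summing to < 1.
#' @param n_atoms atom count of the chain.
#' @return list: `eigenvalues` (length K), `sigma` (noise sd, nm).
#' @export
calibrated_mode_plant <- function(total_var, fractions, n_atoms) {
  stopifnot(all(fractions > 0), sum(fractions) < 1)
  k <- length(fractions)
  free <- 3 * n_atoms - 6 - k
  if (free <= 0) stop("too few atoms for this calibration")
  sigma2 <- (1 - sum(fractions)) * total_var / free
  lam <- fractions * total_var - sigma2
  if (any(lam <= 0)) {
    stop("requested fractions too small relative to the noise floor")
  }
  list(eigenvalues = lam, sigma = sqrt(sigma2))
}

#' Sample a trajectory with planted essential modes
#'
#' Frames are `reference + sum_k a_kt u_k + noise`, with mode amplitudes
#' `a_kt ~ Normal(0, lambda_k)` and isotropic Gaussian noise of standard
#' deviation `sigma` per coordinate. This is the low-rank-plus-noise
#' emulation of a production MD run: the planted eigenvalues are the
#' ground truth that essential-dynamics analysis must recover. With
#' `rigid_body_drift` every frame additionally receives a random rigid
#' rotation/translation, which superposition must remove.
#'
#' @param reference list(`topology`, `coords`) as from
#'   [make_chain_reference()].
#' @param eigenvalues planted mode variances lambda_k (nm^2), length K.
#' @param vectors optional 3N x K orthonormal mode matrix; random
#'   orthonormal directions by default. Non-orthonormal input is an
#'   error.
#' @param sigma isotropic noise sd per coordinate (nm).
#' @param n_frames number of frames T.
#' @param dt time step between frames (ps).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @param rigid_body_drift apply a random rigid transform per frame.
#' @return list: `trajectory`, `amplitudes` (T x K), `vectors`,
#'   `eigenvalues`.
#' @export
sample_mode_trajectory <- function(reference, eigenvalues, vectors = NULL,
                                   sigma = 0, n_frames = 1000L, dt = 100,
                                   seed = 1L, rigid_body_drift = FALSE) {
  stopifnot(all(eigenvalues > 0), sigma >= 0, n_frames >= 2)
  nat <- n_atoms(reference$topology)
  n3 <- 3L * nat
  k <- length(eigenvalues)
  if (is.null(vectors)) {
    vectors <- random_modes(n3, k, seed = seed + 7777L,
                            ref_coords = reference$coords)
  }
  vectors <- as.matrix(vectors)
  stopifnot(nrow(vectors) == n3, ncol(vectors) == k)
  gram <- crossprod(vectors)
  if (max(abs(gram - diag(k))) > 1e-8) {
    stop("mode vectors are not orthonormal (max Gram deviation ",
         signif(max(abs(gram - diag(k))), 3), ")")
  }
  ref_flat <- as.numeric(t(reference$coords))  # x1,y1,z1,x2,...
  withr::with_seed(seed, {
    A <- matrix(rnorm(n_frames * k), n_frames, k) %*%
      diag(sqrt(eigenvalues), k)
    coords <- array(0, dim = c(n_frames, nat, 3))
    for (t in seq_len(n_frames)) {
      disp <- as.numeric(vectors %*% A[t, ])
      if (sigma > 0) disp <- disp + rnorm(n3, sd = sigma)
      fr <- matrix(ref_flat + disp, ncol = 3, byrow = TRUE)
      if (rigid_body_drift) {
        R <- random_rotation(0.35)
        fr <- fr %*% R + matrix(runif(3, -0.4, 0.4), nat, 3, byrow = TRUE)
      }
      coords[t, , ] <- fr
    }
    list(trajectory = trajectory(coords, (seq_len(n_frames) - 1) * dt,
                                 reference$topology),
         amplitudes = A, vectors = vectors, eigenvalues = eigenvalues)
  })
}

#' Expected cross-correlation of the block-motion generator
#'
#' For atoms moving as `latent_group x direction + noise`, the
#' population DCC between atoms of groups g and h is
#' `rho_gh * v / (v + 3 sigma^2)` (and that expression with
#' `rho_gg = 1` within a group).
#'
#' @param rho between-group latent correlation.
#' @param latent_var latent variance v (nm^2).
#' @param sigma isotropic noise sd (nm).
#' @export
expected_block_dccm <- function(rho, latent_var, sigma) {
  rho * latent_var / (latent_var + 3 * sigma^2)
}

#' Sample a trajectory with block-correlated residue motions
#'
#' Residue groups share a scalar latent displacement along a common unit
#' direction; latents across groups have covariance `latent_var * rho`.
#' Per-atom isotropic noise decorrelates atoms within and between
#' groups by the closed-form factor of [expected_block_dccm()]. Atoms
#' outside every group move by noise alone. Emulates the coupled-domain
#' block structure a correlation map reveals.
#'
#' @param reference list(`topology`, `coords`); groups are defined on
#'   its residue numbers.
#' @param groups list of inclusive residue-number ranges `c(lo, hi)`.
#' @param rho symmetric between-group correlation matrix (unit
#'   diagonal, positive semi-definite).
#' @param latent_var latent variance v (nm^2).
#' @param direction unit 3-vector of the shared motion.
#' @param sigma noise sd (nm).
#' @param n_frames,dt,seed as in [sample_mode_trajectory()].
#' @return list: `trajectory`, `latents` (T x G), `group_of_atom`.
#' @export
sample_block_trajectory <- function(reference, groups, rho, latent_var = 1,
                                    direction = c(1, 0, 0), sigma = 0.1,
                                    n_frames = 1000L, dt = 100, seed = 1L) {
  G <- length(groups)
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == G, ncol(rho) == G,
            max(abs(rho - t(rho))) < 1e-12, all(abs(diag(rho) - 1) < 1e-12))
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("rho is not positive semi-definite")
  direction <- direction / sqrt(sum(direction^2))
  top <- reference$topology
  nat <- n_atoms(top)
  group_of_atom <- rep(NA_integer_, nat)
  for (g in seq_len(G)) {
    rng <- groups[[g]]
    group_of_atom[top$resid >= rng[1] & top$resid <= rng[2]] <- g
  }
  # PSD square root via eigendecomposition (chol fails on semidefinite rho)
  eg <- eigen(rho * latent_var, symmetric = TRUE)
  rt <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), G) %*% t(eg$vectors)
  withr::with_seed(seed, {
    S <- matrix(rnorm(n_frames * G), n_frames, G) %*% rt
    coords <- array(0, dim = c(n_frames, nat, 3))
    for (t in seq_len(n_frames)) {
      disp <- matrix(0, nat, 3)
      ing <- !is.na(group_of_atom)
      disp[ing, ] <- outer(S[t, group_of_atom[ing]], direction)
      if (sigma > 0) disp <- disp + matrix(rnorm(3 * nat, sd = sigma), nat, 3)
      coords[t, , ] <- reference$coords + disp
    }
    list(trajectory = trajectory(coords, (seq_len(n_frames) - 1) * dt, top),
         latents = S, group_of_atom = group_of_atom)
  })
}

#' Two-group contact-kinetics scenario
#'
#' A residue-700 side-chain-like atom group (chain A) and a small RNA
#' phosphate group (chain R) separated along x by
#' `d(t) = d0 + speed * t`; matched atoms sit at identical y offsets, so
#' the minimum cross-group distance at time t is exactly `d(t)` (plus
#' optional jitter). With positive speed the groups separate and the
#' contact count under a cutoff c drops to zero after the crossing time
#' `t* = (c - d0)/speed` — the controllable analogue of a mutant
#' interface losing its contacts mid-trajectory.
#'
#' @param d0 initial separation (nm).
#' @param speed separation velocity (nm/ps); 0 for a static interface.
#' @param n_frames,dt,seed as elsewhere.
#' @param jitter optional isotropic positional noise sd (nm).
#' @param n_offsets number of matched y-offset atom rows per group.
#' @return list: `trajectory`, `selA`, `selB` (index vectors),
#'   `separation` (length-T d(t)).
#' @export
sample_contact_trajectory <- function(d0 = 0.18, speed = 0, n_frames = 500L,
                                      dt = 100, seed = 1L, jitter = 0,
                                      n_offsets = 3L) {
  stopifnot(d0 > 0, n_frames >= 2)
  y <- 0.12 * (seq_len(n_offsets) - 1)
  nmA <- c("CB", "CG", "NZ")[seq_len(min(3, n_offsets))]
  if (n_offsets > 3) nmA <- c(nmA, paste0("C", seq_len(n_offsets - 3) + 3))
  top <- topology(
    serial = seq_len(2 * n_offsets),
    name = c(nmA, rep("P", n_offsets)),
    element = c(infer_element(nmA), rep("P", n_offsets)),
    resname = c(rep("LYS", n_offsets), rep("U", n_offsets)),
    resid = c(rep(700L, n_offsets), seq_len(n_offsets)),
    chain = c(rep("A", n_offsets), rep("R", n_offsets))
  )
  times <- (seq_len(n_frames) - 1) * dt
  sep <- d0 + speed * times
  if (any(sep <= 0)) stop("separation becomes non-positive; groups collide")
  base <- cbind(0, y, 0)
  withr::with_seed(seed, {
    coords <- array(0, dim = c(n_frames, 2 * n_offsets, 3))
    for (t in seq_len(n_frames)) {
      A <- base
      B <- base; B[, 1] <- sep[t]
      fr <- rbind(A, B)
      if (jitter > 0) fr <- fr + matrix(rnorm(length(fr), sd = jitter),
                                        nrow(fr), 3)
      coords[t, , ] <- fr
    }
    list(trajectory = trajectory(coords, times, top),
         selA = seq_len(n_offsets), selB = n_offsets + seq_len(n_offsets),
         separation = sep)
  })
}

#' Crossing time of a linear separation through a cutoff
#' @param d0 initial separation (nm).
#' @param speed separation velocity (nm/ps), nonzero.
#' @param cutoff contact cutoff (nm).
#' @return time (ps) at which `d(t) = cutoff`.
#' @export
contact_crossing_time <- function(d0, speed, cutoff) {
  if (speed == 0) stop("crossing time undefined for a static separation")
  (cutoff - d0) / speed
}

#' Random gene network with a planted mutation hub
#'
#' Erdos-Renyi background network over the named genes plus decoys, with
#' the hub wired to a prescribed number of partners. The mutation table
#' plants an exact number of filter-surviving records per gene
#' (missense, pathogenic, score above threshold, matching histology) —
#' the hub strictly the most — plus distractor records that each fail
#' exactly one criterion, so prioritization on the output must rank the
#' hub first with exactly the planted counts. Defaults mirror the
#' breast-carcinoma splicing-gene scenario: SF3B1 with 34 surviving
#' records (most frequent change K700E) against DHX15 13, PRPF19 6,
#' U2AF2 2, SRSF1 2, SF3A2 1.
#'
#' @param gene_counts named integer vector of planted surviving-record
#'   counts; first entry is the hub and must be the strict maximum.
#' @param hub_top_change aa change planted as the hub's most frequent.
#' @param n_decoys number of additional mutation-free genes.
#' @param edge_prob background edge probability.
#' @param hub_degree minimum hub degree.
#' @param histology histology label of surviving records.
#' @param score_threshold planted scores lie strictly above this.
#' @param seed RNG seed.
#' @return list: `network` ([gene_network()]), `records`
#'   ([mutation_records()]), `truth` (planted counts).
#' @export
sample_network_and_mutations <- function(
    gene_counts = c(SF3B1 = 34L, DHX15 = 13L, PRPF19 = 6L, U2AF2 = 2L,
                    SRSF1 = 2L, SF3A2 = 1L),
    hub_top_change = "K700E", n_decoys = 40L, edge_prob = 0.12,
    hub_degree = 12L, histology = "carcinoma", score_threshold = 0.9,
    seed = 1L) {
  if (length(gene_counts) < 1 || is.null(names(gene_counts))) {
    stop("gene_counts must be a named vector; first entry is the hub")
  }
  hub <- names(gene_counts)[1]
  if (length(gene_counts) > 1 &&
      gene_counts[1] <= max(gene_counts[-1])) {
    stop("infeasible mixture: the hub count must be the strict maximum")
  }
  genes <- c(names(gene_counts),
             sprintf("GEN%03d", seq_len(n_decoys)))
  withr::with_seed(seed, {
    n <- length(genes)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < edge_prob
    ed <- data.frame(gene_a = genes[pairs[on, 1]],
                     gene_b = genes[pairs[on, 2]],
                     score = round(runif(sum(on), 0.4, 1), 3))
    partners <- sample(setdiff(genes, hub), min(hub_degree, n - 1))
    ed <- rbind(ed, data.frame(gene_a = hub, gene_b = partners,
                               score = round(runif(length(partners),
                                                   0.7, 1), 3)))
    net <- gene_network(ed, nodes = genes)

    mk_change <- function(m) {
      sprintf("%s%d%s", sample(c("A", "G", "L", "R", "E", "T"), m, TRUE),
              sample(100:900, m, TRUE),
              sample(c("V", "D", "H", "S", "P"), m, TRUE))
    }
    recs <- list()
    sid <- 0L
    for (g in names(gene_counts)) {
      cnt <- gene_counts[[g]]
      if (cnt == 0) next
      if (g == hub) {
        n_top <- max(2L, ceiling(cnt * 0.6))
        ch <- c(rep(hub_top_change, n_top), mk_change(cnt - n_top))
      } else {
        ch <- mk_change(cnt)
      }
      # distinct changes must not outnumber the planted top change
      ch[duplicated(ch) & ch != hub_top_change] <-
        mk_change(sum(duplicated(ch) & ch != hub_top_change))
      recs[[length(recs) + 1L]] <- data.frame(
        gene = g, sample_id = sprintf("S%05d", sid + seq_along(ch)),
        mutation_type = "Substitution - Missense", aa_change = ch,
        histology = histology, fathmm_prediction = "PATHOGENIC",
        fathmm_score = round(runif(length(ch), score_threshold + 0.005,
                                   0.999), 4))
      sid <- sid + length(ch)
      # distractors failing exactly one criterion each
      recs[[length(recs) + 1L]] <- data.frame(
        gene = g, sample_id = sprintf("S%05d", sid + 1:4),
        mutation_type = c("Substitution - Missense",
                          "Substitution - coding silent",
                          "Substitution - Missense",
                          "Substitution - Missense"),
        aa_change = c(mk_change(1), "G83=", mk_change(2)),
        histology = c("adenoma", histology, histology, histology),
        fathmm_prediction = c("PATHOGENIC", "NEUTRAL", "NEUTRAL",
                              "PATHOGENIC"),
        fathmm_score = c(0.95, NA, 0.95,
                         round(runif(1, 0.5, score_threshold - 0.01), 4)))
      sid <- sid + 4L
    }
    df <- do.call(rbind, recs)
    records <- mutation_records(df$gene, df$sample_id, df$mutation_type,
                                df$aa_change, df$histology,
                                df$fathmm_prediction, df$fathmm_score)
    list(network = net, records = records,
         truth = list(counts = gene_counts, hub = hub,
                      hub_top_change = hub_top_change,
                      histology = histology,
                      score_threshold = score_threshold))
  })
}

#' Disjoint-component network with prescribed sizes and edge counts
#'
#' Builds a gene network as a disjoint union of connected components,
#' each with an exact node and edge count (random spanning tree plus
#' random extra pairs). The defaults assemble the reported composition
#' of the pre-mRNA-splicing network: one 54-node/382-edge core plus
#' satellite components of 5/10 (complete), 3/2, 3/2 and 2/1 — 67 nodes
#' and 397 edges in total.
#'
#' @param sizes component node counts.
#' @param edge_counts matching component edge counts; each must lie in
#'   `[size - 1, choose(size, 2)]`.
#' @param seed RNG seed.
#' @return a [gene_network()].
#' @export
sample_component_network <- function(sizes = c(54L, 5L, 3L, 3L, 2L),
                                     edge_counts = c(382L, 10L, 2L, 2L, 1L),
                                     seed = 1L) {
  stopifnot(length(sizes) == length(edge_counts))
  for (i in seq_along(sizes)) {
    n <- sizes[i]; m <- edge_counts[i]
    if (m < n - 1 || m > choose(n, 2)) {
      stop("component ", i, ": ", m, " edges infeasible for ", n, " nodes")
    }
  }
  withr::with_seed(seed, {
    edges <- list()
    for (ci in seq_along(sizes)) {
      n <- sizes[ci]; m <- edge_counts[ci]
      nodes <- sprintf("C%dG%02d", ci, seq_len(n))
      # random spanning tree: attach each node to an earlier one
      tree <- if (n > 1) {
        to <- vapply(2:n, function(k) sample.int(k - 1, 1), 1L)
        cbind(nodes[to], nodes[2:n])
      } else matrix(character(0), 0, 2)
      all_pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
      key <- paste(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
      pool <- paste(nodes[all_pairs[, 1]], nodes[all_pairs[, 2]])
      extra_pool <- all_pairs[!(pool %in% key), , drop = FALSE]
      need <- m - nrow(tree)
      pick <- extra_pool[sample.int(nrow(extra_pool), need), , drop = FALSE]
      edges[[ci]] <- rbind(tree,
                           cbind(nodes[pick[, 1]], nodes[pick[, 2]]))
    }
    em <- do.call(rbind, edges)
    gene_network(data.frame(gene_a = em[, 1], gene_b = em[, 2]))
  })
}

#' SF3B1 per-sample mutation table with the reported sample counts
#'
#' A COSMIC-dialect table for one gene carrying the reported breast-
#' carcinoma sample counts per amino-acid change: K700E in 45 samples;
#' K666Q, R625C and T935K in 2 each; the synonymous G83= and L982= in 2
#' each; 21 samples with an unknown change; and 44 further distinct
#' missense changes in one sample each (120 records in total — the
#' printed per-change counts). Missense records are pathogenic with
#' scores above 0.9; synonymous and unknown records carry neutral /
#' unspecified annotations so they fall to the filters.
#'
#' @param seed RNG seed (scores and sample ids only; counts are fixed).
#' @return a [mutation_records()] table.
#' @export
sf3b1_sample_table <- function(seed = 1L) {
  singles <- sprintf("%s%d%s",
                     rep(c("A", "G", "L", "R"), length.out = 44),
                     as.integer(round(seq(150, 1200, length.out = 44))),
                     rep(c("V", "D", "H", "S"), length.out = 44))
  changes <- c(rep("K700E", 45), rep(c("K666Q", "R625C", "T935K"), each = 2),
               singles)
  syn <- rep(c("G83=", "L982="), each = 2)
  unk <- rep("?", 21)
  n_mis <- length(changes)
  withr::with_seed(seed, {
    mutation_records(
      gene = "SF3B1",
      sample_id = sprintf("BRCA%04d", seq_len(n_mis + length(syn) +
                                                length(unk))),
      mutation_type = c(rep("Substitution - Missense", n_mis),
                        rep("Substitution - coding silent", length(syn)),
                        rep("Unknown", length(unk))),
      aa_change = c(changes, syn, unk),
      histology = "carcinoma",
      fathmm_prediction = c(rep("PATHOGENIC", n_mis),
                            rep("NEUTRAL", length(syn)),
                            rep("", length(unk))),
      fathmm_score = c(round(runif(n_mis, 0.905, 0.999), 4),
                       rep(NA_real_, length(syn) + length(unk)))
    )
  })
}

#' Synthetic K700/pre-mRNA interface model
#'
#' A small synthetic stand-in for the prepared spliceosome model around
#' the SF3B1 K700 site: a three-residue protein stretch (699-701, chain
#' A) whose central lysine side chain extends toward a three-nucleotide
#' RNA (chain R), planted so that the minimum side-chain-to-RNA
#' distance is below 0.20 nm both over heavy atoms (NZ to a phosphate
#' oxygen, 0.19 nm) and over all atoms including the amine hydrogen
#' (0.16 nm). This object is synthetic — it demonstrates the
#' measurement, it is not the experimental structure.
#'
#' @param hydrogens include the side-chain amine hydrogen.
#' @return list: `topology`, `coords` (nm).
#' @export
synthetic_k700_interface <- function(hydrogens = TRUE) {
  # protein: residues 699-701, full lysine side chain on 700
  prot <- list(
    list(resid = 699L, name = "N",  xyz = c(-0.45, 0.10, 0.00)),
    list(resid = 699L, name = "CA", xyz = c(-0.38, 0.00, 0.00)),
    list(resid = 699L, name = "C",  xyz = c(-0.26, 0.09, 0.00)),
    list(resid = 699L, name = "O",  xyz = c(-0.26, 0.21, 0.00)),
    list(resid = 699L, name = "CB", xyz = c(-0.40, -0.12, 0.10)),
    list(resid = 700L, name = "N",  xyz = c(-0.12, 0.08, 0.00)),
    list(resid = 700L, name = "CA", xyz = c(0.00, 0.00, 0.00)),
    list(resid = 700L, name = "C",  xyz = c(0.10, 0.08, -0.08)),
    list(resid = 700L, name = "O",  xyz = c(0.08, 0.20, -0.10)),
    list(resid = 700L, name = "CB", xyz = c(0.06, -0.05, 0.13)),
    list(resid = 700L, name = "CG", xyz = c(0.17, -0.14, 0.17)),
    list(resid = 700L, name = "CD", xyz = c(0.23, -0.22, 0.28)),
    list(resid = 700L, name = "CE", xyz = c(0.34, -0.31, 0.32)),
    list(resid = 700L, name = "NZ", xyz = c(0.44, -0.38, 0.38)),
    list(resid = 701L, name = "N",  xyz = c(0.22, 0.04, -0.12)),
    list(resid = 701L, name = "CA", xyz = c(0.33, 0.11, -0.18)),
    list(resid = 701L, name = "C",  xyz = c(0.45, 0.03, -0.22)),
    list(resid = 701L, name = "O",  xyz = c(0.46, -0.09, -0.20)),
    list(resid = 701L, name = "CB", xyz = c(0.36, 0.24, -0.10))
  )
  nz <- c(0.44, -0.38, 0.38)
  u <- c(0.62, -0.50, 0.60); u <- u / sqrt(sum(u^2))
  # phosphate oxygen on the salt-bridge axis: NZ...O1P = 0.19 nm; the
  # amine hydrogen sits 0.10 nm out from NZ along the same axis, so the
  # all-atom minimum distance is 0.09 nm
  o1p <- nz + 0.19 * u
  if (hydrogens) {
    prot <- c(prot, list(
      list(resid = 700L, name = "HZ1", xyz = nz + 0.10 * u),
      list(resid = 700L, name = "HZ2", xyz = nz + c(-0.06, -0.06, 0.06))
    ))
  }
  rna_origin <- o1p + c(0.10, -0.08, 0.06)
  rna <- list()
  for (j in 1:3) {
    base <- rna_origin + (j - 1) * c(0.45, 0.30, -0.10)
    rna <- c(rna, list(
      list(resid = j, name = "P",   xyz = base),
      list(resid = j, name = "OP1", xyz = if (j == 1) o1p else
        base + c(-0.08, 0.10, 0.08)),
      list(resid = j, name = "OP2", xyz = base + c(0.10, 0.10, -0.06)),
      list(resid = j, name = "O5'", xyz = base + c(0.05, -0.12, 0.09)),
      list(resid = j, name = "C1'", xyz = base + c(0.28, -0.10, 0.14)),
      list(resid = j, name = "N1",  xyz = base + c(0.40, -0.02, 0.22))
    ))
  }
  all <- c(prot, rna)
  nmv <- vapply(all, function(a) a$name, "")
  rid <- vapply(all, function(a) as.integer(a$resid), 1L)
  is_prot <- c(rep(TRUE, length(prot)), rep(FALSE, length(rna)))
  resname <- ifelse(is_prot,
                    c(`699` = "GLU", `700` = "LYS", `701` = "SER")[
                      as.character(rid)],
                    "U")
  top <- topology(
    serial = seq_along(all), name = nmv, element = infer_element(nmv),
    resname = resname, resid = rid,
    chain = ifelse(is_prot, "A", "R")
  )
  coords <- do.call(rbind, lapply(all, function(a) a$xyz))
  list(topology = top, coords = unname(coords))
}

#' Paired wild-type-like / mutant-like synthetic scenarios
#'
#' The qualitative signature suite: two matched synthetic systems on a
#' C-alpha chain whose residue numbers span 455-1300 (in steps of 9, 94
#' residues), planting the three contrasts the K700E comparison shows —
#' (i) a right-shifted RMSD distribution in the mutant (larger mode
#' amplitudes and noise), (ii) a K700-like contact interface whose
#' contacts decay to zero halfway through the mutant run but persist in
#' the wild type, and (iii) a 455-832 correlation block that is strong
#' and negatively coupled to 932-1300 in the wild type but attenuated
#' in the mutant.
#'
#' @param seed RNG seed.
#' @param n_frames frames per trajectory.
#' @param dt frame spacing (ps).
#' @param contact_cutoff contact cutoff (nm) the contact scenario is
#'   tuned against (default 0.3, the K700 side-chain cutoff).
#' @return nested list with `wild_type` and `mutant` scenario bundles
#'   plus the shared `regions` and planted `truth`.
#' @export
sample_paired_scenarios <- function(seed = 1L, n_frames = 600L, dt = 100,
                                   contact_cutoff = 0.3) {
  resids <- seq(455L, 1300L, by = 9L)
  ref <- make_chain_reference(length(resids), resids = resids,
                              atoms = "calpha", layout = "helix")
  regions <- list(c(455L, 832L), c(932L, 1300L))
  rho_wt <- matrix(c(1, -0.6, -0.6, 1), 2)
  rho_mt <- matrix(c(1, -0.15, -0.15, 1), 2)
  v_block <- 0.04
  # noise sd giving within-block DCC attenuation v/(v+3s^2) = alpha
  sig_for <- function(alpha) sqrt(v_block * (1 / alpha - 1) / 3)
  mk <- function(lab, total_var, speed, rho, alpha, s) {
    # both systems share the 37/15 eigenvector split; the mutant's larger
    # total variance produces the right-shifted RMSD distribution
    plant <- calibrated_mode_plant(total_var, c(0.37, 0.15),
                                   length(resids))
    ct <- sample_contact_trajectory(d0 = 0.18, speed = speed,
                                    n_frames = n_frames, dt = dt,
                                    seed = s + 2L)
    list(
      label = lab,
      mode = sample_mode_trajectory(ref, eigenvalues = plant$eigenvalues,
                                    sigma = plant$sigma,
                                    n_frames = n_frames, dt = dt, seed = s),
      contact = ct,
      block = sample_block_trajectory(ref, regions, rho,
                                      latent_var = v_block,
                                      sigma = sig_for(alpha),
                                      n_frames = n_frames, dt = dt,
                                      seed = s + 4L)
    )
  }
  # mutant separates through the cutoff at half the run
  half_t <- (n_frames / 2) * dt
  v_mt <- (contact_cutoff - 0.18) / half_t
  list(
    wild_type = mk("wild_type", total_var = 0.28, speed = 0, rho = rho_wt,
                   alpha = 0.9, s = seed),
    mutant = mk("mutant", total_var = 1.12, speed = v_mt, rho = rho_mt,
                alpha = 0.35, s = seed + 100L),
    regions = regions,
    truth = list(rho = list(wild_type = rho_wt, mutant = rho_mt),
                 attenuation = c(wild_type = 0.9, mutant = 0.35),
                 contact_crossing_ps = c(wild_type = NA, mutant = half_t),
                 cutoff = contact_cutoff)
  )
}
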