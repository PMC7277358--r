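# Independent brute-force oracles. These deliberately avoid the code
# paths they validate: Floyd-Warshall instead of BFS/igraph, double
# loops instead of vectorized linear algebra, the quaternion
# characteristic-polynomial bound instead of the SVD fit.

# All-pairs shortest paths by Floyd-Warshall over an edge data.frame.
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- match(edges[[1]][r], nodes); j <- match(edges[[2]][r], nodes)
    D[i, j] <- D[j, i] <- 1
  }
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, Dk)
  }
  D
}

# Centralities computed directly from a Floyd-Warshall distance matrix.
fw_centralities <- function(nodes, edges) {
  D <- fw_distances(nodes, edges)
  res <- lapply(nodes, function(g) {
    d <- D[g, ]
    comp <- names(d)[is.finite(d)]
    if (length(comp) == 1L) {
      return(data.frame(gene = g, eccentricity = NA_integer_,
                        closeness = NA_real_, radiality = NA_real_))
    }
    dc <- d[comp]
    diam <- max(D[comp, comp])
    meand <- sum(dc) / (length(comp) - 1)
    data.frame(gene = g, eccentricity = as.integer(max(dc)),
               closeness = 1 / meand,
               radiality = (diam + 1 - meand) / diam)
  })
  out <- do.call(rbind, res)
  out[order(out$gene), , drop = FALSE]
}

random_test_network <- function(n, p, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("G%02d", seq_len(n))
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    on <- runif(nrow(pr)) < p
    gene_network(data.frame(gene_a = nodes[pr[on, 1]],
                            gene_b = nodes[pr[on, 2]]),
                 nodes = nodes)
  })
}

# Brute-force cross-group pair scans.
brute_min_distance <- function(frame, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    if (d < best) best <- d
  }
  best
}

brute_contact_count <- function(frame, ia, ib, cutoff) {
  cnt <- 0L
  for (i in ia) for (j in ib) {
    if (sqrt(sum((frame[i, ] - frame[j, ])^2)) <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# Double-loop cross-correlation map over a T x N x 3 coordinate array.
dccm_double_loop <- function(coords) {
  tt <- dim(coords)[1]; n <- dim(coords)[2]
  mu <- apply(coords, c(2, 3), mean)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; di2 <- 0; dj2 <- 0
    for (t in seq_len(tt)) {
      di <- coords[t, i, ] - mu[i, ]
      dj <- coords[t, j, ] - mu[j, ]
      num <- num + sum(di * dj)
      di2 <- di2 + sum(di^2); dj2 <- dj2 + sum(dj^2)
    }
    M[i, j] <- num / sqrt(di2 * dj2)
  }
  M
}

# Minimal attainable RMSD of a rigid fit, from the largest eigenvalue of
# Horn's quaternion matrix (no rotation matrix involved).
quaternion_min_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(P, Q)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lmax) / nrow(P)))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# Small static trajectory used by several tests.
static_trajectory <- function(n_res = 5, n_frames = 4) {
  ref <- make_chain_reference(n_res, atoms = "calpha")
  coords <- array(0, dim = c(n_frames, n_res, 3))
  for (t in seq_len(n_frames)) coords[t, , ] <- ref$coords
  trajectory(coords, topology = ref$topology)
}
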