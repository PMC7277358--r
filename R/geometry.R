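#' Optimal rigid superposition (Kabsch)
#'
#' Weighted least-squares fit of `mobile` onto `reference`: the returned
#' rotation `R` (proper orthogonal, reflections excluded) and translation
#' `t` minimise the weighted squared deviation of `mobile %*% R + t` from
#' `reference`.
#'
#' @param mobile N x 3 coordinates (nm).
#' @param reference N x 3 coordinates (nm), paired by row.
#' @param weights length-N non-negative weights; uniform by default.
#' @return list of class `superposition`: `rotation` (3 x 3), `translation`
#'   (length 3, nm), and `rmsd` — the post-fit weighted RMSD (nm).
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L, nrow(reference) == n)
  if (n < 3L) stop("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  wsum <- sum(weights)
  if (wsum <= 0) stop("superposition weights are all zero")
  w <- weights / wsum
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P * w, Q)  # 3x3 weighted covariance
  sv <- svd(H)
  # collinear/degenerate geometry leaves the rotation underdetermined
  if (sv$d[2] < 1e-12 * max(sv$d[1], .Machine$double.eps)) {
    stop("degenerate geometry: points are (near-)collinear, ",
         "rotation underdetermined")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P %*% R
  dev2 <- rowSums((fitted - Q)^2)
  structure(list(rotation = R,
                 translation = as.numeric(cr - cm %*% R),
                 rmsd = sqrt(sum(w * dev2))),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param fit a `superposition` from [kabsch_fit()].
#' @param coords N x 3 matrix (nm); need not be the fitted atoms.
#' @export
apply_superposition <- function(fit, coords) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, -fit$translation)
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' `sqrt(mean_i d_i^2)` over the n index-paired atoms, where `d_i` is the
#' Euclidean distance of pair i. No superposition is performed here; see
#' [rmsd_series()] for the fitted variant.
#'
#' @param a,b N x 3 coordinate matrices (nm), paired by row.
#' @return RMSD in nm.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0) stop("RMSD of zero atoms is undefined")
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3L, ncol(b) == 3L)
  sqrt(mean(rowSums((a - b)^2)))
}

#' A scalar per-frame series with units
#' @param values length-T numbers.
#' @param times length-T timestamps (ps).
#' @param units unit tag, e.g. "nm" or "count".
#' @export
scalar_series <- function(values, times, units = "nm") {
  stopifnot(length(values) == length(times))
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 units = units),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat("scalar_series (", x$units, "): T=", length(x$values),
      " mean=", signif(mean(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' RMSD time series against a reference frame
#'
#' Each frame is rigidly superposed onto the reference frame using the
#' fit selection, then the RMSD is evaluated on the calculation
#' selection. The default reference is the first frame, matching the
#' convention of measuring drift from the initial structure of a run;
#' fitting can be disabled for analytic work on raw displacements.
#'
#' @param traj a [trajectory()].
#' @param fit_sel,calc_sel selections (string or [atom_selection()]);
#'   both default to backbone atoms.
#' @param reference reference frame index (1-based), default 1.
#' @param fit superpose before measuring (default TRUE).
#' @param mass_weighted use atomic masses as fit weights.
#' @return a [scalar_series()] in nm.
#' @export
rmsd_series <- function(traj, fit_sel = atom_selection(class = "backbone"),
                        calc_sel = fit_sel, reference = 1L, fit = TRUE,
                        mass_weighted = FALSE) {
  if (reference < 1L || reference > n_frames(traj)) {
    stop("reference frame ", reference, " out of range 1..", n_frames(traj))
  }
  ifit <- select_atoms(traj$topology, fit_sel)
  icalc <- select_atoms(traj$topology, calc_sel)
  if (!length(ifit) || !length(icalc)) stop("empty selection for RMSD series")
  ref <- frame_coords(traj, reference)
  w <- if (mass_weighted) traj$topology$mass[ifit] else NULL
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    fr <- frame_coords(traj, t)
    if (fit) {
      sp <- kabsch_fit(fr[ifit, , drop = FALSE], ref[ifit, , drop = FALSE],
                       weights = w)
      fr <- apply_superposition(sp, fr)
    }
    rmsd(fr[icalc, , drop = FALSE], ref[icalc, , drop = FALSE])
  }, numeric(1))
  scalar_series(vals, traj$times, units = "nm")
}

# Squared cross-distance matrix between two coordinate sets (na x nb).
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical negatives
  d2
}

resolve_pair <- function(frame, top, selA, selB) {
  ia <- if (is.numeric(selA)) as.integer(selA) else select_atoms(top, selA)
  ib <- if (is.numeric(selB)) as.integer(selB) else select_atoms(top, selB)
  if (!length(ia) || !length(ib)) stop("both selections must be nonempty")
  if (length(intersect(ia, ib))) {
    stop("selections overlap (", length(intersect(ia, ib)),
         " shared atoms); cross-group distances need disjoint groups")
  }
  list(ia = ia, ib = ib)
}

#' Minimum cross-group distance in one frame
#'
#' Minimum Euclidean distance over all atom pairs (i in A, j in B).
#' Selections must be disjoint.
#'
#' @param frame N x 3 coordinate matrix (nm).
#' @param top the matching [topology()].
#' @param selA,selB selections (string, [atom_selection()], or raw index
#'   vectors).
#' @return distance in nm.
#' @export
min_distance <- function(frame, top, selA, selB) {
  p <- resolve_pair(frame, top, selA, selB)
  sqrt(min(cross_dist2(frame[p$ia, , drop = FALSE],
                       frame[p$ib, , drop = FALSE])))
}

#' Count cross-group atom contacts within a cutoff
#'
#' Number of atom pairs (i in A, j in B) at distance less than or equal
#' to the cutoff; the boundary is inclusive. Pair counting (not residue
#' counting) matches the contact definition of minimum-distance tools.
#'
#' @inheritParams min_distance
#' @param cutoff contact cutoff in nm (the SF3b study used 0.3 nm for the
#'   K700 side chain vs pre-mRNA and 3 nm for p14 side chains vs
#'   pre-mRNA).
#' @return integer pair count.
#' @export
contact_count <- function(frame, top, selA, selB, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive")
  p <- resolve_pair(frame, top, selA, selB)
  d2 <- cross_dist2(frame[p$ia, , drop = FALSE],
                    frame[p$ib, , drop = FALSE])
  sum(d2 <= cutoff^2)
}

#' Per-frame contact-count series
#' @inheritParams contact_count
#' @param traj a [trajectory()].
#' @return a [scalar_series()] with units "count".
#' @export
contact_series <- function(traj, selA, selB, cutoff) {
  top <- traj$topology
  ia <- if (is.numeric(selA)) as.integer(selA) else select_atoms(top, selA)
  ib <- if (is.numeric(selB)) as.integer(selB) else select_atoms(top, selB)
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    contact_count(frame_coords(traj, t), top, ia, ib, cutoff)
  }, numeric(1))
  scalar_series(vals, traj$times, units = "count")
}

#' Per-frame minimum-distance series
#' @inheritParams contact_count
#' @param traj a [trajectory()].
#' @return a [scalar_series()] in nm.
#' @export
min_distance_series <- function(traj, selA, selB) {
  top <- traj$topology
  ia <- if (is.numeric(selA)) as.integer(selA) else select_atoms(top, selA)
  ib <- if (is.numeric(selB)) as.integer(selB) else select_atoms(top, selB)
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    min_distance(frame_coords(traj, t), top, ia, ib)
  }, numeric(1))
  scalar_series(vals, traj$times, units = "nm")
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF of each selected atom about a reference position over the
#' trajectory: `sqrt(mean_t ||x_i(t) - ref_i||^2)`. The reference is the
#' per-atom time average (default) or the first frame. Frames are
#' optionally superposed first via `fit_sel`.
#'
#' @param traj a [trajectory()].
#' @param sel atoms to report (string or [atom_selection()]).
#' @param reference_mode `"time_average"` or `"initial_frame"`.
#' @param fit_sel optional selection used to superpose every frame onto
#'   frame 1 before measuring; NULL means frames are used as stored.
#' @return named numeric vector (nm), one entry per selected atom.
#' @export
rmsf <- function(traj, sel = atom_selection(class = "calpha"),
                 reference_mode = c("time_average", "initial_frame"),
                 fit_sel = NULL) {
  reference_mode <- match.arg(reference_mode)
  tt <- n_frames(traj)
  if (tt < 2L) stop("RMSF needs at least 2 frames")
  idx <- select_atoms(traj$topology, sel)
  if (!length(idx)) stop("empty selection for RMSF")
  coords <- traj$coords
  if (!is.null(fit_sel)) {
    ifit <- select_atoms(traj$topology, fit_sel)
    ref <- frame_coords(traj, 1L)
    for (t in seq_len(tt)) {
      fr <- frame_coords(traj, t)
      sp <- kabsch_fit(fr[ifit, , drop = FALSE], ref[ifit, , drop = FALSE])
      coords[t, , ] <- apply_superposition(sp, fr)
    }
  }
  X <- coords[, idx, , drop = FALSE]
  refpos <- if (reference_mode == "time_average") {
    apply(X, c(2, 3), mean)
  } else {
    matrix(X[1, , ], ncol = 3)
  }
  dev2 <- vapply(seq_len(tt), function(t) {
    rowSums((matrix(X[t, , ], ncol = 3) - refpos)^2)
  }, numeric(length(idx)))
  out <- sqrt(rowMeans(matrix(dev2, nrow = length(idx))))
  names(out) <- paste0(traj$topology$chain[idx], traj$topology$resid[idx],
                       ":", traj$topology$name[idx])
  out
}

#' Probability distribution of a scalar series
#'
#' Normalized histogram: per-bin probabilities (not densities) that sum
#' to one, as used for RMSD and contact-count probability plots.
#'
#' @param series a [scalar_series()] or numeric vector.
#' @param bins number of equal-width bins, or an explicit vector of
#'   strictly increasing bin edges.
#' @return list of class `distribution`: `edges`, `prob`, `mids`.
#' @export
distribution <- function(series, bins = 30) {
  x <- if (inherits(series, "scalar_series")) series$values else
    as.numeric(series)
  if (!length(x)) stop("empty series")
  if (length(bins) == 1L) {
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    edges <- as.numeric(bins)
  }
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  h <- graphics::hist(x, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  if (sum(h$counts) != length(x)) {
    stop("values fall outside the supplied bin edges")
  }
  structure(list(edges = edges, prob = h$counts / length(x), mids = h$mids),
            class = "distribution")
}

#' Mean of a distribution (probability-weighted bin midpoints)
#' @param d a [distribution()].
#' @export
distribution_mean <- function(d) sum(d$prob * d$mids)

#' Mean shift between two scalar series
#'
#' Difference of means, `mean(b) - mean(a)`; positive when `b` is
#' right-shifted relative to `a` (e.g. a destabilised mutant RMSD
#' distribution vs wild type).
#'
#' @param a,b [scalar_series()] or numeric vectors.
#' @export
mean_shift <- function(a, b) {
  va <- if (inherits(a, "scalar_series")) a$values else as.numeric(a)
  vb <- if (inherits(b, "scalar_series")) b$values else as.numeric(b)
  mean(vb) - mean(va)
}

#' Write a scalar series as two-column TSV (time, value)
#' @param series a [scalar_series()].
#' @param path output path.
#' @export
write_series <- function(series, path) {
  df <- data.frame(time_ps = series$times, value = series$values)
  names(df)[2] <- series$units
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
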