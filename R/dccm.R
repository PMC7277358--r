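#' Dynamic cross-correlation map of selected atoms
#'
#' Normalized equal-time cross-correlation of displacement vectors:
#' `DCC(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, with
#' displacements taken about each atom's time mean and the time-ensemble
#' average running over frames. Frames are superposed onto the mean
#' structure on the same selection first — unremoved rigid-body motion
#' would otherwise saturate the correlations. Entries lie in [-1, 1]
#' with a unit diagonal; +1 is fully correlated motion, -1 fully
#' anti-correlated.
#'
#' Atoms with zero total fluctuation have an undefined correlation; their
#' rows and columns are set to NA with a warning, never silently zero.
#'
#' @param traj a [trajectory()].
#' @param sel selection, typically C-alpha atoms.
#' @param superpose superpose to the mean structure first (default TRUE).
#' @return object of class `dccm_map`: `matrix` (N x N) and `resid`
#'   (author residue numbers labelling rows/columns).
#' @export
compute_dccm <- function(traj, sel = atom_selection(class = "calpha"),
                         superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("DCCM needs at least 2 frames")
  idx <- select_atoms(traj$topology, sel)
  if (!length(idx)) stop("empty selection for DCCM")
  if (superpose) {
    traj <- superpose_trajectory(traj, sel, reference = "mean")$trajectory
  }
  tt <- n_frames(traj)
  n <- length(idx)
  # per-axis n x T displacement matrices about the time mean
  cross <- matrix(0, n, n)
  for (k in 1:3) {
    Xk <- t(traj$coords[, idx, k])          # n x T
    Xk <- Xk - rowMeans(Xk)
    cross <- cross + tcrossprod(Xk) / tt    # <dr_i . dr_j> accumulates
  }
  amp <- diag(cross)
  zero <- amp <= 0
  if (any(zero)) {
    warning(sum(zero), " atom(s) with zero fluctuation; their DCCM ",
            "rows/columns are undefined (NA)")
  }
  denom <- sqrt(outer(pmax(amp, .Machine$double.xmin),
                      pmax(amp, .Machine$double.xmin)))
  M <- cross / denom
  M[M > 1] <- 1; M[M < -1] <- -1
  diag(M) <- 1
  M[zero, ] <- NA_real_; M[, zero] <- NA_real_
  resid <- traj$topology$resid[idx]
  dimnames(M) <- list(resid, resid)
  structure(list(matrix = M, resid = resid), class = "dccm_map")
}

#' @export
print.dccm_map <- function(x, ...) {
  cat("dccm_map:", nrow(x$matrix), "x", ncol(x$matrix),
      "residues", x$resid[1], "-", x$resid[length(x$resid)], "\n")
  invisible(x)
}

# Resolve an inclusive residue-number range to matrix indices.
resolve_region <- function(map, region) {
  stopifnot(length(region) == 2L, region[1] <= region[2])
  idx <- which(map$resid >= region[1] & map$resid <= region[2])
  if (!length(idx)) {
    stop("region ", region[1], "-", region[2],
         " resolves to no residues in the map")
  }
  idx
}

#' Summary statistic over a region pair of a correlation map
#'
#' Statistic (mean or median) over the off-diagonal submatrix
#' `map[regionA, regionB]`; self-pairs (the diagonal) are excluded when
#' the regions overlap. Used to compare coupling blocks such as residues
#' 455-832 within themselves (positive in the wild type) and against
#' 932-1300 (negative in the wild type, both attenuated in the K700E
#' mutant).
#'
#' @param map a `dccm_map`.
#' @param regionA,regionB inclusive residue-number ranges `c(lo, hi)`.
#' @param stat `"mean"` or `"median"`.
#' @export
block_stat <- function(map, regionA, regionB = regionA,
                       stat = c("mean", "median")) {
  stat <- match.arg(stat)
  ia <- resolve_region(map, regionA)
  ib <- resolve_region(map, regionB)
  sub <- map$matrix[ia, ib, drop = FALSE]
  same <- outer(ia, ib, "==")
  vals <- sub[!same]
  if (!length(vals)) stop("region pair has no off-diagonal entries")
  if (stat == "mean") mean(vals, na.rm = TRUE) else median(vals, na.rm = TRUE)
}

#' Write a correlation map as TSV (and optionally a heatmap image)
#'
#' The TSV carries the full matrix with residue labels in the header row
#' and first column and round-trips exactly; the PNG heatmap is
#' cosmetic.
#'
#' @param map a `dccm_map`.
#' @param path output TSV path.
#' @param png_path optional heatmap image path.
#' @export
write_dccm <- function(map, path, png_path = NULL) {
  df <- data.frame(resid = map$resid,
                   format(map$matrix, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("resid", map$resid)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
    graphics::image(map$resid, map$resid, map$matrix, zlim = c(-1, 1),
                    col = grDevices::hcl.colors(64, "Cyan-Magenta", rev = TRUE),
                    xlab = "residue", ylab = "residue",
                    main = "dynamic cross-correlation")
  }
  invisible(path)
}

#' Read a correlation map written by [write_dccm()]
#' @param path TSV path.
#' @return a `dccm_map`.
#' @export
read_dccm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  resid <- as.integer(df$resid)
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(resid, resid)
  structure(list(matrix = M, resid = resid), class = "dccm_map")
}
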