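#' @importFrom stats rnorm runif sd var median setNames
#' @importFrom utils read.table write.table head tail
NULL

# Atomic masses (amu) for the elements that occur in protein/RNA systems.
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06, SE = 78.971, FE = 55.845,
  MG = 24.305, ZN = 65.38, K = 39.098, NA. = 22.99, CL = 35.45
)

# Residue names recognised as nucleotides (sugar-phosphate backbone applies).
.NUC_RESNAMES <- c(
  "A", "C", "G", "U", "I", "T",
  "DA", "DC", "DG", "DT", "DI",
  "RA", "RC", "RG", "RU", "ADE", "CYT", "GUA", "URA", "THY"
)

# Backbone atom-name sets. Amino-acid backbone is the four mainchain heavy
# atoms; nucleotide backbone is the sugar-phosphate trace (O1P/O2P are the
# older aliases of OP1/OP2).
.AA_BACKBONE <- c("N", "CA", "C", "O")
.NUC_BACKBONE <- c(
  "P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
  "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'"
)

#' Construct an atom topology
#'
#' A topology is an ordered table of atoms: one row per atom, stable and
#' indexable, carrying the metadata selections and mass weighting need.
#' Residue numbers follow PDB author numbering so ranges quoted for the
#' SF3b system (e.g. residue 700 of SF3B1, p14 residues 20-100) can be
#' used verbatim.
#'
#' @param serial integer atom serial numbers.
#' @param name atom names (PDB convention, e.g. "CA", "OP1").
#' @param element element symbols; inferred from `name` where missing.
#' @param resname residue names (e.g. "LYS", "U").
#' @param resid residue numbers (author numbering, 1-based).
#' @param chain chain identifiers.
#' @param mass atomic masses in amu; looked up from `element` by default.
#' @return a `data.frame` of class `topology`.
#' @export
topology <- function(serial, name, element = NULL, resname, resid, chain,
                     mass = NULL) {
  if (is.null(element)) element <- infer_element(name)
  element <- toupper(element)
  if (is.null(mass)) {
    mass <- unname(.ATOMIC_MASS[element])
    mass[is.na(mass)] <- 12.011  # unknown elements weighted as carbon
  }
  # length-1 arguments recycle across atoms
  top <- data.frame(
    serial = as.integer(serial), name = as.character(name),
    element = element, mass = as.numeric(mass),
    resname = as.character(resname), resid = as.integer(resid),
    chain = as.character(chain), stringsAsFactors = FALSE
  )
  stopifnot(!anyNA(top$resid))
  key <- paste(top$chain, top$resid, top$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) after altloc resolution: ",
         key[duplicated(key)][1])
  }
  class(top) <- c("topology", "data.frame")
  top
}

#' Infer element symbols from PDB atom names
#'
#' First alphabetic character after any leading digits; hydrogens named
#' like "1HB" or "HG1" resolve to H.
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
infer_element <- function(name) {
  stripped <- gsub("^[0-9]+", "", name)
  first <- toupper(substr(stripped, 1, 1))
  first[first == ""] <- "C"
  first
}

#' Number of atoms in a topology
#' @param top a [topology()].
#' @export
n_atoms <- function(top) nrow(top)

#' Construct a trajectory
#'
#' Frames are a `T x N x 3` array of coordinates in nanometres with
#' strictly increasing timestamps in picoseconds, tied to the topology
#' that names the N atoms.
#'
#' @param coords numeric array `T x N x 3` (nm); a single `N x 3` matrix is
#'   promoted to one frame.
#' @param times numeric length-T timestamps (ps); defaults to `0:(T-1)`.
#' @param topology the matching [topology()].
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, times = NULL, topology) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[2] != n_atoms(topology)) {
    stop("frame atom count (", dim(coords)[2], ") does not match topology (",
         n_atoms(topology), ")")
  }
  if (!all(is.finite(coords))) stop("trajectory coordinates must be finite")
  tt <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(tt) - 1L)
  stopifnot(length(times) == tt)
  if (tt > 1 && any(diff(times) <= 0)) {
    stop("trajectory times must be strictly increasing")
  }
  structure(list(coords = coords, times = as.numeric(times),
                 topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$coords)[1], "frames x", dim(x$coords)[2],
      "atoms; t =", x$times[1], "...", x$times[length(x$times)], "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an N x 3 coordinate matrix (nm)
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @export
frame_coords <- function(traj, i = 1L) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records, resolves alternate locations (keeps blank
#' or 'A'), converts Angstrom coordinates to nanometres and assigns
#' masses from the element column (inferred from the atom name, with a
#' warning, when absent). Insertion codes are not supported and raise an
#' error; the SF3b model this package targets does not use them.
#'
#' @param path PDB file path.
#' @return list with `topology` and `coords` (N x 3 matrix, nm).
#' @export
read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("cannot parse PDB '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported (found at residue ",
         at$resno[which(!is.na(at$insert) & at$insert != "")[1]], ")")
  }
  elesy <- at$elesy
  missing_ele <- is.na(elesy) | elesy == ""
  if (any(missing_ele)) {
    warning("element column missing for ", sum(missing_ele),
            " atoms; inferring from atom names")
    elesy[missing_ele] <- infer_element(at$elety[missing_ele])
  }
  chain <- at$chain
  chain[is.na(chain)] <- " "
  top <- topology(serial = at$eleno, name = at$elety, element = elesy,
                  resname = at$resid, resid = at$resno, chain = chain)
  coords <- cbind(at$x, at$y, at$z) / 10  # Angstrom -> nm
  colnames(coords) <- c("x", "y", "z")
  list(topology = top, coords = coords)
}

#' Write a single-frame structure as PDB
#'
#' Coordinates are taken in nm and written in Angstrom.
#' @param top a [topology()].
#' @param coords N x 3 matrix in nm.
#' @param path output path.
#' @export
write_pdb <- function(top, coords, path) {
  stopifnot(nrow(coords) == n_atoms(top))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords * 10)),
    type = rep("ATOM", n_atoms(top)),
    resno = top$resid, resid = top$resname,
    eleno = top$serial, elety = top$name,
    chain = top$chain, elesy = top$element
  )
  invisible(path)
}

#' Write a trajectory as plain-text XYZ
#'
#' One block per frame: an atom-count line, a comment line carrying the
#' timestamp (`t= <ps>`), then one `name x y z` line per atom with
#' coordinates in nm. This text format is the package's portable
#' trajectory interchange.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param digits coordinate precision (significant digits).
#' @export
write_xyz <- function(traj, path, digits = 9) {
  con <- file(path, "w")
  on.exit(close(con))
  nat <- dim(traj$coords)[2]
  for (t in seq_len(n_frames(traj))) {
    writeLines(as.character(nat), con)
    writeLines(sprintf("t= %.6f", traj$times[t]), con)
    fr <- frame_coords(traj, t)
    writeLines(sprintf("%-4s %.*g %.*g %.*g", traj$topology$name,
                       digits, fr[, 1], digits, fr[, 2], digits, fr[, 3]),
               con)
  }
  invisible(path)
}

#' Read a plain-text XYZ trajectory
#'
#' @param path XYZ file path.
#' @param topology optional [topology()]; when given, the file's atom
#'   count must match and the returned trajectory is bound to it.
#' @return a [trajectory()] (with a minimal placeholder topology if none
#'   was supplied).
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty XYZ file: ", path)
  frames <- list(); times <- numeric(0); names_seen <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0) stop("bad atom-count line ", i, " in ", path)
    if (i + 1L + nat > length(lines)) {
      stop("truncated frame at line ", i, ": expected ", nat,
           " atom lines, file ends early")
    }
    tm <- sub("^.*t=\\s*", "", lines[i + 1L])
    tval <- suppressWarnings(as.numeric(tm))
    if (is.na(tval)) tval <- length(times)
    body <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad)) stop("malformed atom line ", i + 1L + bad[1], " in ", path)
    m <- matrix(as.numeric(vapply(parts, function(p) p[2:4], character(3))),
                ncol = 3, byrow = TRUE)
    if (anyNA(m)) stop("non-numeric coordinate in frame starting line ", i)
    frames[[length(frames) + 1L]] <- m
    times <- c(times, tval)
    if (is.null(names_seen)) names_seen <- vapply(parts, `[`, "", 1L)
    i <- i + 2L + nat
  }
  nat <- nrow(frames[[1]])
  if (!is.null(topology) && nat != n_atoms(topology)) {
    stop("XYZ atom count (", nat, ") does not match topology (",
         n_atoms(topology), ")")
  }
  if (is.null(topology)) {
    topology <- topology(serial = seq_len(nat), name = names_seen,
                         resname = "UNK", resid = seq_len(nat), chain = "A")
  }
  coords <- array(0, dim = c(length(frames), nat, 3))
  for (t in seq_along(frames)) coords[t, , ] <- frames[[t]]
  trajectory(coords, times, topology)
}

#' Read a trajectory file
#'
#' Dispatches on extension: `.dcd` (binary, via bio3d, Angstrom converted
#' to nm, times synthesized at a fixed stride) or `.xyz` (plain text, nm).
#' XTC is not supported and raises an informative error.
#'
#' @param path trajectory file.
#' @param topology the matching [topology()].
#' @param dt time step in ps used to synthesize times for formats that do
#'   not store them (DCD).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, topology, dt = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc") {
    stop("XTC reading is not supported; convert to DCD or the plain-text ",
         "XYZ interchange format")
  }
  if (ext == "dcd") {
    m <- bio3d::read.dcd(path, verbose = FALSE)  # T x 3N, Angstrom
    nat <- ncol(m) / 3
    if (nat != n_atoms(topology)) {
      stop("DCD atom count (", nat, ") does not match topology (",
           n_atoms(topology), ")")
    }
    coords <- array(0, dim = c(nrow(m), nat, 3))
    for (t in seq_len(nrow(m))) {
      coords[t, , ] <- matrix(m[t, ], ncol = 3, byrow = TRUE) / 10
    }
    return(trajectory(coords, (seq_len(nrow(m)) - 1) * dt, topology))
  }
  if (ext == "xyz") return(read_xyz(path, topology))
  stop("unrecognised trajectory format: '", ext, "'")
}

#' Declare an atom selection
#'
#' Declarative predicate over a topology: optional chain set, optional
#' inclusive residue range, and an atom class. Classes: `all`, `heavy`
#' (non-hydrogen), `calpha` (CA atoms), `backbone` (N/CA/C/O for amino
#' acids, sugar-phosphate names for nucleotides), `sidechain` (the
#' complement of the backbone within each residue, hydrogens included
#' when present).
#'
#' @param chain character vector of chain ids, or NULL for all.
#' @param resid `c(lo, hi)` inclusive residue range, or NULL for all.
#' @param class one of `"all"`, `"heavy"`, `"calpha"`, `"backbone"`,
#'   `"sidechain"`.
#' @export
atom_selection <- function(chain = NULL, resid = NULL, class = "all") {
  class <- match.arg(class, c("all", "heavy", "calpha", "backbone",
                              "sidechain"))
  if (!is.null(resid)) {
    stopifnot(length(resid) == 2L, resid[1] <= resid[2])
    resid <- as.integer(resid)
  }
  structure(list(chain = chain, resid = resid, class = class),
            class = "atom_selection")
}

#' Parse a selection string
#'
#' Grammar: `chain <ids>`, `resid <lo>-<hi>` (or a single number), and an
#' atom-class keyword, joined by optional `and`. Examples:
#' `"chain B and resid 20-100 and sidechain"`, `"calpha"`,
#' `"resid 700 and sidechain"`.
#'
#' @param text selection string.
#' @return an [atom_selection()].
#' @export
parse_selection <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[tolower(toks) != "and"]
  chain <- NULL; resid <- NULL; cls <- "all"
  i <- 1L
  while (i <= length(toks)) {
    tk <- tolower(toks[i])
    if (tk == "chain") {
      j <- i + 1L
      ids <- character(0)
      while (j <= length(toks) &&
             !tolower(toks[j]) %in% c("chain", "resid", "all", "heavy",
                                      "calpha", "backbone", "sidechain")) {
        ids <- c(ids, toks[j]); j <- j + 1L
      }
      if (!length(ids)) stop("selection: 'chain' needs at least one id")
      chain <- ids; i <- j
    } else if (tk == "resid") {
      if (i + 1L > length(toks)) stop("selection: 'resid' needs a range")
      rng <- strsplit(toks[i + 1L], "-")[[1]]
      lo <- suppressWarnings(as.integer(rng[1]))
      hi <- if (length(rng) > 1) suppressWarnings(as.integer(rng[2])) else lo
      if (anyNA(c(lo, hi))) stop("selection: bad resid range '",
                                 toks[i + 1L], "'")
      resid <- c(lo, hi); i <- i + 2L
    } else if (tk %in% c("all", "heavy", "calpha", "backbone", "sidechain")) {
      cls <- tk; i <- i + 1L
    } else {
      stop("selection: unrecognised token '", toks[i], "'")
    }
  }
  atom_selection(chain = chain, resid = resid, class = cls)
}

#' Resolve a selection to atom indices
#'
#' Pure function of (topology, selection); returns a sorted,
#' duplicate-free 1-based index vector. An empty resolution warns and
#' returns `integer(0)` — the caller decides whether that is an error.
#'
#' @param top a [topology()].
#' @param sel an [atom_selection()] or a selection string.
#' @export
select_atoms <- function(top, sel) {
  if (is.character(sel)) sel <- parse_selection(sel)
  stopifnot(inherits(sel, "atom_selection"))
  keep <- rep(TRUE, n_atoms(top))
  if (!is.null(sel$chain)) keep <- keep & top$chain %in% sel$chain
  if (!is.null(sel$resid)) {
    keep <- keep & top$resid >= sel$resid[1] & top$resid <= sel$resid[2]
  }
  is_nuc <- toupper(top$resname) %in% .NUC_RESNAMES
  is_bb <- ifelse(is_nuc, top$name %in% .NUC_BACKBONE,
                  top$name %in% .AA_BACKBONE)
  keep <- keep & switch(sel$class,
    all = TRUE,
    heavy = top$element != "H",
    calpha = top$name == "CA",
    backbone = is_bb,
    sidechain = !is_bb
  )
  idx <- which(keep)
  if (!length(idx)) warning("selection resolved to zero atoms")
  sort(unique(idx))
}
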