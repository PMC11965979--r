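#' @importFrom stats approx dist optimize rnorm runif sd setNames integrate
#' @importFrom utils read.table write.table write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Core molecular data model: Structure, Trajectory, AtomSelection,
# Kearsley superposition and per-frame RMSD series.
# ---------------------------------------------------------------------------

#' Create a Structure from an atom table
#'
#' A `Structure` is an ordered atom table (serial, name, residue name,
#' author residue number, chain, insertion code, element, occupancy,
#' B-factor) plus an n x 3 coordinate matrix in Angstrom.  Atom order is
#' stable: selections index into this order.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `resid`, `chain`, and optionally `icode`, `element`, `occ`, `b`.
#' @param coords numeric matrix, n_atoms x 3, Angstrom.
#' @param metadata free-form named list.
#' @return object of class `Structure`.
#' @export
structure_model <- function(atoms, coords, metadata = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(nrow(atoms) == nrow(coords), ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates in Structure")
  for (col in c("icode", "element")) if (is.null(atoms[[col]])) atoms[[col]] <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$chain)) atoms$chain <- "A"
  atoms$element <- ifelse(is.na(atoms$element) | atoms$element == "",
                          guess_element(atoms$name), atoms$element)
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, coords = coords, metadata = metadata)
  class(out) <- "Structure"
  out
}

guess_element <- function(name) {
  el <- sub("^[0-9]*", "", trimws(name))
  el <- substr(el, 1, 1)
  bad <- !el %in% c("C", "N", "O", "S", "H", "P", "F", "B", "I", "K")
  if (any(bad)) {
    warning("could not infer element for atom name(s): ",
            paste(unique(name[bad]), collapse = ", "))
    el[bad] <- "X"
  }
  el
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues\n")
  invisible(x)
}

#' Number of atoms in a Structure or Trajectory topology
#' @param x Structure or Trajectory
#' @return integer
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Read a PDB file into a Structure
#'
#' Parsing is delegated to [bio3d::read.pdb()]; on top of it the loader
#' validates ATOM/HETATM records up front (naming the first malformed
#' line), resolves alternate locations to the highest-occupancy copy and
#' records insertion codes.  Atom order is preserved.
#'
#' @param path PDB file path.
#' @return `Structure`.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed PDB record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed PDB record at line ", i, ": bad coordinate field")
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(serial = a$eleno, name = a$elety, resname = a$resid,
                      resid = a$resno, chain = ifelse(is.na(a$chain), "A", a$chain),
                      icode = ifelse(is.na(a$insert), "", a$insert),
                      element = ifelse(is.na(a$elesy), "", a$elesy),
                      occ = ifelse(is.na(a$o), 1, a$o),
                      b = ifelse(is.na(a$b), 0, a$b),
                      alt = ifelse(is.na(a$alt), "", a$alt),
                      stringsAsFactors = FALSE)
  coords <- cbind(a$x, a$y, a$z)
  # altloc: keep the highest-occupancy copy of each atom site
  key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$name)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[order(-atoms$occ[idx], atoms$alt[idx])][1]
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms <- atoms[keep, , drop = FALSE]
  coords <- coords[keep, , drop = FALSE]
  atoms$alt <- NULL
  structure_model(atoms, coords, metadata = list(source = path))
}

#' Write a Structure to a PDB file
#'
#' @param s Structure.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(s$coords)),
                   type = rep("ATOM", nrow(a)), eleno = a$serial,
                   elety = a$name, resid = a$resname, resno = a$resid,
                   chain = a$chain, insert = ifelse(a$icode == "", NA, a$icode),
                   o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}

#' Create a Trajectory
#'
#' Ordered frames over one shared topology.  Every frame must have the
#' topology's atom count; times, when given, must be strictly
#' increasing.
#'
#' @param topology Structure.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param times optional numeric vector of per-frame times (ps).
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "Structure"))
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != nrow(topology$atoms) || ncol(f) != 3)
      stop("frame dimensions do not match topology")
    f
  })
  if (!is.null(times)) {
    if (length(times) != length(frames)) stop("times/frames length mismatch")
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  }
  out <- list(topology = topology, frames = frames, times = times)
  class(out) <- "Trajectory"
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames x", n_atoms(x), "atoms\n")
  invisible(x)
}

#' Number of frames
#' @param traj Trajectory
#' @return integer
#' @export
n_frames <- function(traj) length(traj$frames)

#' Read / write a multi-frame XYZ trajectory
#'
#' Plain XYZ: per frame an atom count line, a comment line (parsed for
#' `t=<time>` when present), then `element x y z` rows.
#'
#' @param path file path.
#' @param topology optional Structure; when omitted a minimal topology is
#'   synthesized from the element column.
#' @return `Trajectory`.
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(0); i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("bad XYZ atom-count line ", i)
    comment <- lines[i + 1]
    tm <- regmatches(comment, regexpr("t= ?[-0-9.eE+]+", comment))
    if (length(tm)) times <- c(times, as.numeric(sub("t= ?", "", tm)))
    rows <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(topology)) {
      el <- vapply(parts, `[`, "", 1)
      topology <- structure_model(
        data.frame(serial = seq_len(n), name = el, resname = "UNK",
                   resid = seq_len(n), chain = "A", element = el),
        co)
    }
    frames[[length(frames) + 1]] <- co
    i <- i + 2 + n
  }
  trajectory(topology, frames,
             times = if (length(times) == length(frames)) times else NULL)
}

#' @rdname read_xyz
#' @param traj Trajectory to write.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  el <- traj$topology$atoms$element
  for (k in seq_along(traj$frames)) {
    cat(n_atoms(traj), "\n", file = con, sep = "")
    tm <- if (!is.null(traj$times)) sprintf(" t=%.6f", traj$times[k]) else ""
    cat(sprintf("frame %d%s\n", k, tm), file = con)
    f <- traj$frames[[k]]
    cat(sprintf("%s %.6f %.6f %.6f\n", el, f[, 1], f[, 2], f[, 3]),
        file = con, sep = "")
  }
  invisible(path)
}

#' Read a DCD trajectory (thin wrapper)
#'
#' @param path DCD file; @param topology Structure for the atom table.
#' @return `Trajectory`.
#' @export
read_dcd_trajectory <- function(path, topology) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  frames <- lapply(seq_len(nrow(xyz)),
                   function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  trajectory(topology, frames)
}

# ---------------------------------------------------------------------------
# Atom selection mini-grammar: `name`, `resid` (ranges / comma lists),
# `chain`, combined with `and` / `or`.  `and` binds tighter than `or`.
# ---------------------------------------------------------------------------

#' Select atoms with a small query grammar
#'
#' Supported terms: `name CA CB`, `resid 8-14,57-66` (inclusive author
#' numbering, ranges and comma lists), `chain A`; terms combine with
#' `and` and `or` (`and` binds tighter).  The result preserves atom
#' order.  A query matching nothing yields an empty selection with a
#' warning, not an error.
#'
#' @param s Structure (or Trajectory, whose topology is used).
#' @param query selection string.
#' @param label optional label stored on the selection.
#' @return object of class `AtomSelection`: list with 1-based `indices`
#'   and `label`.
#' @examples
#' \dontrun{select_atoms(s, "name CA and resid 8-14")}
#' @export
select_atoms <- function(s, query, label = query) {
  if (inherits(s, "Trajectory")) s <- s$topology
  atoms <- s$atoms
  match_term <- function(term) {
    toks <- strsplit(trimws(term), "[[:space:]]+")[[1]]
    if (length(toks) < 2) stop("bad selection term: '", term, "'")
    key <- toks[1]; vals <- paste(toks[-1], collapse = ",")
    switch(key,
      name = atoms$name %in% strsplit(vals, ",")[[1]],
      chain = atoms$chain %in% strsplit(vals, ",")[[1]],
      resid = {
        hit <- rep(FALSE, nrow(atoms))
        for (piece in strsplit(vals, ",")[[1]]) {
          rng <- as.integer(strsplit(piece, "-")[[1]])
          if (any(is.na(rng))) stop("bad resid term: '", piece, "'")
          hit <- hit | (atoms$resid >= rng[1] & atoms$resid <= rng[length(rng)])
        }
        hit
      },
      stop("unknown selection keyword: '", key, "'"))
  }
  hit <- rep(FALSE, nrow(atoms))
  for (disjunct in strsplit(query, "[[:space:]]+or[[:space:]]+")[[1]]) {
    sub <- rep(TRUE, nrow(atoms))
    for (term in strsplit(disjunct, "[[:space:]]+and[[:space:]]+")[[1]])
      sub <- sub & match_term(term)
    hit <- hit | sub
  }
  idx <- which(hit)
  if (length(idx) == 0) warning("selection '", query, "' matched no atoms")
  atom_selection(idx, label)
}

#' Build an AtomSelection from explicit indices
#' @param indices 1-based atom indices (unique, in range when applied).
#' @param label string.
#' @return `AtomSelection`.
#' @export
atom_selection <- function(indices, label = "selection") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  out <- list(indices = indices, label = label)
  class(out) <- "AtomSelection"
  out
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat("AtomSelection '", x$label, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

#' @export
length.AtomSelection <- function(x) length(x$indices)

# ---------------------------------------------------------------------------
# Kearsley quaternion superposition.
# ---------------------------------------------------------------------------

#' Optimal rigid-body superposition (Kearsley's quaternion method)
#'
#' Finds the proper rotation and translation minimizing the (weighted)
#' RMSD between `mobile` and `reference`, via the eigendecomposition of
#' Kearsley's 4 x 4 quaternion matrix: the smallest eigenvalue is the
#' residual sum of squares, its eigenvector the optimal rotation.  The
#' quaternion parameterization yields a proper rotation (det = +1)
#' natively, with no reflection case to repair.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, paired rows.
#' @param weights optional non-negative per-point weights.
#' @return `SuperpositionResult`: list with `rotation` (3 x 3, applied to
#'   mobile row-vectors as `x %*% t(R)`), `translation` (so that
#'   `mobile %*% t(R) + translation` best matches reference) and `rmsd`
#'   (Angstrom).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  m <- as.matrix(mobile); r <- as.matrix(reference)
  if (nrow(m) != nrow(r) || ncol(m) != 3 || ncol(r) != 3)
    stop("mobile/reference must be matched n x 3 matrices")
  n <- nrow(m)
  if (n < 3) stop("superposition needs at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) stop("bad weights")
  wn <- w / sum(w)
  cm <- colSums(m * wn); cr <- colSums(r * wn)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  # degenerate geometry: effectively collinear point sets
  sv <- svd(sqrt(wn) * mc)$d
  if (sv[2] < 1e-10 * max(sv[1], 1e-30) && svd(sqrt(wn) * rc)$d[2] < 1e-10)
    stop("degenerate (collinear) geometry in superposition")
  p <- mc + rc; q <- mc - rc   # 'plus' and 'minus' coordinates
  W <- w
  S <- function(a, b) sum(W * a * b)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S(q[, 1], q[, 1]) + S(q[, 2], q[, 2]) + S(q[, 3], q[, 3])
  K[1, 2] <- K[2, 1] <- S(p[, 2], q[, 3]) - S(q[, 2], p[, 3])
  K[1, 3] <- K[3, 1] <- S(q[, 1], p[, 3]) - S(p[, 1], q[, 3])
  K[1, 4] <- K[4, 1] <- S(p[, 1], q[, 2]) - S(q[, 1], p[, 2])
  K[2, 2] <- S(p[, 2], p[, 2]) + S(p[, 3], p[, 3]) + S(q[, 1], q[, 1])
  K[2, 3] <- K[3, 2] <- S(q[, 1], q[, 2]) - S(p[, 1], p[, 2])
  K[2, 4] <- K[4, 2] <- S(q[, 1], q[, 3]) - S(p[, 1], p[, 3])
  K[3, 3] <- S(p[, 1], p[, 1]) + S(p[, 3], p[, 3]) + S(q[, 2], q[, 2])
  K[3, 4] <- K[4, 3] <- S(q[, 2], q[, 3]) - S(p[, 2], p[, 3])
  K[4, 4] <- S(p[, 1], p[, 1]) + S(p[, 2], p[, 2]) + S(q[, 3], q[, 3])
  e <- eigen(K, symmetric = TRUE)
  qv <- e$vectors[, 4]
  q0 <- qv[1]; q1 <- qv[2]; q2 <- qv[3]; q3 <- qv[4]
  R <- matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 + q2^2 - q1^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 + q3^2 - q1^2 - q2^2),
    3, 3, byrow = TRUE)
  tr <- as.numeric(cr - R %*% cm)
  # post-fit rmsd from the applied transform (more accurate than the
  # smallest eigenvalue near zero residual)
  moved <- sweep(m %*% t(R), 2, tr, `+`)
  rmsd <- sqrt(sum(wn * rowSums((moved - r)^2)))
  out <- list(rotation = R, translation = tr, rmsd = rmsd)
  class(out) <- "SuperpositionResult"
  out
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup SuperpositionResult.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' RMSD between two coordinate sets after optimal superposition
#' @param a,b n x 3 matrices.
#' @param weights optional.
#' @return RMSD in Angstrom.
#' @export
fit_rmsd <- function(a, b, weights = NULL) superpose(a, b, weights)$rmsd

#' Per-frame RMSD series against a reference structure
#'
#' Each frame is superposed on the reference over `sel_fit`; the RMSD is
#' then measured over `sel_measure` (defaults to the fit selection).
#'
#' @param traj Trajectory.
#' @param ref Structure.
#' @param sel_fit AtomSelection used for fitting.
#' @param sel_measure AtomSelection used for measurement.
#' @return numeric vector of per-frame RMSD (Angstrom).
#' @export
rmsd_series <- function(traj, ref, sel_fit, sel_measure = sel_fit) {
  fi <- sel_fit$indices; mi <- sel_measure$indices
  na <- n_atoms(traj)
  if (max(fi, mi) > na || max(fi, mi) > nrow(ref$atoms))
    stop("selection out of range for trajectory or reference")
  rf <- ref$coords[fi, , drop = FALSE]
  rm_ <- ref$coords[mi, , drop = FALSE]
  vapply(traj$frames, function(f) {
    sup <- superpose(f[fi, , drop = FALSE], rf)
    moved <- apply_superposition(sup, f[mi, , drop = FALSE])
    sqrt(mean(rowSums((moved - rm_)^2)))
  }, numeric(1))
}
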