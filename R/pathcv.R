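# ---------------------------------------------------------------------------
# Path collective variables.
#
# A configuration R is located relative to a reference path of N reduced
# representations X(l) by two functions:
#
#   s(R) = (1/(N-1)) * sum_i (i-1) exp(-lambda d_i) / sum_i exp(-lambda d_i)
#   z(R) = -(1/lambda) * ln sum_i exp(-lambda d_i)
#
# where d_i is the SQUARED metric distance to path frame i: the
# mean-squared deviation after optimal (Kearsley) superposition for the
# coordinate metric, or the summed squared contact-map difference for
# the contact metric.  s is the progress along the path in [0, 1]; z the
# distance from it in squared-metric units.
# ---------------------------------------------------------------------------

#' Contact definitions for the contact-map metric
#'
#' Each contact is a rational switching function of the inter-atomic
#' distance r: `C = (1-(r/r0)^n) / (1-(r/r0)^m)`, 1 at r = 0, 1/2 at
#' r = r0 for the default exponents, decaying to 0 at large r.  `r0` is
#' the typical distance at which the contact is formed.
#'
#' @param atom_i,atom_j 1-based atom indices.
#' @param r0 contact distance, Angstrom.
#' @param n,m positive integer exponents, m > n (defaults 6 and 12).
#' @return data.frame of class `ContactDefinition`.
#' @export
contact_definition <- function(atom_i, atom_j, r0, n = 6L, m = 12L) {
  d <- data.frame(atom_i = as.integer(atom_i), atom_j = as.integer(atom_j),
                  r0 = r0, n = as.integer(n), m = as.integer(m))
  if (any(d$r0 <= 0)) stop("r0 must be positive")
  if (any(d$m <= d$n)) stop("exponent m must exceed n")
  class(d) <- c("ContactDefinition", "data.frame")
  d
}

#' Rational contact switching function
#'
#' `(1 - (r/r0)^n) / (1 - (r/r0)^m)` with the removable singularity at
#' r = r0 evaluated by its limit n/m.  Total function of r >= 0.
#'
#' @param r distance(s), Angstrom.
#' @param r0 contact distance; @param n,m exponents (m > n).
#' @param deriv if TRUE also return the derivative dC/dr.
#' @return numeric vector of contact values in (0, 1], or a list
#'   `(value, deriv)` when `deriv = TRUE`.
#' @export
contact_value <- function(r, r0, n = 6L, m = 12L, deriv = FALSE) {
  t <- pmax(r / r0, 0)
  v <- numeric(length(t)); dv <- numeric(length(t))
  # 1 - t^k = -expm1(k log t): accurate through the removable
  # singularity at t = 1; exact-limit branch only at t ~ 1 to machine
  # precision
  L <- ifelse(t > 0, log(t), -Inf)
  at_one <- abs(t - 1) < 1e-12
  A <- -expm1(n * L)                  # 1 - t^n
  B <- -expm1(m * L)                  # 1 - t^m
  v <- ifelse(at_one, n / m, A / B)
  v[t == 0] <- 1
  if (deriv) {
    dv <- ifelse(at_one, -n * (m - n) / (2 * m),
                 (-n * t^(n - 1) * B + A * m * t^(m - 1)) / B^2)
    return(list(value = v, deriv = dv / r0))
  }
  v
}

#' Construct a reference path
#'
#' @param frames list of reduced representations: k x 3 coordinate
#'   matrices (coordinate-RMSD metric) or contact-value vectors
#'   (contact-map metric).  N >= 2, all of one dimensionality.
#' @param metric `"rmsd"` or `"cmap"`.
#' @param lambda smoothing parameter of the path functions (1/Angstrom^2
#'   for the coordinate metric, dimensionless for the contact metric);
#'   if `NULL` it is calibrated from the path spacing, see
#'   [calibrate_lambda()].
#' @param contacts `ContactDefinition` table (contact metric only).
#' @param align_selection AtomSelection giving, for full-coordinate
#'   inputs, the atoms forming the reduced representation (coordinate
#'   metric only; `NULL` means frames are already reduced).
#' @param is_extra logical vector flagging non-physical terminal frames.
#' @return object of class `ReferencePath`.
#' @export
reference_path <- function(frames, metric = c("rmsd", "cmap"), lambda = NULL,
                           contacts = NULL, align_selection = NULL,
                           is_extra = rep(FALSE, length(frames))) {
  metric <- match.arg(metric)
  if (length(frames) < 2) stop("a path needs at least 2 frames")
  if (metric == "rmsd") {
    frames <- lapply(frames, as.matrix)
    dims <- vapply(frames, nrow, integer(1))
  } else {
    if (is.null(contacts)) stop("contact metric requires a contacts table")
    frames <- lapply(frames, as.numeric)
    dims <- vapply(frames, length, integer(1))
    if (any(dims != nrow(contacts)))
      stop("contact-map frames must match the contacts table length")
    if (any(unlist(frames) < -1e-9 | unlist(frames) > 1 + 1e-9))
      stop("contact values must lie in [0, 1]")
  }
  if (length(unique(dims)) != 1) stop("path frames differ in dimensionality")
  out <- list(metric = metric, frames = frames, lambda = lambda,
              contacts = contacts, align_selection = align_selection,
              is_extra = is_extra)
  class(out) <- "ReferencePath"
  if (is.null(lambda)) out$lambda <- calibrate_lambda(validate_spacing(out))
  if (out$lambda <= 0) stop("lambda must be positive")
  out
}

#' @export
print.ReferencePath <- function(x, ...) {
  cat(sprintf("ReferencePath: %d frames (%d real), metric %s, lambda %.4g\n",
              length(x$frames), sum(!x$is_extra), x$metric, x$lambda))
  invisible(x)
}

#' Reduce full coordinates to the path's representation
#'
#' Coordinate metric: rows of the alignment selection.  Contact metric:
#' the vector of switched contact values over the contact table.
#'
#' @param coords full n x 3 coordinate matrix (or a Structure).
#' @param path ReferencePath.
#' @return k x 3 matrix or contact vector.
#' @export
reduce_representation <- function(coords, path) {
  if (inherits(coords, "Structure")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (path$metric == "rmsd") {
    idx <- if (!is.null(path$align_selection)) path$align_selection$indices
           else seq_len(nrow(path$frames[[1]]))
    if (max(idx) > nrow(coords)) stop("coordinates missing atoms used by the path")
    coords[idx, , drop = FALSE]
  } else {
    cd <- path$contacts
    if (max(cd$atom_i, cd$atom_j) > nrow(coords))
      stop("coordinates missing atoms used by the contact table")
    dvec <- sqrt(rowSums((coords[cd$atom_i, , drop = FALSE] -
                          coords[cd$atom_j, , drop = FALSE])^2))
    contact_value(dvec, cd$r0, cd$n, cd$m)
  }
}

# squared metric distances d_i from reduced representation `x` to every
# path frame; optionally the gradient of each d_i w.r.t. the full
# coordinates (rotation held fixed at its optimum for the rmsd metric,
# whose first-order contribution vanishes there)
path_distances <- function(x_red, path, coords = NULL, gradient = FALSE) {
  N <- length(path$frames)
  if (path$metric == "rmsd") {
    k <- nrow(x_red)
    d <- numeric(N)
    grads <- if (gradient) vector("list", N)
    for (i in seq_len(N)) {
      sup <- superpose(path$frames[[i]], x_red)
      al <- apply_superposition(sup, path$frames[[i]])
      diff <- x_red - al
      d[i] <- mean(rowSums(diff^2))
      if (gradient) grads[[i]] <- (2 / k) * diff
    }
    list(d = d, grads = if (gradient) grads)
  } else {
    d <- vapply(path$frames, function(f) sum((x_red - f)^2), numeric(1))
    grads <- NULL
    if (gradient) {
      cd <- path$contacts
      cw <- contact_value(sqrt(rowSums((coords[cd$atom_i, , drop = FALSE] -
                                        coords[cd$atom_j, , drop = FALSE])^2)),
                          cd$r0, cd$n, cd$m, deriv = TRUE)
      rij <- coords[cd$atom_i, , drop = FALSE] - coords[cd$atom_j, , drop = FALSE]
      rlen <- sqrt(rowSums(rij^2))
      unit <- rij / pmax(rlen, 1e-12)
      grads <- vector("list", N)
      for (i in seq_len(N)) {
        coef <- 2 * (x_red - path$frames[[i]]) * cw$deriv  # d d_i / d r_p
        g <- matrix(0, nrow(coords), 3)
        contrib <- coef * unit
        for (ax in 1:3) {
          g[, ax] <- g[, ax] +
            tapply_add(contrib[, ax], cd$atom_i, nrow(coords)) -
            tapply_add(contrib[, ax], cd$atom_j, nrow(coords))
        }
        grads[[i]] <- g
      }
    }
    list(d = d, grads = grads)
  }
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Evaluate the path collective variables s and z
#'
#' Computes progress `s` in [0, 1] and distance `z` (squared-metric
#' units) of a configuration relative to a reference path, with optional
#' gradients with respect to the full atomic coordinates.  The kernel
#' sums are evaluated in log-space so large `lambda * d` cannot
#' overflow.
#'
#' @param coords full coordinate matrix (or Structure) for the rmsd
#'   metric with an alignment selection / the contact metric; or an
#'   already-reduced representation.
#' @param path ReferencePath.
#' @param gradient if TRUE, return `ds_dx` and `dz_dx` (n x 3 matrices
#'   over the full coordinates).
#' @return list of class `CVValue`: `s`, `z`, optionally `ds_dx`,
#'   `dz_dx`, plus the per-frame squared distances `d`.
#' @export
evaluate_path_cv <- function(coords, path, gradient = FALSE) {
  if (inherits(coords, "Structure")) coords <- coords$coords
  coords <- as.matrix(coords)
  full <- coords
  x_red <- reduce_representation(coords, path)
  N <- length(path$frames)
  if (N < 2) stop("a path needs at least 2 frames")
  pd <- path_distances(x_red, path, coords = full, gradient = gradient)
  lam <- path$lambda
  lw <- -lam * pd$d
  M <- max(lw)
  w <- exp(lw - M)           # stabilized weights
  S0 <- sum(w)
  S1 <- sum((seq_len(N) - 1) * w)
  s <- S1 / ((N - 1) * S0)
  z <- -(M + log(S0)) / lam
  out <- list(s = s, z = z, d = pd$d)
  if (gradient) {
    # ds/dd_i = (lambda w_i / S0) (s - (i-1)/(N-1));  dz/dd_i = w_i / S0
    ds_dd <- (lam * w / S0) * (s - (seq_len(N) - 1) / (N - 1))
    dz_dd <- w / S0
    nfull <- nrow(full)
    ds <- matrix(0, nfull, 3); dz <- matrix(0, nfull, 3)
    if (path$metric == "rmsd") {
      idx <- if (!is.null(path$align_selection)) path$align_selection$indices
             else seq_len(nrow(x_red))
      for (i in seq_len(N)) {
        ds[idx, ] <- ds[idx, ] + ds_dd[i] * pd$grads[[i]]
        dz[idx, ] <- dz[idx, ] + dz_dd[i] * pd$grads[[i]]
      }
    } else {
      for (i in seq_len(N)) {
        ds <- ds + ds_dd[i] * pd$grads[[i]]
        dz <- dz + dz_dd[i] * pd$grads[[i]]
      }
    }
    out$ds_dx <- ds; out$dz_dx <- dz
  }
  class(out) <- "CVValue"
  out
}

#' Inter-frame spacing diagnostics for a reference path
#'
#' Reports the successive inter-frame metric distances (RMSD in Angstrom
#' for the coordinate metric; the summed squared contact difference for
#' the contact metric, i.e. the quantity entering the exponent), their
#' mean and coefficient of variation.  A path is considered equally
#' spaced when cv <= 0.25; otherwise a warning attribute is set.
#' Terminal extra (non-physical) frames are included in the distance
#' list but the count of real frames is reported separately.
#'
#' @param path ReferencePath (N >= 3 for a meaningful cv).
#' @return list of class `PathDiagnostics`: `interframe_distances`,
#'   `mean`, `cv`, `metric`, `n_real`, `equally_spaced`.
#' @export
validate_spacing <- function(path) {
  N <- length(path$frames)
  d <- vapply(seq_len(N - 1), function(i) {
    if (path$metric == "rmsd")
      fit_rmsd(path$frames[[i + 1]], path$frames[[i]])
    else
      sum((path$frames[[i + 1]] - path$frames[[i]])^2)
  }, numeric(1))
  m <- mean(d)
  cv <- if (m > 0) sd(d) / m else 0
  out <- list(interframe_distances = d, mean = m, cv = cv,
              metric = path$metric, n_real = sum(!path$is_extra),
              equally_spaced = cv <= 0.25)
  if (!out$equally_spaced)
    warning(sprintf("path spacing uneven: cv = %.2f > 0.25", cv))
  class(out) <- "PathDiagnostics"
  out
}

#' @export
print.PathDiagnostics <- function(x, ...) {
  cat(sprintf("PathDiagnostics (%s): mean inter-frame distance %.4g, cv %.3f%s\n",
              x$metric, x$mean, x$cv,
              if (x$equally_spaced) "" else "  [UNEVEN]"))
  invisible(x)
}

#' Calibrate the path smoothing parameter lambda
#'
#' Default rule `lambda = 2.3 / mean(d)` where `d` is the quantity that
#' enters the exponential kernel: the mean summed squared contact
#' difference for the contact metric, the mean squared inter-frame RMSD
#' for the coordinate metric.  The rule reproduces published
#' contact-metric settings closely; coordinate-metric values from the
#' literature do not follow a single rule and should be supplied
#' explicitly, which always overrides calibration.
#'
#' @param diag PathDiagnostics.
#' @return lambda (1/Angstrom^2 or dimensionless).
#' @export
calibrate_lambda <- function(diag) {
  m <- if (diag$metric == "rmsd") mean(diag$interframe_distances^2)
       else diag$mean
  if (m <= 0) stop("cannot calibrate lambda: zero mean inter-frame distance")
  2.3 / m
}

#' Build a reference path from a transition trajectory
#'
#' Picks `n_frames` frames approximately equidistant in the chosen
#' metric by greedy equal-arc-length selection along the trajectory,
#' then prepends and appends one terminal extra (non-physical) frame
#' each, linearly extrapolated with the same inter-frame step, giving a
#' path of `n_frames + 2` frames.
#'
#' @param traj Trajectory spanning the transition.
#' @param n_frames number of real frames to extract (>= 2).
#' @param metric `"rmsd"` or `"cmap"`.
#' @param align_selection AtomSelection defining the reduced
#'   representation (rmsd metric; default all atoms).
#' @param contacts ContactDefinition table (cmap metric).
#' @param lambda optional explicit lambda; calibrated from the final
#'   spacing when omitted.
#' @return `ReferencePath` with `n_frames + 2` frames.
#' @export
build_path <- function(traj, n_frames, metric = c("rmsd", "cmap"),
                       align_selection = NULL, contacts = NULL,
                       lambda = NULL) {
  metric <- match.arg(metric)
  nf <- n_frames(traj)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (nf < n_frames) stop("trajectory shorter than requested frame count")
  reduced <- lapply(traj$frames, function(f) {
    if (metric == "rmsd") {
      idx <- if (!is.null(align_selection)) align_selection$indices
             else seq_len(nrow(f))
      f[idx, , drop = FALSE]
    } else {
      dvec <- sqrt(rowSums((f[contacts$atom_i, , drop = FALSE] -
                            f[contacts$atom_j, , drop = FALSE])^2))
      contact_value(dvec, contacts$r0, contacts$n, contacts$m)
    }
  })
  step_dist <- function(a, b) {
    if (metric == "rmsd") fit_rmsd(b, a) else sqrt(sum((b - a)^2))
  }
  arc <- c(0, cumsum(vapply(seq_len(nf - 1), function(i)
    step_dist(reduced[[i]], reduced[[i + 1]]), numeric(1))))
  targets <- seq(0, arc[nf], length.out = n_frames)
  pick <- integer(n_frames)
  last <- 0L
  for (k in seq_len(n_frames)) {
    cand <- which.min(abs(arc - targets[k]))
    pick[k] <- max(cand, last + 1L)  # keep strictly increasing
    last <- pick[k]
  }
  sel <- reduced[pick]
  if (metric == "rmsd") {
    # align each frame onto its predecessor so extrapolation is internal
    for (k in 2:n_frames) {
      sup <- superpose(sel[[k]], sel[[k - 1]])
      sel[[k]] <- apply_superposition(sup, sel[[k]])
    }
    first <- sel[[1]] - (sel[[2]] - sel[[1]])
    lastf <- sel[[n_frames]] + (sel[[n_frames]] - sel[[n_frames - 1]])
  } else {
    first <- pmin(pmax(sel[[1]] - (sel[[2]] - sel[[1]]), 0), 1)
    lastf <- pmin(pmax(sel[[n_frames]] + (sel[[n_frames]] - sel[[n_frames - 1]]), 0), 1)
  }
  frames <- c(list(first), sel, list(lastf))
  # the path's reduced frames are stored as-is; full-coordinate inputs are
  # reduced at evaluation time through align_selection / contacts
  reference_path(frames, metric = metric, lambda = lambda,
                 contacts = contacts, align_selection = align_selection,
                 is_extra = c(TRUE, rep(FALSE, n_frames), TRUE))
}

#' Save / load a path archive
#'
#' A directory holding numbered frame files (`frame_###.pdb` via a bead
#' topology for the coordinate metric, `frame_###.csv` contact vectors
#' for the contact metric), a `contacts.tsv` table when applicable, and
#' a `path.yml` descriptor with metric, lambda and extra-frame flags.
#'
#' @param path ReferencePath; @param dir directory to create.
#' @param topology optional Structure for writing PDB frames; a minimal
#'   carbon-bead topology is synthesized when omitted.
#' @return `dir`, invisibly.
#' @export
save_path_archive <- function(path, dir, topology = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  desc <- list(metric = path$metric, lambda = path$lambda,
               n_frames = length(path$frames),
               is_extra = as.logical(path$is_extra))
  yaml::write_yaml(desc, file.path(dir, "path.yml"))
  if (path$metric == "rmsd") {
    for (k in seq_along(path$frames)) {
      f <- path$frames[[k]]
      topo <- topology %||% structure_model(
        data.frame(serial = seq_len(nrow(f)), name = "CA", resname = "GLY",
                   resid = seq_len(nrow(f)), chain = "A", element = "C"), f)
      s <- structure_model(topo$atoms, f)
      write_structure(s, file.path(dir, sprintf("frame_%03d.pdb", k)))
    }
  } else {
    write.table(path$contacts, file.path(dir, "contacts.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    for (k in seq_along(path$frames))
      write.table(data.frame(value = path$frames[[k]]),
                  file.path(dir, sprintf("frame_%03d.csv", k)),
                  sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname save_path_archive
#' @export
load_path_archive <- function(dir) {
  desc <- yaml::read_yaml(file.path(dir, "path.yml"))
  n <- desc$n_frames
  if (desc$metric == "rmsd") {
    frames <- lapply(seq_len(n), function(k)
      load_structure(file.path(dir, sprintf("frame_%03d.pdb", k)))$coords)
    contacts <- NULL
  } else {
    ct <- read.table(file.path(dir, "contacts.tsv"), header = TRUE, sep = "\t")
    contacts <- contact_definition(ct$atom_i, ct$atom_j, ct$r0, ct$n, ct$m)
    frames <- lapply(seq_len(n), function(k)
      read.table(file.path(dir, sprintf("frame_%03d.csv", k)),
                 header = TRUE, sep = ",")$value)
  }
  reference_path(frames, metric = desc$metric, lambda = desc$lambda,
                 contacts = contacts,
                 is_extra = as.logical(desc$is_extra))
}
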