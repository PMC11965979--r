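# ---------------------------------------------------------------------------
# Descriptive trajectory statistics: dynamical cross-correlation of
# C-alpha fluctuations, region RMSD summaries, inter-atomic distance
# probes (ionic locks) and interaction occupancy.
# ---------------------------------------------------------------------------

#' Dynamical cross-correlation matrix of atomic fluctuations
#'
#' Pearson correlation of per-atom positional deviations.  For 3-vector
#' displacements the standard dynamical cross-correlation form is used:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, which keeps
#' `C_ii = 1` and `C_ij` in [-1, 1].  Atoms are the rows of `sel`;
#' frames are optionally superposed (2 rounds of iterative fitting onto
#' the running average structure) before deviations are measured.
#'
#' @param traj Trajectory (>= 10 frames).
#' @param sel AtomSelection of the atoms to correlate (e.g. C-alpha).
#' @param fit logical: superpose frames before measuring fluctuations
#'   (default TRUE; disable for pre-aligned or synthetic input).
#' @param fit_sel AtomSelection used for the fit (default `sel`).
#' @return object of class `CorrelationMatrix`: `values` (n x n),
#'   `labels` (residue ids).  Zero-variance atoms give NA rows/columns.
#' @export
pearson_matrix <- function(traj, sel, fit = TRUE, fit_sel = sel) {
  nf <- n_frames(traj)
  if (nf < 10) stop("need at least 10 frames")
  idx <- sel$indices
  n <- length(idx)
  X <- t(vapply(traj$frames, function(f) as.numeric(t(f[idx, , drop = FALSE])),
                numeric(3 * n)))
  if (fit) {
    fidx <- fit_sel$indices
    F3 <- lapply(traj$frames, function(f) f[fidx, , drop = FALSE])
    ref <- F3[[1]]
    for (round in 1:2) {
      fitted <- lapply(seq_len(nf), function(k) {
        sup <- superpose(F3[[k]], ref)
        list(sup = sup, co = apply_superposition(sup, F3[[k]]))
      })
      ref <- Reduce(`+`, lapply(fitted, `[[`, "co")) / nf
      X <- t(vapply(seq_len(nf), function(k) {
        as.numeric(t(apply_superposition(fitted[[k]]$sup,
                                         traj$frames[[k]][idx, , drop = FALSE])))
      }, numeric(3 * n)))
    }
  }
  Xc <- scale(X, scale = FALSE)
  G <- crossprod(Xc) / nf                      # 3n x 3n covariance
  ax <- rep(seq_len(n), each = 3)
  # sum the 3x3 block diagonals: num[i,j] = sum_axes G[3i-3+a, 3j-3+a]
  num <- matrix(0, n, n)
  for (a in 1:3) {
    ia <- seq(a, 3 * n, by = 3)
    num <- num + G[ia, ia]
  }
  v <- diag(num)
  zero <- v <= 1e-12
  denom <- sqrt(outer(v, v))
  C <- num / denom
  C[zero, ] <- NA; C[, zero] <- NA
  diag(C)[!zero] <- 1
  labels <- traj$topology$atoms$resid[idx]
  dimnames(C) <- list(labels, labels)
  out <- list(values = C, labels = labels)
  class(out) <- "CorrelationMatrix"
  out
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("CorrelationMatrix:", nrow(x$values), "x", ncol(x$values), "atoms\n")
  invisible(x)
}

#' Classify correlated / anti-correlated pairs
#'
#' Pairs with `|C| > threshold` (default 0.5, the conventional cutoff
#' for "correlated spots") are reported.
#'
#' @param cm CorrelationMatrix; @param threshold |C| cutoff.
#' @return data.frame (i, j, value, kind).
#' @export
correlated_pairs <- function(cm, threshold = 0.5) {
  C <- cm$values
  ut <- upper.tri(C)
  hit <- which(ut & !is.na(C) & abs(C) > threshold, arr.ind = TRUE)
  data.frame(i = cm$labels[hit[, 1]], j = cm$labels[hit[, 2]],
             value = C[hit],
             kind = ifelse(C[hit] > 0, "correlated", "anti-correlated"))
}

#' Built-in receptor region definitions
#'
#' Author-numbered residue ranges of the orthosteric binding site (OBS),
#' connector and intracellular binding site (IBS) regions of the
#' adenosine A2A receptor (UniProt P29274 numbering).
#'
#' @return named list of two-column range matrices.
#' @export
region_definitions <- function() {
  list(
    OBS = rbind(c(8, 14), c(57, 66), c(75, 90), c(132, 140), c(175, 187),
                c(245, 258), c(267, 278)),
    connector = rbind(c(15, 23), c(50, 56), c(91, 97), c(127, 131),
                      c(188, 197), c(236, 244), c(279, 283)),
    IBS = rbind(c(24, 31), c(42, 49), c(98, 106), c(119, 126), c(198, 208),
                c(222, 235), c(283, 287)))
}

region_query <- function(ranges, atom = "CA") {
  paste0("name ", atom, " and resid ",
         paste(sprintf("%d-%d", ranges[, 1], ranges[, 2]), collapse = ","))
}

#' Region RMSD series with summary
#'
#' C-alpha RMSD of a region after fitting each frame on a core
#' selection (default: all C-alpha atoms), reported per frame plus the
#' conventional mean +/- sd summary.
#'
#' @param traj Trajectory; @param ref Structure.
#' @param region two-column matrix of residue ranges, a region name from
#'   [region_definitions()], or an AtomSelection.
#' @param fit_sel AtomSelection to fit on (default all C-alpha).
#' @return list of class `RegionRMSD`: `series`, `mean`, `sd`, `label`.
#' @export
region_rmsd <- function(traj, ref, region, fit_sel = NULL) {
  if (is.character(region)) {
    label <- region
    region <- region_definitions()[[region]]
    if (is.null(region)) stop("unknown region name: ", label)
  } else label <- "region"
  sel <- if (inherits(region, "AtomSelection")) region
         else select_atoms(traj, region_query(region), label = label)
  if (length(sel) == 0) stop("region resolves to no atoms")
  want <- unique(traj$topology$atoms$resid[sel$indices])
  if (inherits(region, "matrix")) {
    expect <- unlist(lapply(seq_len(nrow(region)),
                            function(i) region[i, 1]:region[i, 2]))
    missing <- setdiff(intersect(expect, traj$topology$atoms$resid), want)
    if (length(missing))
      stop("region residues missing from topology: ",
           paste(missing, collapse = ", "))
  }
  fit_sel <- fit_sel %||% select_atoms(traj, "name CA", label = "core")
  series <- rmsd_series(traj, ref, fit_sel, sel)
  out <- list(series = series, mean = mean(series), sd = sd(series),
              label = label)
  class(out) <- "RegionRMSD"
  out
}

#' @export
print.RegionRMSD <- function(x, ...) {
  cat(sprintf("%s RMSD: %.2f +/- %.2f A over %d frames\n",
              x$label, x$mean, x$sd, length(x$series)))
  invisible(x)
}

#' Define a distance probe
#'
#' A labelled pair of atoms given as (residue number, atom name), e.g.
#' the activating ionic lock AIL = E228:CG -- R205:CZ or the
#' inactivating ionic lock IIL = E228:CG -- R102:CZ.
#'
#' @param label string; @param resid_a,name_a,resid_b,name_b atom specs.
#' @return list of class `DistanceProbe`.
#' @export
distance_probe <- function(label, resid_a, name_a, resid_b, name_b) {
  out <- list(label = label, a = list(resid = resid_a, name = name_a),
              b = list(resid = resid_b, name = name_b))
  class(out) <- "DistanceProbe"
  out
}

resolve_atom <- function(topology, spec, probe_label) {
  i <- which(topology$atoms$resid == spec$resid & topology$atoms$name == spec$name)
  if (length(i) != 1)
    stop("probe '", probe_label, "': cannot resolve atom ", spec$resid, ":",
         spec$name)
  i
}

#' Per-frame probe distances
#'
#' Euclidean inter-atomic distances, no fitting (internal distances are
#' frame-invariant under rigid motion).
#'
#' @param traj Trajectory; @param probes list of [distance_probe()]s.
#' @return data.frame: frame, time, one column per probe (Angstrom).
#' @export
probe_distances <- function(traj, probes) {
  if (inherits(probes, "DistanceProbe")) probes <- list(probes)
  cols <- lapply(probes, function(p) {
    ia <- resolve_atom(traj$topology, p$a, p$label)
    ib <- resolve_atom(traj$topology, p$b, p$label)
    vapply(traj$frames, function(f) sqrt(sum((f[ia, ] - f[ib, ])^2)),
           numeric(1))
  })
  names(cols) <- vapply(probes, `[[`, "", "label")
  out <- data.frame(frame = seq_len(n_frames(traj)),
                    time = traj$times %||% seq_len(n_frames(traj)))
  cbind(out, as.data.frame(cols))
}

#' Interaction occupancy of a distance series
#'
#' Fraction of frames in which the distance is at or below the cutoff
#' (default 4.5 Angstrom, the conventional side-chain salt-bridge
#' criterion).
#'
#' @param series numeric distance series, Angstrom; @param cutoff Angstrom.
#' @return list of class `OccupancySeries`: `formed` (per-frame
#'   logical), `frequency`.
#' @export
occupancy <- function(series, cutoff = 4.5) {
  if (length(series) == 0) stop("empty distance series")
  if (cutoff <= 0) stop("cutoff must be positive")
  formed <- series <= cutoff
  out <- list(formed = formed, frequency = mean(formed))
  class(out) <- "OccupancySeries"
  out
}

#' @export
print.OccupancySeries <- function(x, ...) {
  cat(sprintf("Occupancy: %.1f%% of %d frames\n", 100 * x$frequency,
              length(x$formed)))
  invisible(x)
}
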