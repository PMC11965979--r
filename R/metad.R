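# ---------------------------------------------------------------------------
# Well-tempered metadynamics bookkeeping.
#
# A history-dependent bias V_G(S, t) is grown by depositing Gaussian
# kernels on the collective variables S; in the well-tempered variant
# the height of each new kernel is damped by the bias already present,
#   W = w0 * exp(-V_G(S, t) / (kB * dT)),   dT = (gamma - 1) * T,
# so the total bias converges to -(dT/(dT+T)) F(S) and the free energy
# is recovered as F(S) = -(gamma/(gamma-1)) V_G(S).
# ---------------------------------------------------------------------------

#' Well-tempered metadynamics parameters
#'
#' @param height initial Gaussian height w0*tauG, kcal/mol.
#' @param stride deposition stride, ps.
#' @param bias_factor bias factor gamma = (T + dT)/T, > 1 (default 15).
#' @param temperature system temperature, K (default 300).
#' @param widths Gaussian widths, one per collective variable (CV units).
#' @return object of class `WTParams` (includes derived `delta_t`).
#' @export
wt_params <- function(height = 0.95, stride = 1, bias_factor = 15,
                      temperature = 300, widths = 0.1) {
  if (bias_factor <= 1) stop("bias factor must exceed 1")
  if (any(widths <= 0)) stop("Gaussian widths must be positive")
  if (height <= 0) stop("initial height must be positive")
  out <- list(height = height, stride = stride, bias_factor = bias_factor,
              temperature = temperature, widths = as.numeric(widths),
              delta_t = (bias_factor - 1) * temperature)
  class(out) <- "WTParams"
  out
}

#' Create an (initially empty) bias state
#'
#' Kernels are stored as parallel arrays ordered by deposition step;
#' heights never exceed the initial height.
#'
#' @param params WTParams.
#' @param d number of collective variables.
#' @return object of class `BiasState`.
#' @export
bias_state <- function(params, d = length(params$widths)) {
  out <- list(centers = matrix(numeric(0), 0, d), heights = numeric(0),
              widths = matrix(numeric(0), 0, d), steps = integer(0),
              times = numeric(0), params = params, d = d)
  class(out) <- "BiasState"
  out
}

#' @export
print.BiasState <- function(x, ...) {
  cat(sprintf("BiasState: %d kernels over %d CV(s), gamma = %g\n",
              length(x$heights), x$d, x$params$bias_factor))
  invisible(x)
}

#' Append one Gaussian kernel to a bias state
#' @param state BiasState; @param center CV vector; @param height kcal/mol;
#' @param step integer deposition step; @param time ps.
#' @return updated BiasState.
#' @export
add_kernel <- function(state, center, height, step = length(state$heights) + 1L,
                       time = NA_real_) {
  if (height <= 0) stop("kernel height must be positive")
  if (height > state$params$height + 1e-12)
    stop("kernel height exceeds the initial height")
  state$centers <- rbind(state$centers, matrix(center, 1))
  state$heights <- c(state$heights, height)
  state$widths <- rbind(state$widths, matrix(state$params$widths, 1))
  state$steps <- c(state$steps, as.integer(step))
  state$times <- c(state$times, time)
  state
}

#' Evaluate the accumulated bias at a point
#'
#' Sum over kernels of `W * exp(-sum(delta^2 / (2 sigma^2)))`.  Kernels
#' farther than 6 sigma in any CV are skipped (relative error < 1e-8).
#'
#' @param state BiasState; @param point CV vector.
#' @param n_kernels evaluate only the first `n_kernels` kernels
#'   (truncated-bias reconstructions); default all.
#' @return bias, kcal/mol (0 for an empty state).
#' @export
bias_value <- function(state, point, n_kernels = length(state$heights)) {
  if (n_kernels == 0) return(0)
  ctr <- state$centers[seq_len(n_kernels), , drop = FALSE]
  wid <- state$widths[seq_len(n_kernels), , drop = FALSE]
  h <- state$heights[seq_len(n_kernels)]
  if (length(point) != ncol(ctr)) stop("point dimensionality mismatch")
  keep <- rep(TRUE, n_kernels)
  e2 <- numeric(n_kernels)
  for (j in seq_len(ncol(ctr))) {
    dj <- (point[j] - ctr[, j]) / wid[, j]
    keep <- keep & abs(dj) <= 6
    e2 <- e2 + 0.5 * dj^2
  }
  sum(h[keep] * exp(-e2[keep]))
}

#' Well-tempered height of the next kernel
#'
#' `W = w0 * exp(-v_here / (kB * dT))` with `dT = (gamma - 1) * T`: the
#' more bias already deposited at the current point, the smaller the new
#' kernel.  In the gamma -> Inf limit the height is constant (standard
#' metadynamics).
#'
#' @param params WTParams; @param v_here bias already present, kcal/mol.
#' @return height, kcal/mol.
#' @export
next_height <- function(params, v_here) {
  if (v_here < 0) stop("accumulated bias must be non-negative")
  if (!is.finite(params$delta_t)) return(params$height)
  params$height * exp(-v_here / (KB_KCAL * params$delta_t))
}

#' Regular CV grid specification
#' @param min,max per-CV bounds; @param n points per CV.
#' @return grid spec list.
#' @export
grid_spec <- function(min, max, n) {
  stopifnot(length(min) == length(max), all(max > min), all(n >= 2))
  list(min = min, max = max, n = as.integer(n))
}

grid_axes <- function(gs) {
  lapply(seq_along(gs$min), function(j) seq(gs$min[j], gs$max[j],
                                            length.out = gs$n[j]))
}

# evaluate total bias on a regular grid (1D or 2D)
bias_on_grid <- function(state, gs, n_kernels = length(state$heights)) {
  axes <- grid_axes(gs)
  d <- length(axes)
  if (d == 1) {
    v <- numeric(length(axes[[1]]))
    for (k in seq_len(n_kernels)) {
      dx <- (axes[[1]] - state$centers[k, 1]) / state$widths[k, 1]
      idx <- abs(dx) <= 6
      v[idx] <- v[idx] + state$heights[k] * exp(-0.5 * dx[idx]^2)
    }
    list(axes = axes, values = v)
  } else if (d == 2) {
    v <- matrix(0, length(axes[[1]]), length(axes[[2]]))
    for (k in seq_len(n_kernels)) {
      dx <- (axes[[1]] - state$centers[k, 1]) / state$widths[k, 1]
      dy <- (axes[[2]] - state$centers[k, 2]) / state$widths[k, 2]
      ix <- which(abs(dx) <= 6); iy <- which(abs(dy) <= 6)
      if (length(ix) && length(iy))
        v[ix, iy] <- v[ix, iy] + state$heights[k] *
          exp(-0.5 * dx[ix]^2) %o% exp(-0.5 * dy[iy]^2)
    }
    list(axes = axes, values = v)
  } else stop("grids supported in 1 or 2 dimensions")
}

#' Free-energy surface from the deposited bias
#'
#' `F(S) = -((dT + T)/dT) V_G(S) = -(gamma/(gamma-1)) V_G(S)` on a
#' regular grid, zeroed at its minimum.  With gamma = 15 the prefactor
#' is 15/14.
#'
#' @param state BiasState with at least one kernel.
#' @param gs grid spec from [grid_spec()].
#' @param n_kernels optionally truncate the kernel list (convergence
#'   checks).
#' @return object of class `FESGrid` (`axes`, `values` kcal/mol).
#' @export
fes_from_bias <- function(state, gs, n_kernels = length(state$heights)) {
  if (length(state$heights) == 0) stop("empty bias state")
  g <- bias_on_grid(state, gs, n_kernels)
  gam <- state$params$bias_factor
  vals <- -(gam / (gam - 1)) * g$values
  vals <- vals - min(vals)
  out <- list(axes = g$axes, values = vals)
  class(out) <- "FESGrid"
  out
}

#' @export
print.FESGrid <- function(x, ...) {
  cat(sprintf("FESGrid: %s points, range 0 - %.3f kcal/mol\n",
              paste(vapply(x$axes, length, integer(1)), collapse = " x "),
              max(x$values)))
  invisible(x)
}

#' Basin free energy of a region of an FES
#'
#' `G = -kB T ln sum_region exp(-F/kBT)`, the Boltzmann-weighted free
#' energy of all grid points inside the region.
#'
#' @param fes FESGrid (1D); @param range c(lo, hi) on the CV axis;
#' @param temperature K.
#' @return kcal/mol (NA when no grid point falls in the region).
#' @export
basin_free_energy <- function(fes, range, temperature = 300) {
  x <- fes$axes[[1]]
  idx <- x >= range[1] & x <= range[2]
  if (!any(idx)) return(NA_real_)
  bt <- KB_KCAL * temperature
  -bt * logsumexp(-fes$values[idx] / bt)
}

#' Acceleration factor of a metadynamics run
#'
#' `alpha = exp(delta_f / (kB T))`: the boost the bias gives the slowest
#' barrier crossing, from the free-energy difference between the lowest
#' minimum and the highest transition state.
#'
#' @param delta_f barrier, kcal/mol (>= 0); @param temperature K.
#' @return dimensionless factor.
#' @export
estimate_boost <- function(delta_f, temperature = 300) {
  if (delta_f < 0) stop("delta_f must be non-negative")
  exp(delta_f / (KB_KCAL * temperature))
}

#' Reweight biased samples onto an arbitrary collective variable
#'
#' Implements the time-dependent-offset scheme: each sample at time t is
#' weighted proportionally to `exp((V(s_t, t) - c(t)) / kBT)` where
#' `V(s_t, t)` is the instantaneous bias felt by the sample and `c(t)`
#' is the offset computed from the evolving bias on the deposition
#' grid,
#'   `c(t) = (1/beta) ln( int e^{beta g V/(g-1)} / int e^{beta V/(g-1)} )`,
#' with g the bias factor.  The weighted histogram of the target CV is
#' converted to a free energy and zeroed at its minimum.
#'
#' @param samples data.frame with column `time` (ps), one column per
#'   biased CV (in the order of the bias state), and column `bias`
#'   giving the instantaneous bias energy of the frame, kcal/mol.
#' @param target numeric vector: the (possibly auxiliary) CV the free
#'   energy is requested on, aligned with `samples` rows.
#' @param state BiasState that generated the bias.
#' @param gs 1D grid spec for the output free energy.
#' @param bias_grid grid spec over the *biased* CVs used to evaluate
#'   c(t); defaults to `gs` (valid when target is the biased CV).
#' @param temperature K.
#' @return `FESGrid` on the target CV.
#' @export
reweight <- function(samples, target, state, gs, bias_grid = NULL,
                     temperature = state$params$temperature) {
  if (nrow(samples) == 0) stop("no samples to reweight")
  bt <- KB_KCAL * temperature
  gam <- state$params$bias_factor
  nk <- length(state$heights)
  if (nk > 0) {
    bg <- bias_grid %||% gs
    # evolving c(t) at each kernel deposition time
    g <- bias_on_grid(state, bg, 0)
    v <- as.numeric(g$values)
    ct <- numeric(nk)
    axes <- g$axes
    for (k in seq_len(nk)) {
      if (length(axes) == 1) {
        dx <- (axes[[1]] - state$centers[k, 1]) / state$widths[k, 1]
        idx <- abs(dx) <= 6
        v[idx] <- v[idx] + state$heights[k] * exp(-0.5 * dx[idx]^2)
      } else {
        stop("c(t) evaluation supported for one biased CV")
      }
      ct[k] <- bt * (logsumexp(gam * v / ((gam - 1) * bt)) -
                     logsumexp(v / ((gam - 1) * bt)))
    }
    c_of_t <- approx(state$times, ct, xout = samples$time, rule = 2)$y
  } else {
    c_of_t <- 0
  }
  logw <- (samples$bias - c_of_t) / bt
  logw <- logw - max(logw)
  w <- exp(logw)
  if (all(w == 0)) stop("all reweighting weights are zero")
  ax <- grid_axes(gs)[[1]]
  edges <- c(ax[1] - diff(ax[1:2]) / 2,
             ax + c(diff(ax) / 2, diff(ax)[length(ax) - 1] / 2))
  bin <- findInterval(target, edges, all.inside = TRUE)
  hist <- tapply_add(w, bin, length(ax))
  fe <- ifelse(hist > 0, -bt * log(hist), Inf)
  fe <- fe - min(fe)
  out <- list(axes = list(ax), values = fe)
  class(out) <- "FESGrid"
  out
}

#' Free-energy convergence profile between two basins
#'
#' Recomputes the basin-to-basin free-energy difference from the bias
#' truncated at each checkpoint time; convergence is declared when the
#' drift over the final 20% of checkpoints is below `tol`.
#'
#' @param state BiasState; @param basin_a,basin_b c(lo, hi) CV ranges;
#' @param checkpoints times, ps (>= 2); @param gs 1D grid spec;
#' @param tol drift tolerance, kcal/mol (default 0.5).
#' @return data.frame (time, delta_g) with attribute `converged`.
#' @export
convergence_profile <- function(state, basin_a, basin_b, checkpoints, gs,
                                tol = 0.5) {
  if (length(checkpoints) < 2) stop("need at least 2 checkpoints")
  temp <- state$params$temperature
  dg <- vapply(checkpoints, function(tc) {
    nk <- sum(state$times <= tc)
    if (nk == 0) return(NA_real_)
    fes <- fes_from_bias(state, gs, n_kernels = nk)
    ga <- basin_free_energy(fes, basin_a, temp)
    gb <- basin_free_energy(fes, basin_b, temp)
    gb - ga
  }, numeric(1))
  out <- data.frame(time = checkpoints, delta_g = dg)
  tail_n <- max(2L, ceiling(0.2 * length(dg)))
  tail_dg <- tail(dg[!is.na(dg)], tail_n)
  attr(out, "converged") <- length(tail_dg) >= 2 &&
    (max(tail_dg) - min(tail_dg)) < tol
  out
}

# ---------------------------------------------------------------------------
# HILLS-style log and gnuplot-style FES table.
# ---------------------------------------------------------------------------

#' Write / read a HILLS-style kernel log
#'
#' One row per kernel: time, center(s), width(s), height, bias factor;
#' full precision so the state replays bit-exactly.
#'
#' @param state BiasState; @param path file.
#' @param cv_names names of the CVs for the header.
#' @return `path`, invisibly.
#' @export
write_hills <- function(state, path, cv_names = paste0("cv", seq_len(state$d))) {
  con <- file(path, "w"); on.exit(close(con))
  cat("#! FIELDS time", cv_names, paste0("sigma_", cv_names), "height biasf\n",
      file = con)
  nk <- length(state$heights)
  for (k in seq_len(nk)) {
    cat(sprintf("%.17g", c(state$times[k], state$centers[k, ],
                           state$widths[k, ], state$heights[k],
                           state$params$bias_factor)),
        file = con, sep = " ")
    cat("\n", file = con)
  }
  invisible(path)
}

#' @rdname write_hills
#' @param params WTParams used to rebuild the state.
#' @export
read_hills <- function(path, params) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  state <- bias_state(params)
  d <- state$d
  for (i in seq_along(lines)) {
    v <- as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]])
    state$centers <- rbind(state$centers, matrix(v[2:(1 + d)], 1))
    state$widths <- rbind(state$widths, matrix(v[(2 + d):(1 + 2 * d)], 1))
    state$heights <- c(state$heights, v[2 + 2 * d])
    state$times <- c(state$times, v[1])
    state$steps <- c(state$steps, i)
  }
  state
}

#' Write an FES grid as a whitespace-delimited table
#' @param fes FESGrid; @param path file.
#' @return `path`, invisibly.
#' @export
write_fes <- function(fes, path) {
  if (length(fes$axes) == 1) {
    df <- data.frame(cv1 = fes$axes[[1]], free_energy = fes$values)
  } else {
    gr <- expand.grid(cv1 = fes$axes[[1]], cv2 = fes$axes[[2]])
    df <- cbind(gr, free_energy = as.numeric(fes$values))
  }
  write.table(format(df, digits = 10), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
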