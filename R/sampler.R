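# ---------------------------------------------------------------------------
# Langevin dynamics over pluggable energy models (BAOAB splitting), with
# optional well-tempered metadynamics, steered (moving harmonic)
# restraints and one-sided harmonic walls.  Units: Angstrom, kcal/mol,
# ps, amu.  All randomness flows through one generator seeded per run.
# ---------------------------------------------------------------------------

#' Define an energy model
#'
#' @param fun function(x) returning `list(energy, grad)` in kcal/mol and
#'   kcal/mol/A over a configuration vector `x`.
#' @param d dimensionality of the configuration vector.
#' @param kind `"vector"` for generic coordinates or `"atoms"` when `x`
#'   is a flattened n x 3 coordinate set.
#' @param meta free-form metadata (e.g. analytic reference values).
#' @return object of class `EnergyModel`.
#' @export
energy_model <- function(fun, d, kind = c("vector", "atoms"), meta = list()) {
  kind <- match.arg(kind)
  out <- list(fun = fun, d = as.integer(d), kind = kind, meta = meta)
  class(out) <- "EnergyModel"
  out
}

#' Check a model gradient against central finite differences
#' @param model EnergyModel; @param x configuration; @param h step.
#' @return max relative error.
#' @export
check_gradient <- function(model, x, h = 1e-5) {
  g <- model$fun(x)$grad
  fd <- vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (model$fun(xp)$energy - model$fun(xm)$energy) / (2 * h)
  }, numeric(1))
  max(abs(fd - g) / pmax(abs(g), 1e-8))
}

#' Langevin integration parameters
#'
#' @param temperature K; @param friction 1/ps; @param timestep ps;
#' @param n_steps number of steps; @param seed mandatory RNG seed;
#' @param mass amu, scalar or per-coordinate.
#' @return object of class `LangevinParams`.
#' @export
langevin_params <- function(temperature = 300, friction = 5, timestep = 0.01,
                            n_steps = 10000, seed, mass = 40) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (timestep <= 0) stop("timestep must be positive")
  out <- list(temperature = temperature, friction = friction,
              timestep = timestep, n_steps = as.integer(n_steps),
              seed = as.integer(seed), mass = mass)
  class(out) <- "LangevinParams"
  out
}

#' Collective-variable object
#'
#' @param fun function(x) returning `list(value, grad)` over the model
#'   configuration vector.
#' @param label string.
#' @return object of class `CV`.
#' @export
make_cv <- function(fun, label = "cv") {
  out <- list(fun = fun, label = label)
  class(out) <- "CV"
  out
}

#' CV selecting one coordinate of the configuration vector
#' @param index coordinate index; @param d model dimensionality.
#' @return `CV`.
#' @export
coordinate_cv <- function(index, d) {
  g <- numeric(d); g[index] <- 1
  make_cv(function(x) list(value = x[index], grad = g),
          label = paste0("x", index))
}

#' Path-CV (s or z) over a flattened atoms-kind configuration
#' @param path ReferencePath; @param which `"s"` or `"z"`;
#' @param n_atoms_total atoms in the model configuration.
#' @return `CV`.
#' @export
path_cv <- function(path, which = c("s", "z"), n_atoms_total) {
  which <- match.arg(which)
  make_cv(function(x) {
    co <- matrix(x, n_atoms_total, 3, byrow = TRUE)
    ev <- evaluate_path_cv(co, path, gradient = TRUE)
    gm <- if (which == "s") ev$ds_dx else ev$dz_dx
    list(value = ev[[which]], grad = as.numeric(t(gm)))
  }, label = paste0("path_", which))
}

#' CV measuring RMSD to a target conformation
#' @param target k x 3 coordinates; @param indices atom indices measured;
#' @param n_atoms_total atoms in the configuration.
#' @return `CV`.
#' @export
rmsd_cv <- function(target, indices = seq_len(nrow(target)), n_atoms_total) {
  target <- as.matrix(target)
  k <- length(indices)
  make_cv(function(x) {
    co <- matrix(x, n_atoms_total, 3, byrow = TRUE)[indices, , drop = FALSE]
    sup <- superpose(target, co)
    al <- apply_superposition(sup, target)
    diff <- co - al
    r <- sqrt(mean(rowSums(diff^2)))
    gm3 <- diff / (k * max(r, 1e-12))
    g <- numeric(3 * n_atoms_total)
    g[rep((indices - 1) * 3, each = 3) + rep(1:3, k)] <- as.numeric(t(gm3))
    list(value = r, grad = g)
  }, label = "rmsd")
}

#' One-sided harmonic wall on a collective variable
#'
#' Applies `k/2 (cv - threshold)^2` only beyond the threshold (above for
#' `side = "upper"`, below for `"lower"`).
#'
#' @param cv `CV` object, or an integer index into the run's CV list.
#' @param threshold CV units; @param k kcal/mol/unit^2; @param side
#'   `"upper"` or `"lower"`.
#' @return object of class `WallRestraint`.
#' @export
wall_restraint <- function(cv, threshold, k, side = c("upper", "lower")) {
  side <- match.arg(side)
  if (k < 0) stop("wall spring constant must be non-negative")
  out <- list(cv = cv, threshold = threshold, k = k, side = side)
  class(out) <- "WallRestraint"
  out
}

#' Moving-harmonic (steered) restraint schedule
#'
#' Restraint `V(t) = kappa(t)/2 (cv - s0(t))^2` with spring constant and
#' target both piecewise-linear in time between knots.
#'
#' @param cv `CV` object (or integer index into the run's CV list).
#' @param kappa data.frame (time, value): spring, kcal/mol/unit^2; a
#'   single number means constant.
#' @param target data.frame (time, value): moving target s0(t).
#' @param duration ps; the schedule must cover [0, duration].
#' @return object of class `SteeredSchedule`.
#' @export
steered_schedule <- function(cv, kappa, target, duration) {
  as_knots <- function(v) {
    if (is.data.frame(v)) v else data.frame(time = c(0, duration), value = v)
  }
  kappa <- as_knots(kappa); target <- as_knots(target)
  if (any(kappa$value < 0)) stop("kappa must be non-negative")
  for (kn in list(kappa, target))
    if (min(kn$time) > 0 || max(kn$time) < duration)
      stop("schedule knots must cover [0, duration]")
  out <- list(cv = cv, kappa = kappa, target = target, duration = duration)
  class(out) <- "SteeredSchedule"
  out
}

# piecewise-linear interpolation and its time-derivative at t
sched_interp <- function(knots, t) {
  approx(knots$time, knots$value, xout = t, rule = 2)$y
}
sched_slope <- function(knots, t) {
  i <- findInterval(t, knots$time, all.inside = TRUE)
  (knots$value[i + 1] - knots$value[i]) /
    (knots$time[i + 1] - knots$time[i])
}

# --------------------------------------------------------------------------
# The integrator.  One engine serves plain Langevin, metadynamics and
# steered runs; hot path kept allocation-light.
# --------------------------------------------------------------------------

run_dynamics <- function(model, params, x0, cvs = list(), wt = NULL,
                         gs = NULL, steered = NULL, walls = list(),
                         record_stride = 10L) {
  set.seed(params$seed)
  d <- model$d
  x <- as.numeric(x0)
  if (length(x) != d) stop("x0 does not match model dimensionality")
  dt <- params$timestep
  m <- if (length(params$mass) == 1) rep(params$mass, d) else params$mass
  c1 <- exp(-params$friction * dt)
  c2 <- sqrt(1 - c1^2)
  sv <- sqrt(ACC_FACTOR * KB_KCAL * params$temperature / m)
  ncv <- length(cvs)
  cv_funs <- lapply(cvs, `[[`, "fun")

  metad_on <- !is.null(wt)
  if (metad_on) {
    if (ncv == 0) stop("metadynamics requires at least one CV")
    if (length(wt$widths) != ncv) stop("one Gaussian width per CV required")
    if (is.null(gs)) stop("metadynamics requires a CV grid spec")
    axes <- grid_axes(gs)
    if (ncv == 1) {
      ax1 <- axes[[1]]; ng1 <- length(ax1)
      dx1 <- ax1[2] - ax1[1]; lo1 <- ax1[1]
      Vg <- numeric(ng1); dVg1 <- numeric(ng1)
    } else if (ncv == 2) {
      ax1 <- axes[[1]]; ax2 <- axes[[2]]
      ng1 <- length(ax1); ng2 <- length(ax2)
      dx1 <- ax1[2] - ax1[1]; lo1 <- ax1[1]
      dx2 <- ax2[2] - ax2[1]; lo2 <- ax2[1]
      Vg <- matrix(0, ng1, ng2)
      dVg1 <- matrix(0, ng1, ng2); dVg2 <- matrix(0, ng1, ng2)
    } else stop("metadynamics supported on 1 or 2 CVs")
    stride_steps <- max(1L, as.integer(round(wt$stride / dt)))
    max_k <- params$n_steps %/% stride_steps + 1L
    k_centers <- matrix(NA_real_, max_k, ncv)
    k_heights <- numeric(max_k); k_steps <- integer(max_k)
    k_times <- numeric(max_k); nk <- 0L
    sig <- wt$widths
    damp <- KB_KCAL * wt$delta_t
  }

  steer_on <- !is.null(steered)
  if (steer_on) {
    st_cv <- steered$cv
    st_fun <- if (inherits(st_cv, "CV")) st_cv$fun else NULL
    work <- 0
  }
  wall_funs <- lapply(walls, function(w)
    if (inherits(w$cv, "CV")) w$cv$fun else NULL)

  nrec <- params$n_steps %/% record_stride
  rec_x <- matrix(NA_real_, nrec, d)
  rec_cv <- if (ncv) matrix(NA_real_, nrec, ncv)
  rec_bias <- numeric(nrec); rec_e <- numeric(nrec)
  rec_t <- numeric(nrec); rec_w <- if (steer_on) numeric(nrec)
  irec <- 0L

  cvv <- numeric(max(ncv, 1))
  cvg <- vector("list", max(ncv, 1))

  total_force <- function(x, t) {
    me <- model$fun(x)
    f <- -me$grad
    e <- me$energy
    b <- 0
    if (ncv) for (j in seq_len(ncv)) {
      ev <- cv_funs[[j]](x)
      cvv[j] <<- ev$value
      cvg[[j]] <<- ev$grad
    }
    if (metad_on) {
      if (ncv == 1) {
        gi <- min(max(as.integer(round((cvv[1] - lo1) / dx1)) + 1L, 1L), ng1)
        b <- Vg[gi]
        f <- f - dVg1[gi] * cvg[[1]]
      } else {
        gi <- min(max(as.integer(round((cvv[1] - lo1) / dx1)) + 1L, 1L), ng1)
        gj <- min(max(as.integer(round((cvv[2] - lo2) / dx2)) + 1L, 1L), ng2)
        b <- Vg[gi, gj]
        f <- f - dVg1[gi, gj] * cvg[[1]] - dVg2[gi, gj] * cvg[[2]]
      }
    }
    for (wi in seq_along(walls)) {
      w <- walls[[wi]]
      if (is.null(wall_funs[[wi]])) {
        val <- cvv[w$cv]; grd <- cvg[[w$cv]]
      } else {
        ev <- wall_funs[[wi]](x); val <- ev$value; grd <- ev$grad
      }
      over <- if (w$side == "upper") val - w$threshold else val - w$threshold
      active <- if (w$side == "upper") over > 0 else over < 0
      if (active) {
        e <- e + 0.5 * w$k * over^2
        f <- f - w$k * over * grd
      }
    }
    if (steer_on) {
      if (is.null(st_fun)) {
        val <- cvv[st_cv]; grd <- cvg[[st_cv]]
      } else {
        ev <- st_fun(x); val <- ev$value; grd <- ev$grad
      }
      kap <- sched_interp(steered$kappa, t)
      s0 <- sched_interp(steered$target, t)
      dev <- val - s0
      e <- e + 0.5 * kap * dev^2
      f <- f - kap * dev * grd
      # external work rate: dV/dt at fixed configuration
      wrate <- 0.5 * sched_slope(steered$kappa, t) * dev^2 -
        kap * dev * sched_slope(steered$target, t)
      attr(f, "wrate") <- wrate
    }
    attr(f, "energy") <- e
    attr(f, "bias") <- b
    f
  }

  v <- numeric(d)
  f <- total_force(x, 0)
  a <- ACC_FACTOR * as.numeric(f) / m
  for (step in seq_len(params$n_steps)) {
    t <- step * dt
    v <- v + 0.5 * dt * a
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * sv * rnorm(d)
    x <- x + 0.5 * dt * v
    f <- total_force(x, t)
    a <- ACC_FACTOR * as.numeric(f) / m
    v <- v + 0.5 * dt * a
    if (steer_on) work <- work + attr(f, "wrate") * dt
    if (metad_on && step %% stride_steps == 0L) {
      b_here <- attr(f, "bias")
      W <- wt$height * exp(-b_here / damp)
      nk <- nk + 1L
      k_centers[nk, ] <- cvv[seq_len(ncv)]
      k_heights[nk] <- W; k_steps[nk] <- step; k_times[nk] <- t
      if (ncv == 1) {
        idx <- which(abs(ax1 - cvv[1]) <= 6 * sig[1])
        ee <- exp(-(ax1[idx] - cvv[1])^2 / (2 * sig[1]^2))
        Vg[idx] <- Vg[idx] + W * ee
        dVg1[idx] <- dVg1[idx] - W * (ax1[idx] - cvv[1]) / sig[1]^2 * ee
      } else {
        ix <- which(abs(ax1 - cvv[1]) <= 6 * sig[1])
        iy <- which(abs(ax2 - cvv[2]) <= 6 * sig[2])
        e1 <- exp(-(ax1[ix] - cvv[1])^2 / (2 * sig[1]^2))
        e2 <- exp(-(ax2[iy] - cvv[2])^2 / (2 * sig[2]^2))
        g2 <- e1 %o% e2
        Vg[ix, iy] <- Vg[ix, iy] + W * g2
        dVg1[ix, iy] <- dVg1[ix, iy] -
          W * ((ax1[ix] - cvv[1]) / sig[1]^2 * e1) %o% e2
        dVg2[ix, iy] <- dVg2[ix, iy] -
          W * e1 %o% ((ax2[iy] - cvv[2]) / sig[2]^2 * e2)
      }
    }
    if (step %% record_stride == 0L) {
      en <- attr(f, "energy")
      if (!is.finite(en))
        stop("non-finite energy at step ", step, " (frame ", irec + 1L, ")")
      irec <- irec + 1L
      rec_x[irec, ] <- x
      if (ncv) rec_cv[irec, ] <- cvv[seq_len(ncv)]
      rec_bias[irec] <- attr(f, "bias")
      rec_e[irec] <- en
      rec_t[irec] <- t
      if (steer_on) rec_w[irec] <- work
    }
  }

  out <- list(positions = rec_x, times = rec_t, energies = rec_e,
              cv = if (ncv) {
                colnames(rec_cv) <- vapply(cvs, `[[`, "", "label")
                rec_cv
              },
              bias = rec_bias, params = params, seed = params$seed)
  if (steer_on) out$work <- rec_w
  if (metad_on) {
    state <- bias_state(wt, d = ncv)
    if (nk > 0) {
      state$centers <- k_centers[seq_len(nk), , drop = FALSE]
      state$heights <- k_heights[seq_len(nk)]
      state$widths <- matrix(rep(sig, each = nk), nk)
      state$steps <- k_steps[seq_len(nk)]
      state$times <- k_times[seq_len(nk)]
    }
    out$state <- state
  }
  class(out) <- "DynamicsRun"
  out
}

#' @export
print.DynamicsRun <- function(x, ...) {
  cat(sprintf("DynamicsRun: %d recorded frames, seed %d%s\n",
              nrow(x$positions), x$seed,
              if (!is.null(x$state))
                sprintf(", %d kernels", length(x$state$heights)) else ""))
  invisible(x)
}

#' Plain Langevin dynamics
#'
#' BAOAB-discretized Langevin trajectory over an energy model plus any
#' wall restraints; reproducible per seed.
#'
#' @param model EnergyModel; @param params LangevinParams;
#' @param x0 initial configuration;
#' @param cvs list of `CV`s recorded along the run;
#' @param walls list of [wall_restraint()]s;
#' @param record_stride record every so many steps.
#' @return `DynamicsRun`: recorded positions, times, energies, CV series.
#' @export
run_langevin <- function(model, params, x0, cvs = list(), walls = list(),
                         record_stride = 10L) {
  run_dynamics(model, params, x0, cvs = cvs, walls = walls,
               record_stride = record_stride)
}

#' Well-tempered metadynamics run
#'
#' Langevin dynamics with a history-dependent bias on the given CVs: a
#' kernel is deposited every `wt$stride` ps with height from
#' [next_height()] at the current CV point, and the bias force is added
#' to the model force (chain rule through the CV gradients).  The bias
#' and its CV-gradient are accumulated on the deposition grid, so the
#' per-step cost is independent of the kernel count.
#'
#' @inheritParams run_langevin
#' @param wt WTParams; @param gs CV grid spec ([grid_spec()]).
#' @return `DynamicsRun` with a `state` (BiasState) component.
#' @export
run_metad <- function(model, params, x0, cvs, wt, gs, walls = list(),
                      record_stride = 10L) {
  run_dynamics(model, params, x0, cvs = cvs, wt = wt, gs = gs,
               walls = walls, record_stride = record_stride)
}

#' Steered (moving-restraint) run
#'
#' @inheritParams run_langevin
#' @param schedule SteeredSchedule; the run length is
#'   `schedule$duration` unless `params$n_steps` is shorter.
#' @return `DynamicsRun` with a `work` series (kcal/mol).
#' @export
run_steered <- function(model, params, x0, schedule, cvs = list(),
                        walls = list(), record_stride = 10L) {
  run_dynamics(model, params, x0, cvs = cvs, steered = schedule,
               walls = walls, record_stride = record_stride)
}
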