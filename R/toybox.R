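# ---------------------------------------------------------------------------
# Synthetic fixtures: a two-state bead-chain "receptor" with an
# analytically known double-well energy, transition trajectories, and
# correlated-Gaussian trajectories.  Every fixture is reproducible from
# (spec, seed).
# ---------------------------------------------------------------------------

#' Specification of the two-state bead chain
#'
#' The default endpoints emulate, at bead scale, the hallmark motion of
#' class A GPCR activation: one helix-like segment of the chain (the
#' "TM6" segment) translates by about 3 Angstrom and rotates about 45
#' degrees around the chain axis between the two states, so the
#' endpoint conformations differ by both a translation-like and a
#' rotation-like internal change.
#'
#' @param n_beads beads in the chain (default 24).
#' @param displacement translation of the mobile segment, Angstrom
#'   (default 3).
#' @param rotation rotation of the mobile segment, degrees (default 45).
#' @param barrier barrier height parameter of the double well, kcal/mol
#'   (default 6).
#' @param delta_g tilt between the two basins, kcal/mol (default 2;
#'   state B sits higher).
#' @param k_perp harmonic stiffness orthogonal to the transition
#'   coordinate, kcal/mol/A^2 (default 2).
#' @return spec list of class `TwoStateChainSpec`.
#' @export
two_state_chain_spec <- function(n_beads = 24, displacement = 3,
                                 rotation = 45, barrier = 6, delta_g = 2,
                                 k_perp = 2) {
  if (barrier <= 0) stop("barrier must be positive")
  out <- list(n_beads = as.integer(n_beads), displacement = displacement,
              rotation = rotation, barrier = barrier, delta_g = delta_g,
              k_perp = k_perp)
  class(out) <- "TwoStateChainSpec"
  out
}

# helix-like bead chain along z (rise 1.5 A, radius 2.3 A, 100 deg/bead)
helix_coords <- function(n) {
  ang <- (seq_len(n) - 1) * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), (seq_len(n) - 1) * 1.5)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Build the two-state chain model and its endpoint structures
#'
#' Endpoint A is a helix-like bead chain; endpoint B moves the second
#' half of the chain (the mobile "TM6" segment) by the requested
#' translation and axial rotation.  The energy over the flattened
#' coordinates X is a tilted double well along the A-to-B line,
#'
#'   V(X) = h (u^2 - 1)^2 + (g/2) u + (k_perp/2) |X_perp|^2,
#'
#' where u is the signed projection of X onto the A-B axis scaled so
#' u = -1 at A and +1 at B, and X_perp the orthogonal residual.  The
#' perpendicular modes are Gaussian and identical in both basins, so the
#' free energy along u is exactly the 1D profile f(u) = h(u^2-1)^2 +
#' (g/2)u up to a constant; the analytic basin free-energy difference
#' and barrier are computed from f by quadrature (see
#' [analytic_reference()]).
#'
#' @param spec TwoStateChainSpec.
#' @return list: `model` (EnergyModel over 3*n_beads coordinates),
#'   `A`, `B` (endpoint Structures), `spec`, and `profile` (the 1D
#'   function f(u)).
#' @export
make_two_state_chain <- function(spec = two_state_chain_spec()) {
  n <- spec$n_beads
  A <- helix_coords(n)
  mobile <- (n %/% 2 + 1):n
  B <- A
  seg <- A[mobile, , drop = FALSE]
  ctr <- colMeans(seg)
  B[mobile, ] <- sweep(sweep(seg, 2, ctr) %*% t(rot_z(spec$rotation)), 2,
                       ctr + c(0, 0, spec$displacement), `+`)
  if (max(abs(A - B)) < 1e-9) stop("degenerate endpoints: A and B identical")
  a <- as.numeric(t(A)); b <- as.numeric(t(B))
  mid <- (a + b) / 2
  axis <- (b - a)
  L <- sqrt(sum(axis^2)) / 2
  e <- axis / (2 * L)
  h <- spec$barrier; g <- spec$delta_g; kp <- spec$k_perp
  f_u <- function(u) h * (u^2 - 1)^2 + (g / 2) * u
  fun <- function(x) {
    dxv <- x - mid
    u <- sum(dxv * e) / L
    perp <- dxv - (u * L) * e
    energy <- f_u(u) + 0.5 * kp * sum(perp^2)
    df_du <- 4 * h * u * (u^2 - 1) + g / 2
    grad <- (df_du / L) * e + kp * perp
    list(energy = energy, grad = grad)
  }
  topo <- data.frame(serial = seq_len(n), name = "CA", resname = "GLY",
                     resid = seq_len(n), chain = "A", element = "C")
  list(model = energy_model(fun, 3 * n, kind = "atoms",
                            meta = list(spec = spec, profile = f_u,
                                        x_A = a, x_B = b)),
       A = structure_model(topo, A), B = structure_model(topo, B),
       spec = spec, profile = f_u)
}

#' One-dimensional tilted double-well model
#'
#' `f(x) = h (x^2 - 1)^2 + (g/2) x`: minima near x = -1 and +1, barrier
#' near x = 0.  The 1D surrogate of the two-state chain, used to
#' exercise the bias machinery where the free energy along the
#' coordinate is the potential itself.
#'
#' @param barrier h, kcal/mol (default 6); @param tilt g, kcal/mol
#'   (default 2).
#' @return `EnergyModel` with d = 1.
#' @export
double_well_model <- function(barrier = 6, tilt = 2) {
  h <- barrier; g <- tilt
  energy_model(function(x) list(
    energy = h * (x[1]^2 - 1)^2 + (g / 2) * x[1],
    grad = 4 * h * x[1] * (x[1]^2 - 1) + g / 2),
    d = 1, kind = "vector",
    meta = list(profile = function(u) h * (u^2 - 1)^2 + (g / 2) * u))
}

#' Analytic free-energy reference of a double-well profile
#'
#' Locates the two minima and the intervening maximum of the 1D profile
#' and computes the exact basin free-energy difference
#' `dG = -kBT ln(Z_right / Z_left)` by numerical quadrature of the
#' Boltzmann weight on each side of the barrier top, plus the barrier
#' measured from the lower (left) minimum.
#'
#' @param model EnergyModel carrying a `profile` function in its meta,
#'   or a bare function f(u).
#' @param temperature K; @param range integration range on u.
#' @return list: `delta_g`, `barrier`, `x_max`, `x_min_left`,
#'   `x_min_right` (all kcal/mol / CV units).
#' @export
analytic_reference <- function(model, temperature = 300,
                               range = c(-2.5, 2.5)) {
  f <- if (inherits(model, "EnergyModel")) model$meta$profile else model
  xmax <- optimize(f, c(-0.6, 0.6), maximum = TRUE)$maximum
  xl <- optimize(f, c(range[1], xmax))$minimum
  xr <- optimize(f, c(xmax, range[2]))$minimum
  bt <- KB_KCAL * temperature
  zl <- integrate(function(x) exp(-(f(x) - f(xl)) / bt), range[1], xmax)$value
  zr <- integrate(function(x) exp(-(f(x) - f(xl)) / bt), xmax, range[2])$value
  list(delta_g = -bt * log(zr / zl), barrier = f(xmax) - f(xl),
       x_max = xmax, x_min_left = xl, x_min_right = xr)
}

# quaternion slerp of a rotation matrix toward the identity
partial_rotation <- function(R, frac) {
  tr <- sum(diag(R))
  ang <- acos(pmin(pmax((tr - 1) / 2, -1), 1))
  if (ang < 1e-12) return(diag(3))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  a <- ang * frac
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Synthetic transition trajectory between the chain endpoints
#'
#' Geodesic interpolation: endpoint B is optimally superposed onto A,
#' coordinates are blended linearly in the aligned frame, and the rigid
#' part of the A-to-B motion is reintroduced gradually (quaternion
#' interpolation of the rotation, linear translation) so that frame 1
#' equals A and the last frame equals B exactly at zero noise.
#' Gaussian coordinate noise is then added (never to the endpoints'
#' defining blend; noise 0 reproduces the endpoints bit-exactly).
#'
#' @param chain result of [make_two_state_chain()].
#' @param n_frames frames in the trajectory.
#' @param noise Gaussian coordinate noise s.d., Angstrom.
#' @param seed RNG seed.
#' @return `Trajectory`.
#' @export
make_transition_trajectory <- function(chain, n_frames = 50, noise = 0,
                                       seed = 1) {
  set.seed(seed)
  A <- chain$A$coords; B <- chain$B$coords
  sup <- superpose(B, A)                 # B aligned onto A
  Bal <- apply_superposition(sup, B)
  # inverse rigid transform taking aligned B back to B
  Rinv <- t(sup$rotation)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    tfrac <- (k - 1) / (n_frames - 1)
    blend <- (1 - tfrac) * A + tfrac * Bal
    Rk <- partial_rotation(Rinv, tfrac)
    ck <- colMeans(blend)
    moved <- sweep(sweep(blend, 2, ck) %*% t(Rk), 2, ck, `+`)
    # translation component interpolated linearly
    shift <- tfrac * (colMeans(B) - colMeans(Bal))
    moved <- sweep(moved, 2, shift, `+`)
    if (noise > 0 && k > 1 && k < n_frames)
      moved <- moved + matrix(rnorm(length(moved), sd = noise), nrow(moved))
    frames[[k]] <- moved
  }
  frames[[1]] <- A; frames[[n_frames]] <- B
  trajectory(chain$A, frames, times = seq_len(n_frames))
}

#' Specification for a correlated-Gaussian trajectory
#'
#' @param n_atoms atoms; @param rho pairwise correlation: a scalar
#'   (applied to every off-diagonal pair) or a full n x n correlation
#'   matrix; @param n_frames frames; @param seed RNG seed;
#' @param sd per-coordinate fluctuation s.d., Angstrom.
#' @return spec list of class `CorrelatedTrajSpec`.
#' @export
correlated_traj_spec <- function(n_atoms = 4, rho = 0.5, n_frames = 1000,
                                 seed = 1, sd = 1) {
  if (is.matrix(rho)) {
    stopifnot(nrow(rho) == n_atoms, isSymmetric(rho))
  }
  out <- list(n_atoms = as.integer(n_atoms), rho = rho,
              n_frames = as.integer(n_frames), seed = as.integer(seed),
              sd = sd)
  class(out) <- "CorrelatedTrajSpec"
  out
}

#' Trajectory of atoms with prescribed displacement correlations
#'
#' Frames are drawn from a multivariate normal around a straight-line
#' reference geometry, with the same atom-atom correlation matrix
#' applied independently to each Cartesian axis, so the dynamical
#' cross-correlation of atoms i and j equals rho_ij exactly in
#' expectation.
#'
#' @param spec CorrelatedTrajSpec.
#' @return `Trajectory`.
#' @export
make_correlated_trajectory <- function(spec = correlated_traj_spec()) {
  n <- spec$n_atoms
  C <- if (is.matrix(spec$rho)) spec$rho else {
    M <- matrix(spec$rho, n, n); diag(M) <- 1; M
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  Sigma <- spec$sd^2 * C
  set.seed(spec$seed)
  ref <- cbind(seq_len(n) * 5, 0, 0)
  dx <- MASS::mvrnorm(spec$n_frames, rep(0, n), Sigma)
  dy <- MASS::mvrnorm(spec$n_frames, rep(0, n), Sigma)
  dz <- MASS::mvrnorm(spec$n_frames, rep(0, n), Sigma)
  frames <- lapply(seq_len(spec$n_frames), function(k)
    ref + cbind(dx[k, ], dy[k, ], dz[k, ]))
  topo <- structure_model(
    data.frame(serial = seq_len(n), name = "CA", resname = "ALA",
               resid = seq_len(n), chain = "A", element = "C"), ref)
  trajectory(topo, frames, times = seq_len(spec$n_frames))
}

#' Emit the default fixture tree
#'
#' Writes endpoint PDBs, a transition trajectory in XYZ and a YAML spec
#' into `dir`; everything regenerates bit-identically from the seed.
#'
#' @param dir output directory; @param seed RNG seed.
#' @return `dir`, invisibly.
#' @export
write_fixture_tree <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- two_state_chain_spec()
  chain <- make_two_state_chain(spec)
  write_structure(chain$A, file.path(dir, "state_A.pdb"))
  write_structure(chain$B, file.path(dir, "state_B.pdb"))
  traj <- make_transition_trajectory(chain, n_frames = 50, noise = 0.05,
                                     seed = seed)
  write_xyz(traj, file.path(dir, "transition.xyz"))
  yaml::write_yaml(c(unclass(spec), list(seed = seed, n_frames = 50,
                                         noise = 0.05)),
                   file.path(dir, "fixtures.yml"))
  invisible(dir)
}
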