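test_that("contact switching function matches closed forms and limits", {
  expect_equal(contact_value(0, 1), 1)
  expect_equal(contact_value(1, 1), 0.5)              # n/m limit at r = r0
  expect_equal(contact_value(2, 1), 63 / 4095, tolerance = 1e-12)
  expect_equal(contact_value(3, 2, n = 2, m = 4),
               (1 - 1.5^2) / (1 - 1.5^4), tolerance = 1e-12)
  # continuity across the removable singularity
  eps <- 1e-8
  expect_equal(contact_value(1 - eps, 1), contact_value(1 + eps, 1),
               tolerance = 1e-6)
})

test_that("contact derivative matches finite differences, including near r0", {
  rs <- c(0.3, 0.7, 0.9999999, 1.0000001, 1.3, 2.5)
  for (r in rs) {
    d <- contact_value(r, 1, deriv = TRUE)
    h <- 1e-6
    fd <- (contact_value(r + h, 1) - contact_value(r - h, 1)) / (2 * h)
    expect_equal(d$deriv, fd, tolerance = 1e-4)
  }
})

# a well-behaved coordinate-metric path for reuse: 4 atoms deforming
make_test_path <- function(N = 12, lambda = 40) {
  base <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0, 1, 1, 3), 4, 3, byrow = TRUE)
  frames <- lapply(seq_len(N), function(k) {
    t <- (k - 1) / (N - 1)
    base + t * matrix(c(0, 0, 1, 1, 0, 0, 0, -1, 0, -1, 0, 1), 4, 3,
                      byrow = TRUE)
  })
  reference_path(frames, metric = "rmsd", lambda = lambda)
}

test_that("s hits its endpoint identities at the path termini", {
  p <- make_test_path(lambda = 2000)   # lambda * neighbor distance >> 1
  e1 <- evaluate_path_cv(p$frames[[1]], p)
  eN <- evaluate_path_cv(p$frames[[12]], p)
  expect_equal(e1$s, 0, tolerance = 1e-6)
  expect_equal(e1$z, 0, tolerance = 1e-6)
  expect_equal(eN$s, 1, tolerance = 1e-6)
})

test_that("s and z equal the brute-force sum oracle on seeded instances", {
  set.seed(123)
  for (case in 1:200) {
    N <- sample(3:6, 1)
    natoms <- sample(4:6, 1)
    frames <- lapply(seq_len(N), function(k) matrix(rnorm(3 * natoms), natoms))
    lam <- runif(1, 0.2, 5)
    p <- reference_path(frames, metric = "rmsd", lambda = lam)
    x <- matrix(rnorm(3 * natoms), natoms)
    ev <- evaluate_path_cv(x, p)
    d_oracle <- vapply(frames, function(f) svd_rmsd(f, x)^2, numeric(1))
    o <- naive_sz(d_oracle, lam)
    expect_equal(ev$s, o$s, tolerance = 1e-9)
    expect_equal(ev$z, o$z, tolerance = 1e-9)
  }
})

test_that("contact-metric s and z equal the brute-force oracle", {
  set.seed(77)
  cd <- contact_definition(c(1, 1, 2), c(3, 4, 4), r0 = c(3, 4, 3.5))
  for (case in 1:50) {
    frames <- lapply(1:4, function(k) runif(3))    # direct contact vectors
    lam <- runif(1, 0.5, 4)
    p <- reference_path(frames, metric = "cmap", lambda = lam, contacts = cd)
    co <- matrix(rnorm(12, sd = 2), 4)
    xred <- reduce_representation(co, p)
    ev <- evaluate_path_cv(co, p)
    d_oracle <- vapply(frames, function(f) sum((xred - f)^2), numeric(1))
    o <- naive_sz(d_oracle, lam)
    expect_equal(ev$s, o$s, tolerance = 1e-9)
    expect_equal(ev$z, o$z, tolerance = 1e-9)
  }
})

test_that("reduction produces selection rows or switched contacts", {
  co <- matrix(c(0, 0, 0, 1, 0, 0, 0, 2, 0, 0, 0, 4), 4, 3, byrow = TRUE)
  cd <- contact_definition(c(1, 1), c(2, 4), r0 = c(1, 2))
  p <- reference_path(list(c(0.5, 0.5), c(0.4, 0.4)), metric = "cmap",
                      lambda = 1, contacts = cd)
  red <- reduce_representation(co, p)
  expect_equal(red, c(0.5, contact_value(4, 2)), tolerance = 1e-12)
  # pair at r = 0 gives contact 1
  co0 <- co; co0[2, ] <- 0
  expect_equal(reduce_representation(co0, p)[1], 1)
})

test_that("path CV gradients match central finite differences", {
  p <- make_test_path(N = 6, lambda = 5)
  set.seed(31)
  x <- p$frames[[3]] + matrix(rnorm(12, sd = 0.15), 4)
  ev <- evaluate_path_cv(x, p, gradient = TRUE)
  h <- 1e-6
  for (i in c(1, 2, 4)) for (j in 1:3) {
    xp <- x; xm <- x
    xp[i, j] <- xp[i, j] + h; xm[i, j] <- xm[i, j] - h
    fd_s <- (evaluate_path_cv(xp, p)$s - evaluate_path_cv(xm, p)$s) / (2 * h)
    fd_z <- (evaluate_path_cv(xp, p)$z - evaluate_path_cv(xm, p)$z) / (2 * h)
    expect_equal(ev$ds_dx[i, j], fd_s, tolerance = 1e-5 * max(1, abs(fd_s)))
    expect_equal(ev$dz_dx[i, j], fd_z, tolerance = 1e-5 * max(1, abs(fd_z)))
  }
})

test_that("contact-metric gradients propagate through the switching function", {
  cd <- contact_definition(c(1, 2), c(3, 4), r0 = c(2, 2.5))
  set.seed(13)
  frames <- lapply(1:3, function(k) runif(2))
  p <- reference_path(frames, metric = "cmap", lambda = 2, contacts = cd)
  x <- matrix(rnorm(12, sd = 1.5), 4)
  ev <- evaluate_path_cv(x, p, gradient = TRUE)
  h <- 1e-6
  for (i in 1:4) for (j in 1:3) {
    xp <- x; xm <- x
    xp[i, j] <- xp[i, j] + h; xm[i, j] <- xm[i, j] - h
    fd <- (evaluate_path_cv(xp, p)$s - evaluate_path_cv(xm, p)$s) / (2 * h)
    expect_equal(ev$ds_dx[i, j], fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("s stays in [0,1] and is invariant under rigid motion", {
  p <- make_test_path()
  set.seed(55)
  for (k in 1:25) {
    x <- p$frames[[sample(12, 1)]] + matrix(rnorm(12, sd = 0.5), 4)
    ev <- evaluate_path_cv(x, p)
    expect_gte(ev$s, 0); expect_lte(ev$s, 1)
    expect_gt(ev$z, -log(12) / p$lambda)      # lower bound on z
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
    x2 <- sweep(x %*% t(R), 2, rnorm(3, sd = 3), `+`)
    expect_equal(evaluate_path_cv(x2, p)$s, ev$s, tolerance = 1e-9)
  }
})

test_that("z approaches the nearest-frame distance as lambda grows", {
  base <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 1, 1, 1), 4, 3, byrow = TRUE)
  step <- matrix(c(0, 0, 1, 1, 0, 0, 0, -1, 0, -1, 1, 0), 4, 3, byrow = TRUE)
  frames <- lapply(0:3, function(k) base + k * step)   # non-rigid deformation
  set.seed(8)
  x <- frames[[2]] + matrix(rnorm(12, sd = 0.2), 4)
  dmin <- min(vapply(frames, function(f) svd_rmsd(f, x)^2, numeric(1)))
  p_hi <- reference_path(frames, metric = "rmsd", lambda = 500)
  expect_equal(evaluate_path_cv(x, p_hi)$z, dmin, tolerance = 1e-3)
  # z at a path frame goes to 0
  expect_equal(abs(evaluate_path_cv(frames[[3]], p_hi)$z), 0, tolerance = 1e-6)
})

test_that("large lambda * distance does not overflow the kernel sums", {
  p <- make_test_path(N = 4, lambda = 1e6)
  ev <- evaluate_path_cv(p$frames[[1]] + 50, p)
  expect_true(is.finite(ev$s) && is.finite(ev$z))
})

test_that("path construction extracts frames plus two terminal extras", {
  ch <- make_two_state_chain()
  tr <- make_transition_trajectory(ch, n_frames = 60, noise = 0.02, seed = 4)
  p <- build_path(tr, 10)
  expect_length(p$frames, 12)
  expect_equal(p$is_extra, c(TRUE, rep(FALSE, 10), TRUE))
  expect_equal(sum(!p$is_extra), 10)
  expect_error(build_path(tr, 100), "shorter")
  expect_error(build_path(tr, 1), ">= 2")
})

test_that("equal-arc selection is exactly equidistant on a linear transition", {
  base <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0, 1, 1, 2), 4, 3, byrow = TRUE)
  step <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0, 0, 0, -1), 4, 3, byrow = TRUE)
  topo <- structure_model(
    data.frame(serial = 1:4, name = "CA", resname = "GLY", resid = 1:4,
               chain = "A", element = "C"), base)
  frames <- lapply(0:20, function(k) base + (k / 20) * step)
  traj <- trajectory(topo, frames)
  p <- build_path(traj, 5)
  d <- validate_spacing(p)
  expect_lt(d$cv, 0.01)
  # terminal extrapolation continues the same step vector
  expect_equal(p$frames[[1]], p$frames[[2]] - (p$frames[[3]] - p$frames[[2]]),
               tolerance = 1e-9)
  expect_equal(p$frames[[7]], p$frames[[6]] + (p$frames[[6]] - p$frames[[5]]),
               tolerance = 1e-9)
})

test_that("s along the source trajectory is non-decreasing at picked frames", {
  ch <- make_two_state_chain()
  tr <- make_transition_trajectory(ch, n_frames = 40, noise = 0.03, seed = 6)
  p <- build_path(tr, 10)
  svals <- vapply(tr$frames, function(f) evaluate_path_cv(f, p)$s, numeric(1))
  expect_true(all(diff(svals) > -0.02))
  expect_lt(svals[1], 0.15)
  expect_gt(svals[40], 0.85)
})

test_that("spacing diagnostics report mean and coefficient of variation", {
  frames1d <- lapply(c(0, 1, 2, 3), function(v) matrix(c(0, 0, 0, v, 0, 0,
                                                         0, v, 0), 3, 3,
                                                       byrow = TRUE))
  # equal gaps in rmsd metric
  p <- reference_path(frames1d, metric = "rmsd", lambda = 1)
  expect_equal(validate_spacing(p)$cv, 0, tolerance = 1e-9)
  # one doubled gap: distances (1,1,2)/sqrt(3)... use cmap for exact control
  cd <- contact_definition(1, 2, 1)
  pc <- reference_path(list(0.1, 0.2, 0.3, 0.5),
                       metric = "cmap", lambda = 1, contacts = cd)
  dd <- suppressWarnings(validate_spacing(pc))
  # squared contact gaps: 0.01, 0.01, 0.04 -> mean 0.02, sd 0.01732
  expect_equal(dd$interframe_distances, c(0.01, 0.01, 0.04), tolerance = 1e-12)
  expect_equal(dd$mean, 0.02, tolerance = 1e-12)
  expect_equal(dd$cv, sd(c(.01, .01, .04)) / 0.02, tolerance = 1e-9)
})

test_that("lambda calibration follows the 2.3/mean rule with user override", {
  cd <- contact_definition(1, 2, 1)
  diag_c <- list(interframe_distances = c(0.63, 0.63), mean = 0.63, cv = 0,
                 metric = "cmap", n_real = 3)
  expect_equal(calibrate_lambda(diag_c), 2.3 / 0.63, tolerance = 1e-9)
  expect_equal(calibrate_lambda(diag_c), 3.65, tolerance = 0.01)
  diag_r <- list(interframe_distances = c(2.3, 2.3), mean = 2.3, cv = 0,
                 metric = "cmap", n_real = 3)
  expect_equal(calibrate_lambda(diag_r), 1.0)
  expect_error(calibrate_lambda(list(interframe_distances = 0, mean = 0,
                                     metric = "cmap")), "zero mean")
  # explicit production-style override is honored verbatim
  p <- make_test_path(lambda = 1.22)
  expect_equal(p$lambda, 1.22)
})

test_that("path archives round-trip through the on-disk format", {
  p <- make_test_path(N = 5, lambda = 3.5)
  dir <- file.path(tempdir(), "patharchive")
  save_path_archive(p, dir)
  back <- load_path_archive(dir)
  expect_equal(back$lambda, 3.5)
  expect_equal(length(back$frames), 5)
  for (k in 1:5) expect_equal(back$frames[[k]], p$frames[[k]],
                              tolerance = 1e-3)   # PDB 3-decimal precision
  # contact-metric archive
  cd <- contact_definition(c(1, 2), c(3, 4), r0 = c(2, 3))
  pc <- reference_path(lapply(1:4, function(k) c(0.1 * k, 0.2 * k)),
                       metric = "cmap", lambda = 2, contacts = cd)
  dir2 <- file.path(tempdir(), "patharchive2")
  save_path_archive(suppressWarnings(pc), dir2)
  back2 <- load_path_archive(dir2)
  expect_equal(back2$frames, pc$frames, tolerance = 1e-9)
  expect_equal(back2$contacts$r0, c(2, 3))
})
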