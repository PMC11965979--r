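# hand-built two-residue structure: side-chain atoms placed so exactly
# three cross pairs fall inside the 4.5 A cutoff
two_residue_toy <- function() {
  atoms <- data.frame(
    serial = 1:10,
    name = c("N", "CA", "C", "SB1", "SB2", "N", "CA", "C", "SB1", "SB2"),
    resname = "XXA",
    resid = c(rep(1, 5), rep(3, 5)),        # non-adjacent residues
    chain = "A", element = "C")
  co <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),     # backbone res 1
    c(0, 2, 0), c(1, 2, 0),                 # side chain res 1
    c(0, 0, 20), c(1, 0, 20), c(2, 0, 20),  # backbone res 3 (far away)
    c(0, 5, 0), c(1, 6, 0))                 # side chain res 3, near res 1
  # cross side-chain pairs within 4.5: SB1-SB1 = 3, SB2-SB1 = sqrt(10),
  # SB2-SB2 = 4.4; SB1-SB2 = sqrt(1 + 4.4^2) = 4.512 excluded -> 3 pairs
  co[10, ] <- c(1, 6.4, 0)
  structure_model(atoms, co)
}

test_that("interaction strength follows the normalized contact-count form", {
  expect_equal(interaction_strength(0, 5, 5), 0)
  expect_equal(interaction_strength(4, 16, 16), 25)
  expect_equal(interaction_strength(1, 1, 1), 100)
  expect_equal(interaction_strength(3, 9, 9), 100 / 3, tolerance = 1e-9)
  expect_error(interaction_strength(1, 0, 4), "positive")
})

test_that("graph construction counts side-chain pairs and applies the cutoff", {
  s <- two_residue_toy()
  norm <- c(XXA = 9)
  g <- build_psg(s, psn_params(i_min = 30, normalization = norm))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$strength, 3 / 9 * 100, tolerance = 1e-9)
  # raising i_min past the strength removes the edge (monotone filtering)
  g2 <- build_psg(s, psn_params(i_min = 40, normalization = norm))
  expect_equal(nrow(g2$edges), 0)
})

test_that("residues far apart and poly-glycine inputs give empty graphs", {
  s <- two_residue_toy()
  s$coords[9:10, 3] <- 50                      # move res-3 side chain away
  g <- suppressWarnings(build_psg(s, psn_params(normalization = c(XXA = 9))))
  expect_equal(nrow(g$edges), 0)
  gly <- structure_model(
    data.frame(serial = 1:6, name = rep(c("N", "CA", "C"), 2),
               resname = "GLY", resid = rep(1:2, each = 3), chain = "A",
               element = c("N", "C", "C")),
    matrix(rnorm(18), 6))
  expect_warning(g0 <- build_psg(gly), "empty graph")
  expect_equal(nrow(g0$edges), 0)
})

test_that("sequence neighbors are excluded from edges by default", {
  atoms <- data.frame(
    serial = 1:4, name = rep("SB", 4), resname = "XXA",
    resid = c(1, 2, 3, 5), chain = "A", element = "C")
  co <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0), c(6, 0, 0))
  s <- structure_model(atoms, co)
  g <- build_psg(s, psn_params(atom_cutoff = 2.5, i_min = 0,
                               normalization = c(XXA = 1)))
  keys <- paste(g$edges$res_i, g$edges$res_j)
  expect_false("A:1 A:2" %in% keys)            # |i-j| = 1 excluded
  expect_true("A:3 A:5" %in% keys)             # |i-j| = 2 kept
})

test_that("per-frame graphs match the naive pair-loop oracle exactly", {
  set.seed(71)
  n_res <- 6
  atoms <- data.frame(
    serial = 1:(3 * n_res),
    name = rep(c("CA", "SB1", "SB2"), n_res),
    resname = rep(c("AAA", "BBB"), length.out = 3 * n_res),
    resid = rep(seq_len(n_res) * 2, each = 3), chain = "A", element = "C")
  atoms$resname <- rep(rep(c("AAA", "BBB"), length.out = n_res), each = 3)
  for (trial in 1:5) {
    co <- matrix(runif(9 * n_res, 0, 12), 3 * n_res)
    s <- structure_model(atoms, co)
    norm <- c(AAA = 4, BBB = 7)
    g <- build_psg(s, psn_params(i_min = 5, normalization = norm))
    oracle <- naive_psn_edges(s, 4.5, 5, norm)
    if (is.null(oracle)) {
      expect_equal(nrow(g$edges), 0)
    } else {
      got <- g$edges[order(g$edges$res_i, g$edges$res_j), ]
      want <- oracle[order(oracle$res_i, oracle$res_j), ]
      expect_equal(got$res_i, want$res_i)
      expect_equal(got$res_j, want$res_j)
      expect_equal(got$strength, want$strength, tolerance = 1e-12)
    }
  }
})

test_that("consensus graphs over trajectories carry edge frequencies", {
  s <- two_residue_toy()
  co2 <- s$coords
  co2[9:10, ] <- co2[9:10, ] + 30              # broken in frame 2
  traj <- trajectory(s, list(s$coords, s$coords, co2))
  g <- build_psg(traj, psn_params(i_min = 30, normalization = c(XXA = 9)))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$frequency, 2 / 3, tolerance = 1e-12)
  expect_length(g$frames, 3)
})

test_that("self-calibrated normalization is deterministic and positive", {
  set.seed(5)
  s <- two_residue_toy()
  g1 <- build_psg(s, psn_params(i_min = 0))
  g2 <- build_psg(s, psn_params(i_min = 0))
  expect_identical(g1$normalization, g2$normalization)
  expect_true(all(g1$normalization > 0))
})

test_that("hub detection ranks high-degree residues", {
  # star: center residue contacts five satellites
  mk_edges <- function(center, sats) {
    data.frame(res_i = pmin(center, sats), res_j = pmax(center, sats),
               strength = 50, frequency = 1)
  }
  g <- structure(list(nodes = data.frame(id = c("A:1", paste0("A:", 3:8))),
                      edges = mk_edges("A:1", paste0("A:", 3:7)),
                      params = psn_params()), class = "PSNGraph")
  hubs <- find_hubs(g, min_degree = 4)
  expect_equal(hubs$id, "A:1")
  expect_equal(hubs$degree, 5)
  empty <- structure(list(nodes = data.frame(id = character(0)),
                          edges = data.frame(res_i = character(0),
                                             res_j = character(0)),
                          params = psn_params()), class = "PSNGraph")
  expect_equal(nrow(find_hubs(empty)), 0)
})

test_that("metapaths prefer persistently present edges", {
  mk_frame <- function(edges) {
    structure(list(nodes = data.frame(id = c("A:1", "A:2", "A:3", "A:4")),
                   edges = edges, params = psn_params()),
              class = "PSNGraph")
  }
  e_direct <- data.frame(res_i = c("A:1", "A:2", "A:1", "A:3"),
                         res_j = c("A:2", "A:4", "A:3", "A:4"),
                         strength = 10)
  e_nodirect <- e_direct[-3, ]
  frames <- c(lapply(1:2, function(i) mk_frame(e_direct)),
              lapply(1:2, function(i) mk_frame(e_nodirect)))
  # path 1-2-4 uses edges present in all frames; 1-3-4 only in half
  mp <- metapath(frames, "A:1", "A:4", freq_min = 0.4)
  expect_equal(mp$path[1], "A:1 -> A:2 -> A:4")
  expect_equal(mp$frequency[1], 1, tolerance = 1e-6)
  # identical frames reduce to the plain shortest path
  same <- lapply(1:3, function(i) mk_frame(e_direct))
  mp2 <- metapath(same, "A:1", "A:4", freq_min = 0.5)
  expect_equal(mp2$frequency[1], 1, tolerance = 1e-6)
  expect_true(mp2$path[1] %in% c("A:1 -> A:2 -> A:4", "A:1 -> A:3 -> A:4"))
})

test_that("metapath ranking agrees with exhaustive path enumeration", {
  set.seed(83)
  nodes <- paste0("A:", 1:7)
  for (trial in 1:10) {
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (sum(keep) < 3) next
    edges <- data.frame(res_i = pairs[keep, 1], res_j = pairs[keep, 2],
                        strength = 10,
                        frequency = round(runif(sum(keep), 0.55, 1), 2))
    g <- structure(list(nodes = data.frame(id = nodes), edges = edges,
                        params = psn_params(), frames = NULL),
                   class = "PSNGraph")
    mp <- metapath(g, "A:1", "A:7", freq_min = 0.5, k = 50)
    bf <- best_path_bruteforce(edges, "A:1", "A:7")
    if (bf$freq < 0) {
      expect_equal(nrow(mp), 0)
    } else {
      expect_equal(mp$frequency[1], unname(bf$freq), tolerance = 1e-9)
    }
  }
})

test_that("metapath ranking is invariant to frame order", {
  mk_frame <- function(edges) {
    structure(list(nodes = data.frame(id = paste0("A:", 1:4)), edges = edges,
                   params = psn_params()), class = "PSNGraph")
  }
  e1 <- data.frame(res_i = c("A:1", "A:2"), res_j = c("A:2", "A:3"),
                   strength = 5)
  e2 <- data.frame(res_i = c("A:1", "A:2", "A:3"),
                   res_j = c("A:2", "A:3", "A:4"), strength = 5)
  frames <- list(mk_frame(e1), mk_frame(e2), mk_frame(e2))
  mp_a <- metapath(frames, "A:1", "A:3", freq_min = 0.3)
  mp_b <- metapath(rev(frames), "A:1", "A:3", freq_min = 0.3)
  expect_equal(mp_a, mp_b)
})

test_that("disconnected endpoints yield an empty diagnostic result", {
  g <- structure(list(nodes = data.frame(id = paste0("A:", 1:4)),
                      edges = data.frame(res_i = "A:1", res_j = "A:2",
                                         strength = 10, frequency = 1),
                      params = psn_params(), frames = NULL),
                 class = "PSNGraph")
  mp <- metapath(g, "A:1", "A:4", freq_min = 0.5)
  expect_equal(nrow(mp), 0)
  expect_match(attr(mp, "diagnostic"), "disconnected")
})

test_that("edge lists export as TSV", {
  s <- two_residue_toy()
  g <- build_psg(s, psn_params(i_min = 30, normalization = c(XXA = 9)))
  f <- tempfile(fileext = ".tsv")
  write_psn(g, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$strength, 100 / 3, tolerance = 1e-6)
})
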