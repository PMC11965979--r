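# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: superposition via SVD (Kabsch) instead
# of the quaternion method, CV sums written out naively, per-pair loops
# instead of vectorized linear algebra.

# Kabsch/SVD rigid superposition: returns min RMSD between paired sets
svd_rmsd <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  H <- t(sweep(mobile, 2, cm)) %*% sweep(reference, 2, cr)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(mobile %*% t(R), 2, as.numeric(cr - R %*% cm), `+`)
  sqrt(mean(rowSums((moved - reference)^2)))
}

# brute-force path CV sums: d = vector of squared metric distances
naive_sz <- function(d, lambda) {
  N <- length(d)
  w <- exp(-lambda * d)
  list(s = sum((seq_len(N) - 1) * w) / ((N - 1) * sum(w)),
       z = -log(sum(w)) / lambda)
}

# per-pair loop Pearson cross-correlation of 3-vector displacements
naive_dccm <- function(frames, idx) {
  nf <- length(frames)
  n <- length(idx)
  devs <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- t(vapply(frames, function(f) f[idx[i], ], numeric(3)))
    devs[[i]] <- sweep(xi, 2, colMeans(xi))
  }
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- mean(rowSums(devs[[i]] * devs[[j]]))
    den <- sqrt(mean(rowSums(devs[[i]]^2)) * mean(rowSums(devs[[j]]^2)))
    C[i, j] <- num / den
  }
  C
}

# naive O(n^2) PSN edge construction with an explicit normalization table
naive_psn_edges <- function(s, cutoff, i_min, norm, exclude = 1) {
  atoms <- s$atoms
  side <- which(!(atoms$name %in% c("N", "CA", "C", "O", "OXT")) &
                  atoms$element != "H")
  res <- unique(atoms$resid)
  edges <- NULL
  for (a in seq_along(res)) for (b in seq_along(res)) {
    if (b <= a) next
    if (abs(res[a] - res[b]) <= exclude) next
    ia <- side[atoms$resid[side] == res[a]]
    ib <- side[atoms$resid[side] == res[b]]
    nij <- 0
    for (i in ia) for (j in ib) {
      if (sqrt(sum((s$coords[i, ] - s$coords[j, ])^2)) <= cutoff)
        nij <- nij + 1
    }
    I <- nij / sqrt(norm[atoms$resname[match(res[a], atoms$resid)]] *
                      norm[atoms$resname[match(res[b], atoms$resid)]]) * 100
    if (nij > 0 && I >= i_min)
      edges <- rbind(edges, data.frame(res_i = paste0("A:", res[a]),
                                       res_j = paste0("A:", res[b]),
                                       strength = I))
  }
  edges
}

# exhaustive enumeration of simple paths between two nodes of a small
# edge list; returns the path maximizing the product of edge frequencies
best_path_bruteforce <- function(edges, source, sink) {
  adj <- list()
  for (k in seq_len(nrow(edges))) {
    i <- edges$res_i[k]; j <- edges$res_j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  fkey <- function(i, j) paste(min(i, j), max(i, j))
  fr <- setNames(edges$frequency, mapply(fkey, edges$res_i, edges$res_j))
  best <- list(freq = -1, path = NULL)
  walk <- function(node, seen, freq) {
    if (node == sink) {
      if (freq > best$freq) best <<- list(freq = freq, path = seen)
      return()
    }
    for (nb in adj[[node]]) {
      if (nb %in% seen) next
      walk(nb, c(seen, nb), freq * fr[[fkey(node, nb)]])
    }
  }
  if (!source %in% names(adj) || !sink %in% names(adj)) return(best)
  walk(source, source, 1)
  best
}

# minimal hand-rolled PDB text for parser tests
write_tiny_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          occ = 1, b = 0, alt = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resid, x, y, z, occ, b, element)
}

# a complete synthetic C-alpha chain of n residues (helix-like geometry)
make_ca_chain <- function(n) {
  ang <- (seq_len(n) - 1) * 100 * pi / 180
  co <- cbind(2.3 * cos(ang), 2.3 * sin(ang), (seq_len(n) - 1) * 1.5)
  structure_model(
    data.frame(serial = seq_len(n), name = "CA", resname = "ALA",
               resid = seq_len(n), chain = "A", element = "C"), co)
}
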