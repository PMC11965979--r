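# ---------------------------------------------------------------------------
# Protein structure networks: residues as nodes, edges weighted by the
# normalized side-chain contact count
#   I_ij = n_ij / sqrt(N_i N_j) * 100   (percent),
# filtered at a minimum interaction strength I_min; hubs, and
# cross-frame metapaths.
# ---------------------------------------------------------------------------

#' PSN construction parameters
#'
#' @param atom_cutoff side-chain atom distance cutoff, Angstrom
#'   (default 4.5).
#' @param i_min minimum interaction strength, percent (default 3).
#' @param normalization optional named vector of per-residue-type
#'   normalization factors; when `NULL` they are self-calibrated from
#'   the input ensemble (mean side-chain contact count per residue
#'   type).
#' @param exclude sequence-neighbor exclusion span: residues with
#'   `|i - j| <= exclude` in the same chain never form an edge
#'   (default 1).
#' @return list of class `PSNParams`.
#' @export
psn_params <- function(atom_cutoff = 4.5, i_min = 3, normalization = NULL,
                       exclude = 1L) {
  if (atom_cutoff <= 0) stop("atom_cutoff must be positive")
  if (!is.null(normalization) && any(normalization <= 0))
    stop("normalization factors must be positive")
  out <- list(atom_cutoff = atom_cutoff, i_min = i_min,
              normalization = normalization, exclude = as.integer(exclude))
  class(out) <- "PSNParams"
  out
}

#' Interaction strength between two residues
#'
#' `I_ij = n_ij / sqrt(N_i N_j) * 100`, in percent.
#'
#' @param n_ij number of side-chain atom pairs within the cutoff (>= 0).
#' @param n_i,n_j normalization factors (> 0).
#' @return percent.
#' @export
interaction_strength <- function(n_ij, n_i, n_j) {
  if (any(n_i <= 0) || any(n_j <= 0)) stop("normalization factors must be positive")
  if (any(n_ij < 0)) stop("pair counts must be non-negative")
  n_ij / sqrt(n_i * n_j) * 100
}

BACKBONE <- c("N", "CA", "C", "O", "OXT")

# per-frame raw side-chain pair counts between residues
psn_pair_counts <- function(atoms, coords, cutoff, exclude) {
  side <- which(!(atoms$name %in% BACKBONE) & atoms$element != "H")
  if (length(side) == 0) return(NULL)
  res_key <- paste(atoms$chain, atoms$resid, sep = ":")
  ids <- unique(res_key)
  co <- coords[side, , drop = FALSE]
  rk <- res_key[side]
  dm <- as.matrix(dist(co))
  within <- dm <= cutoff
  diag(within) <- FALSE
  hit <- which(within & upper.tri(within), arr.ind = TRUE)
  if (nrow(hit) == 0) return(list(counts = NULL, ids = ids))
  ri <- rk[hit[, 1]]; rj <- rk[hit[, 2]]
  same <- ri == rj
  ri <- ri[!same]; rj <- rj[!same]
  # sequence-neighbor exclusion within a chain
  spl_i <- strsplit(ri, ":"); spl_j <- strsplit(rj, ":")
  ch_i <- vapply(spl_i, `[`, "", 1); ch_j <- vapply(spl_j, `[`, "", 1)
  no_i <- as.integer(vapply(spl_i, `[`, "", 2))
  no_j <- as.integer(vapply(spl_j, `[`, "", 2))
  keep <- !(ch_i == ch_j & abs(no_i - no_j) <= exclude)
  if (!any(keep)) return(list(counts = NULL, ids = ids))
  # canonical pair order: by chain, then numeric residue number
  first <- ch_i[keep] < ch_j[keep] |
    (ch_i[keep] == ch_j[keep] & no_i[keep] < no_j[keep])
  key <- paste(ifelse(first, ri[keep], rj[keep]),
               ifelse(first, rj[keep], ri[keep]), sep = "|")
  counts <- table(key)
  list(counts = counts, ids = ids)
}

#' Build a protein structure graph
#'
#' Counts side-chain atom pairs (backbone N, CA, C, O excluded) within
#' `atom_cutoff` for every residue pair, converts the counts to
#' interaction strengths and keeps edges with `I_ij >= i_min`.  On a
#' trajectory, per-frame graphs are built and merged into a consensus
#' graph whose edges carry an occurrence `frequency` and the mean
#' strength over the frames where present.
#'
#' @param x Structure or Trajectory.
#' @param params PSNParams.
#' @return object of class `PSNGraph`: `nodes` (data.frame), `edges`
#'   (res_i, res_j, strength, frequency), `normalization`, `params`,
#'   and for trajectories `frames` (list of per-frame edge data.frames).
#' @export
build_psg <- function(x, params = psn_params()) {
  structures <- if (inherits(x, "Trajectory")) {
    lapply(x$frames, function(f) list(atoms = x$topology$atoms, coords = f))
  } else list(list(atoms = x$atoms, coords = x$coords))
  atoms <- structures[[1]]$atoms
  per_frame_counts <- lapply(structures, function(s)
    psn_pair_counts(s$atoms, s$coords, params$atom_cutoff, params$exclude))
  ids <- unique(paste(atoms$chain, atoms$resid, sep = ":"))
  restype <- setNames(atoms$resname[!duplicated(paste(atoms$chain, atoms$resid,
                                                      sep = ":"))], ids)
  if (all(vapply(per_frame_counts, function(p) is.null(p$counts), logical(1)))) {
    warning("no side-chain contacts found (poly-glycine input?): empty graph")
    empty <- data.frame(res_i = character(0), res_j = character(0),
                        strength = numeric(0), frequency = numeric(0))
    out <- list(nodes = data.frame(id = ids, resname = restype[ids]),
                edges = empty, normalization = NULL, params = params,
                frames = NULL)
    class(out) <- "PSNGraph"
    return(out)
  }
  # normalization: user table, else self-calibrated mean side-chain
  # contact count per residue type over the ensemble
  norm <- params$normalization
  if (is.null(norm)) {
    totals <- list()
    for (p in per_frame_counts) {
      if (is.null(p$counts)) next
      for (k in seq_along(p$counts)) {
        pair <- strsplit(names(p$counts)[k], "|", fixed = TRUE)[[1]]
        for (r in pair)
          totals[[r]] <- (totals[[r]] %||% 0) + p$counts[[k]]
      }
    }
    per_res <- setNames(numeric(length(ids)), ids)
    per_res[names(totals)] <- unlist(totals) / length(structures)
    norm <- tapply(per_res, restype[names(per_res)], mean)
    norm <- pmax(norm, 1)
  }
  nfactor <- function(res) unname(norm[restype[res]])
  frame_edges <- lapply(per_frame_counts, function(p) {
    if (is.null(p$counts) || length(p$counts) == 0)
      return(data.frame(res_i = character(0), res_j = character(0),
                        strength = numeric(0)))
    pair <- do.call(rbind, strsplit(names(p$counts), "|", fixed = TRUE))
    I <- interaction_strength(as.numeric(p$counts), nfactor(pair[, 1]),
                              nfactor(pair[, 2]))
    keep <- I >= params$i_min
    data.frame(res_i = pair[keep, 1], res_j = pair[keep, 2],
               strength = I[keep])
  })
  all_keys <- unique(unlist(lapply(frame_edges, function(fe)
    paste(fe$res_i, fe$res_j, sep = "|"))))
  nf <- length(frame_edges)
  if (length(all_keys)) {
    freq <- setNames(numeric(length(all_keys)), all_keys)
    ssum <- setNames(numeric(length(all_keys)), all_keys)
    for (fe in frame_edges) {
      k <- paste(fe$res_i, fe$res_j, sep = "|")
      freq[k] <- freq[k] + 1
      ssum[k] <- ssum[k] + fe$strength
    }
    pair <- do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
    edges <- data.frame(res_i = pair[, 1], res_j = pair[, 2],
                        strength = ssum / freq, frequency = freq / nf)
    edges <- edges[order(edges$res_i, edges$res_j), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(res_i = character(0), res_j = character(0),
                        strength = numeric(0), frequency = numeric(0))
  }
  out <- list(nodes = data.frame(id = ids, resname = unname(restype[ids])),
              edges = edges, normalization = norm, params = params,
              frames = if (nf > 1) frame_edges else NULL)
  class(out) <- "PSNGraph"
  out
}

#' @export
print.PSNGraph <- function(x, ...) {
  cat(sprintf("PSNGraph: %d nodes, %d edges (I_min = %g%%)\n",
              nrow(x$nodes), nrow(x$edges), x$params$i_min))
  invisible(x)
}

as_igraph <- function(g, weight = c("strength", "frequency")) {
  weight <- match.arg(weight)
  if (nrow(g$edges) == 0)
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(g$nodes$id))
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = g$nodes$id)
  igraph::E(ig)$weight <- g$edges[[weight]]
  ig
}

#' Hub residues of a PSN
#'
#' Residues engaging at least `min_degree` edges (default 4), sorted by
#' decreasing degree then residue id.
#'
#' @param g PSNGraph; @param min_degree integer.
#' @return data.frame (id, degree).
#' @export
find_hubs <- function(g, min_degree = 4) {
  if (nrow(g$edges) == 0)
    return(data.frame(id = character(0), degree = integer(0)))
  deg <- table(c(g$edges$res_i, g$edges$res_j))
  hubs <- deg[deg >= min_degree]
  out <- data.frame(id = names(hubs), degree = as.integer(hubs))
  out[order(-out$degree, out$id), , drop = FALSE]
}

#' Most recurrent communication path across frames (metapath)
#'
#' Edges are weighted by their occurrence frequency across the
#' per-frame graphs; edges below `freq_min` are dropped, shortest paths
#' between source and sink computed with edge weight `-ln(frequency)`
#' (so the minimum-weight path maximizes the product of edge
#' frequencies), and paths ranked by that cumulative frequency.
#'
#' @param frames list of PSNGraph (one per frame) or a consensus
#'   PSNGraph built from a trajectory.
#' @param source,sink residue ids ("chain:resid").
#' @param freq_min minimum edge frequency (default 0.5).
#' @param k number of alternative paths to rank (default 5).
#' @return data.frame (rank, path, frequency); zero rows when source
#'   and sink are disconnected, with a `diagnostic` attribute.
#' @export
metapath <- function(frames, source, sink, freq_min = 0.5, k = 5) {
  if (inherits(frames, "PSNGraph")) {
    g <- frames
    if (is.null(g$frames) && nrow(g$edges) > 0 &&
        all(g$edges$frequency == 1) && length(unique(g$edges$frequency)) == 1) {
      # single-structure graph: every edge has frequency 1
    }
    edges <- g$edges
    nodes <- g$nodes$id
  } else {
    if (length(frames) < 2) stop("need at least 2 frames")
    nf <- length(frames)
    tab <- list()
    for (fr in frames) {
      key <- paste(fr$edges$res_i, fr$edges$res_j, sep = "|")
      for (kk in key) tab[[kk]] <- (tab[[kk]] %||% 0) + 1
    }
    if (length(tab)) {
      pair <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
      edges <- data.frame(res_i = pair[, 1], res_j = pair[, 2],
                          strength = NA_real_,
                          frequency = unlist(tab) / nf)
    } else {
      edges <- data.frame(res_i = character(0), res_j = character(0),
                          strength = numeric(0), frequency = numeric(0))
    }
    nodes <- unique(unlist(lapply(frames, function(f) f$nodes$id)))
  }
  edges <- edges[edges$frequency >= freq_min, , drop = FALSE]
  empty <- data.frame(rank = integer(0), path = character(0),
                      frequency = numeric(0))
  if (!all(c(source, sink) %in% nodes)) {
    attr(empty, "diagnostic") <- "source or sink not in graph"
    return(empty)
  }
  if (nrow(edges) == 0) {
    attr(empty, "diagnostic") <- "no edges above freq_min"
    return(empty)
  }
  ig <- igraph::graph_from_data_frame(edges[, c("res_i", "res_j")],
                                      directed = FALSE, vertices = nodes)
  igraph::E(ig)$weight <- -log(edges$frequency) + 1e-12
  ks <- tryCatch(
    suppressWarnings(igraph::k_shortest_paths(ig, from = source,
                                              to = sink, k = k)),
    error = function(e) NULL)
  if (is.null(ks) || length(ks$vpaths) == 0) {
    attr(empty, "diagnostic") <- "source and sink disconnected"
    return(empty)
  }
  paths <- vapply(ks$vpaths, function(p) paste(names(p), collapse = " -> "), "")
  freqs <- vapply(ks$epaths, function(ep)
    exp(-sum(igraph::E(ig)$weight[ep])), numeric(1))
  ord <- order(-freqs)
  data.frame(rank = seq_along(ord), path = paths[ord],
             frequency = freqs[ord])
}

#' Export a PSN as an edge-list TSV (and optionally GraphML)
#'
#' @param g PSNGraph; @param path TSV output file;
#' @param graphml optional GraphML output file.
#' @return `path`, invisibly.
#' @export
write_psn <- function(g, path, graphml = NULL) {
  write.table(g$edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(g), graphml, format = "graphml")
  invisible(path)
}
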