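#' Displacement cross-correlation matrix
#'
#' Frames are least-squares superposed onto the mean structure (one
#' iteration: fit to the first frame, recompute the mean, refit), then
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` over the node atoms,
#' with `dr_i = r_i(t) - <r_i>`.
#'
#' @param traj A [trajectory()] with at least 10 frames.
#' @param node_atoms Atom indices serving as nodes (e.g. one Calpha-like
#'   atom per residue).
#' @param fit Superpose frames before computing displacements.
#' @param fit_set Atom indices used for the fit (default: `node_atoms`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
displacement_correlation <- function(traj, node_atoms, fit = TRUE,
                                     fit_set = node_atoms) {
  nf <- length(traj$frames)
  if (nf < 10) stop("need at least 10 frames, got ", nf)
  frames <- traj$frames
  if (fit) {
    frames <- lapply(frames, function(f) {
      superpose(f, frames[[1]], fit_set)$frame
    })
    mean_frame <- Reduce(`+`, frames) / nf
    frames <- lapply(frames, function(f) {
      superpose(f, mean_frame, fit_set)$frame
    })
  }
  n <- length(node_atoms)
  coords <- vapply(frames, function(f) {
    as.vector(t(f[node_atoms, , drop = FALSE]))  # x1 y1 z1 x2 ...
  }, numeric(3 * n))                              # (3n) x nf
  mu <- rowMeans(coords)
  d <- coords - mu
  cov3 <- matrix(0, n, n)
  for (ax in 1:3) {
    da <- d[seq(ax, 3 * n, by = 3), , drop = FALSE]
    cov3 <- cov3 + tcrossprod(da) / nf
  }
  v <- diag(cov3)
  if (any(v <= 0)) {
    stop("zero-variance node(s): ",
         paste(node_atoms[v <= 0], collapse = ", "))
  }
  C <- cov3 / sqrt(outer(v, v))
  diag(C) <- 1
  dimnames(C) <- list(node_atoms, node_atoms)
  C
}

#' Residue contact adjacency from a trajectory
#'
#' Residues are adjacent when the contact criterion holds in at least
#' `occupancy_min` of the frames. Default criterion: any-heavy-atom
#' residue-residue minimum distance `<= cutoff` (the standard dynamical
#' network convention); `calpha_strict = TRUE` instead applies the cutoff
#' to the node (Calpha) atoms themselves, the literal reading of the
#' 4.5-A rule.
#'
#' @param system A `molecular_system`.
#' @param traj A [trajectory()].
#' @param cutoff Contact distance, Angstrom (default 4.5).
#' @param occupancy_min Minimum fraction of frames (default 0.75).
#' @param calpha_strict Use node-atom distances instead of any-heavy-atom
#'   distances.
#' @param node_atoms One atom per residue (required when
#'   `calpha_strict = TRUE`; defaults to each residue's first heavy atom).
#' @param exclude_sequential Drop pairs within this many sequence
#'   positions (default 0: keep all).
#' @return List: `adjacency` (logical residue x residue matrix),
#'   `occupancy` (numeric matrix), `residue_ids`.
#' @export
contact_adjacency <- function(system, traj, cutoff = 4.5,
                              occupancy_min = 0.75,
                              calpha_strict = FALSE, node_atoms = NULL,
                              exclude_sequential = 0) {
  a <- system$atoms
  res_ids <- unique(a$residue_id)
  nres <- length(res_ids)
  heavy <- which(is_heavy(a$element))
  if (is.null(node_atoms)) {
    node_atoms <- vapply(res_ids, function(r) {
      intersect(which(a$residue_id == r), heavy)[1]
    }, integer(1))
  }
  hits <- matrix(0, nres, nres)
  for (frame in traj$frames) {
    if (calpha_strict) {
      d <- as.matrix(stats::dist(frame[node_atoms, , drop = FALSE]))
      hits <- hits + (d <= cutoff)
    } else {
      dh <- as.matrix(stats::dist(frame[heavy, , drop = FALSE]))
      rh <- match(a$residue_id[heavy], res_ids)
      close <- dh <= cutoff
      for (p in seq_len(nres)) {
        rows <- rh == p
        for (q in seq_len(nres)) {
          if (q <= p) next
          if (any(close[rows, rh == q])) {
            hits[p, q] <- hits[p, q] + 1
            hits[q, p] <- hits[q, p] + 1
          }
        }
      }
    }
  }
  occ <- hits / length(traj$frames)
  diag(occ) <- 0
  adj <- occ >= occupancy_min
  if (exclude_sequential > 0) {
    seq_d <- abs(outer(res_ids, res_ids, "-"))
    adj[seq_d <= exclude_sequential] <- FALSE
  }
  diag(adj) <- FALSE
  dimnames(adj) <- dimnames(occ) <- list(res_ids, res_ids)
  list(adjacency = adj, occupancy = occ, residue_ids = res_ids)
}

#' Build the residue contact graph
#'
#' Edges connect adjacent node pairs with weight `d_ij = -log |C_ij|`
#' (natural logarithm; `|C_ij|` floored at 1e-12). Negative correlations
#' enter through their absolute value and are flagged on the edge.
#'
#' @param C Correlation matrix over the nodes.
#' @param adjacency Logical adjacency matrix on the same nodes (e.g. from
#'   [contact_adjacency()]), or its enclosing list.
#' @param node_ids Optional node labels (default: adjacency row names).
#' @return An undirected `igraph` graph of class `contact_graph` with edge
#'   attributes `correlation`, `weight` (= d_ij), `negative`, and
#'   `occupancy` when available.
#' @export
build_network <- function(C, adjacency, node_ids = NULL) {
  occ <- NULL
  if (is.list(adjacency) && !is.matrix(adjacency)) {
    occ <- adjacency$occupancy
    adjacency <- adjacency$adjacency
  }
  if (!all(dim(C) == dim(adjacency))) {
    stop("C and adjacency must be on the same node set")
  }
  if (is.null(node_ids)) {
    node_ids <- rownames(adjacency) %||% as.character(seq_len(nrow(C)))
  }
  idx <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  cc <- C[idx]
  d <- -log(pmax(abs(cc), 1e-12))
  g <- igraph::graph_from_data_frame(
    data.frame(from = node_ids[idx[, 1]], to = node_ids[idx[, 2]],
               correlation = cc, weight = d, negative = cc < 0,
               occupancy = if (is.null(occ)) NA_real_ else occ[idx]),
    directed = FALSE,
    vertices = data.frame(name = node_ids)
  )
  class(g) <- c("contact_graph", class(g))
  g
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of maximum betweenness (edge weights
#' `d_ij` act as distances) and keeps the partition of maximum modularity
#' over the resulting dendrogram. Ties in modularity resolve to the
#' earliest (coarsest) partition, which is deterministic.
#'
#' @param graph A `contact_graph` (or any undirected igraph graph).
#' @return A tibble of class `community_partition` (`node`, `community`)
#'   with attributes `modularity` and `n_communities`.
#' @export
girvan_newman <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  ceb <- igraph::cluster_edge_betweenness(
    graph, weights = igraph::E(graph)$weight, modularity = FALSE,
    membership = FALSE)
  n <- igraph::vcount(graph)
  n_comp <- igraph::count_components(graph)
  ks <- seq(n_comp, n)
  best <- NULL
  best_q <- -Inf
  for (k in ks) {
    memb <- igraph::cut_at(ceb, no = k)
    q <- igraph::modularity(graph, memb)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  out <- tibble::tibble(node = igraph::V(graph)$name,
                        community = as.integer(best))
  class(out) <- c("community_partition", class(out))
  attr(out, "modularity") <- best_q
  attr(out, "n_communities") <- length(unique(best))
  out
}

#' Optimal (and suboptimal) communication paths
#'
#' Minimum total `d_ij` path between two nodes on the contact graph;
#' optionally the next `n_suboptimal` shortest simple paths.
#'
#' @param graph A `contact_graph`.
#' @param source,sink Node names (or indices).
#' @param n_suboptimal Number of additional paths (default 0).
#' @return A tibble of class `path_result` (`rank`, `nodes` list-column,
#'   `length`); zero rows with attribute `found = FALSE` when source and
#'   sink are disconnected.
#' @export
optimal_path <- function(graph, source, sink, n_suboptimal = 0) {
  source <- as.character(source); sink <- as.character(sink)
  if (source == sink) {
    out <- tibble::tibble(rank = 1L, nodes = list(source), length = 0)
  } else {
    # igraph warns when sink is unreachable; we return an explicit
    # no-path result instead
    ks <- suppressWarnings(
      igraph::k_shortest_paths(graph, from = source, to = sink,
                               k = n_suboptimal + 1,
                               weights = igraph::E(graph)$weight))
    if (length(ks$vpaths) == 0) {
      out <- tibble::tibble(rank = integer(), nodes = list(),
                            length = numeric())
      class(out) <- c("path_result", class(out))
      attr(out, "found") <- FALSE
      return(out)
    }
    lens <- vapply(ks$epaths, function(ep) {
      sum(igraph::E(graph)$weight[as.integer(ep)])
    }, numeric(1))
    out <- tibble::tibble(
      rank = seq_along(ks$vpaths),
      nodes = lapply(ks$vpaths, function(vp) igraph::V(graph)$name[vp]),
      length = lens
    )
  }
  class(out) <- c("path_result", class(out))
  attr(out, "found") <- TRUE
  out
}

#' Export a contact graph as an edge-list table
#'
#' @param graph A `contact_graph`.
#' @param path Optional output path (tab-separated text).
#' @return The edge tibble (`node_i`, `node_j`, `correlation`, `d_ij`,
#'   `occupancy`), invisibly written to `path` when given.
#' @export
export_edges <- function(graph, path = NULL) {
  el <- igraph::as_data_frame(graph, what = "edges")
  out <- tibble::tibble(node_i = el$from, node_j = el$to,
                        correlation = el$correlation,
                        d_ij = el$weight, occupancy = el$occupancy)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(out)
}
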