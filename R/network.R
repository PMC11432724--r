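#' Build a correlation-weighted residue interaction network
#'
#' Nodes are residues; an undirected edge joins every pair flagged in the
#' contact-persistence adjacency, weighted by the communication distance
#' `w_ij = -log R(X_i, X_j)` derived from the generalized correlation, so
#' strongly correlated contacts are short links for information flow.
#' `R >= 1 - 1e-12` is clamped (weight floor 1e-12, keeping weights
#' positive); `R = 0` edges are dropped with a warning (infinite distance).
#'
#' @param persistence a `persistence_matrix` from [contact_persistence()].
#' @param gc a `correlation_matrix` (normally `kind = "gc"`) on the same
#'   residues.
#' @return a `residue_network`: list with `resid`, `edges` (data.frame
#'   `i`, `j` node indices, `resid_i`, `resid_j`, `R`, `weight`) and
#'   `n_nodes`.
#' @export
build_network <- function(persistence, gc) {
  stopifnot(inherits(persistence, "persistence_matrix"),
            inherits(gc, "correlation_matrix"))
  if (!identical(persistence$resid, gc$resid))
    stop("persistence and correlation matrices cover different residues",
         call. = FALSE)
  adj <- persistence$adjacency
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  R <- gc$matrix[idx]
  dropped <- R <= 0
  if (any(dropped))
    warning(sum(dropped), " edge(s) with R = 0 dropped (infinite distance)")
  idx <- idx[!dropped, , drop = FALSE]
  R <- R[!dropped]
  Rc <- pmin(R, 1 - 1e-12)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      resid_i = gc$resid[idx[, 1]],
                      resid_j = gc$resid[idx[, 2]],
                      R = R, weight = pmax(-log(Rc), 1e-12))
  structure(list(resid = gc$resid, edges = edges,
                 n_nodes = length(gc$resid)),
            class = "residue_network")
}

#' @export
print.residue_network <- function(x, ...) {
  cat(sprintf("<residue_network> %d nodes, %d edges; weight range [%.3g, %.3g]\n",
              x$n_nodes, nrow(x$edges),
              if (nrow(x$edges)) min(x$edges$weight) else NA,
              if (nrow(x$edges)) max(x$edges$weight) else NA))
  invisible(x)
}

# dense weight matrix (Inf off-edges) for the shortest-path kernel
network_weight_matrix <- function(network, keep_edges = NULL) {
  W <- matrix(Inf, network$n_nodes, network$n_nodes)
  e <- network$edges
  if (!is.null(keep_edges)) e <- e[keep_edges, , drop = FALSE]
  W[cbind(e$i, e$j)] <- e$weight
  W[cbind(e$j, e$i)] <- e$weight
  diag(W) <- 0
  W
}

#' All-pairs shortest paths with path counts
#'
#' Runs Floyd-Warshall on the communication-distance matrix, returning all
#' pairwise shortest distances together with the number of co-optimal
#' shortest paths per pair (ties within 1e-9 on path length all counted).
#' Disconnected pairs carry infinite distance and a count of 0.
#'
#' @param network a `residue_network`.
#' @return a `shortest_path_ensemble`: list with `dist` and `counts`
#'   (node x node matrices) and `resid`.
#' @export
shortest_paths <- function(network) {
  stopifnot(inherits(network, "residue_network"))
  if (any(network$edges$weight <= 0))
    stop("internal error: non-positive edge weight", call. = FALSE)
  fw <- cpp_floyd_warshall(network_weight_matrix(network))
  structure(list(dist = fw$dist, counts = fw$counts, resid = network$resid),
            class = "shortest_path_ensemble")
}

#' Betweenness centrality profile with Z-score hotspot calling
#'
#' Node betweenness is the sum over residue pairs of the fraction of
#' shortest paths passing through the node (endpoints excluded; pairs are
#' summed within connected components). Z-scores standardize the raw
#' centralities over all nodes, and residues with `Z >= z_threshold`
#' (default 2) are called high-centrality allosteric hotspots. When every
#' node has equal centrality the Z-scores are all 0 and no hotspots are
#' called, with a warning.
#'
#' @param paths a `shortest_path_ensemble` from [shortest_paths()].
#' @param z_threshold hotspot cutoff on the Z-score.
#' @return a `centrality_profile`: list with `profile` (data.frame `resid`,
#'   `betweenness`, `z`), `hotspots` (residue ids), `z_threshold`.
#' @export
betweenness_profile <- function(paths, z_threshold = 2) {
  stopifnot(inherits(paths, "shortest_path_ensemble"))
  cb <- cpp_node_betweenness(paths$dist, paths$counts)
  sdev <- sd(cb)
  if (!is.finite(sdev) || sdev == 0) {
    warning("all nodes have equal centrality; Z-scores set to 0, no hotspots")
    z <- rep(0, length(cb))
  } else {
    z <- (cb - mean(cb)) / sdev
  }
  profile <- data.frame(resid = paths$resid, betweenness = cb, z = z)
  structure(list(profile = profile,
                 hotspots = paths$resid[z >= z_threshold],
                 z_threshold = z_threshold),
            class = "centrality_profile")
}

# connected-component membership from a finite-distance matrix
components_from_dist <- function(d) {
  n <- nrow(d)
  membership <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      comp <- comp + 1L
      membership[is.finite(d[i, ])] <- comp
      membership[i] <- comp
    }
  }
  membership
}

# Newman modularity of a partition on the (unweighted) edge set
modularity_q <- function(edges, membership) {
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- tabulate(c(edges$i, edges$j), nbins = length(membership))
  same <- membership[edges$i] == membership[edges$j]
  q <- 0
  for (c in unique(membership)) {
    e_c <- sum(same & membership[edges$i] == c) / m
    d_c <- sum(deg[membership == c]) / (2 * m)
    q <- q + e_c - d_c^2
  }
  q
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of maximum weighted edge betweenness,
#' recomputing shortest paths after every removal, and returns the
#' partition (connected components) that maximizes Newman modularity along
#' the removal dendrogram. Modularity is evaluated on the original
#' (unweighted) edge set; a fully connected graph whose best partition is a
#' single community yields modularity 0.
#'
#' @param network a `residue_network` with at least 2 nodes.
#' @return a `community_partition`: list with `membership` (community id
#'   per node, named by residue id), `modularity`, `n_communities`, and
#'   `removals` (data.frame of removed edges in order, with the modularity
#'   of the partition after each removal).
#' @export
detect_communities <- function(network) {
  stopifnot(inherits(network, "residue_network"))
  n <- network$n_nodes
  if (n < 2) {
    return(structure(list(membership = setNames(rep(1L, n), network$resid),
                          modularity = 0, n_communities = max(n, 1L),
                          removals = NULL),
                     class = "community_partition"))
  }
  edges <- network$edges
  alive <- rep(TRUE, nrow(edges))
  fw <- cpp_floyd_warshall(network_weight_matrix(network))
  best_membership <- components_from_dist(fw$dist)
  best_q <- modularity_q(edges, best_membership)
  removals <- list()
  step <- 0L
  while (any(alive)) {
    idx_alive <- which(alive)
    eb <- cpp_edge_betweenness(fw$dist, fw$counts,
                               as.matrix(edges[idx_alive, c("i", "j")]),
                               edges$weight[idx_alive])
    drop_e <- idx_alive[which.max(eb)]
    alive[drop_e] <- FALSE
    fw <- cpp_floyd_warshall(network_weight_matrix(network, keep_edges = alive))
    membership <- components_from_dist(fw$dist)
    q <- modularity_q(edges, membership)
    step <- step + 1L
    removals[[step]] <- data.frame(step = step,
                                   resid_i = edges$resid_i[drop_e],
                                   resid_j = edges$resid_j[drop_e],
                                   edge_betweenness = max(eb),
                                   modularity = q)
    if (q > best_q) {
      best_q <- q
      best_membership <- membership
    }
  }
  structure(list(membership = setNames(best_membership, network$resid),
                 modularity = best_q,
                 n_communities = length(unique(best_membership)),
                 removals = do.call(rbind, removals)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, modularity %.3f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Community bridgeness profile
#'
#' For node `i` in community `I`, the bridgeness is
#' `G_i = sum_{J != I} delta_iJ * l_IJ`, where `delta_iJ` indicates that
#' `i` has at least one edge into community `J` and
#' `l_IJ = 1 / (number of edges between I and J)` is the effective distance
#' between the communities (a Rao-Stirling-style diversity sum). Nodes
#' whose edges are all internal score exactly 0; a node providing the sole
#' link between two communities scores 1 from that pair.
#'
#' @param network a `residue_network`.
#' @param partition a `community_partition` covering all nodes (or an
#'   integer membership vector).
#' @return a `bridgeness_profile`: list with `profile` (data.frame `resid`,
#'   `community`, `bridgeness`) and `inter_links` (community x community
#'   edge counts).
#' @export
bridgeness_profile <- function(network, partition) {
  stopifnot(inherits(network, "residue_network"))
  membership <- if (inherits(partition, "community_partition"))
    partition$membership else as.integer(partition)
  if (length(membership) != network$n_nodes)
    stop("partition does not cover all nodes", call. = FALSE)
  membership <- as.integer(membership)
  comms <- sort(unique(membership))
  nc <- length(comms)
  cid <- match(membership, comms)
  e <- network$edges
  links <- matrix(0L, nc, nc, dimnames = list(comms, comms))
  for (r in seq_len(nrow(e))) {
    a <- cid[e$i[r]]; b <- cid[e$j[r]]
    if (a != b) {
      links[a, b] <- links[a, b] + 1L
      links[b, a] <- links[b, a] + 1L
    }
  }
  G <- numeric(network$n_nodes)
  for (v in seq_len(network$n_nodes)) {
    nbr <- c(e$j[e$i == v], e$i[e$j == v])
    foreign <- unique(cid[nbr])
    foreign <- foreign[foreign != cid[v]]
    for (J in foreign)
      if (links[cid[v], J] > 0) G[v] <- G[v] + 1 / links[cid[v], J]
  }
  structure(list(profile = data.frame(resid = network$resid,
                                      community = membership,
                                      bridgeness = G),
                 inter_links = links),
            class = "bridgeness_profile")
}

#' Map mutation sites onto allosteric hotspots
#'
#' Classifies each mutational site as `direct_hotspot` (the site itself is
#' a called hotspot), `proximal` (its Calpha lies within `proximity`
#' Angstrom of a hotspot Calpha in the representative conformation) or
#' `distal`. The representative conformation is by convention the first
#' model of the state's ensemble.
#'
#' @param sites integer residue ids of the mutation sites.
#' @param profile a `centrality_profile` from [betweenness_profile()].
#' @param representative a [conf_ensemble()] (first model used) or an
#'   `n x 3` matrix over the profile residues.
#' @param proximity distance cutoff, Angstrom (default 5).
#' @return a `hotspot_mapping` data.frame with `site`, `status`,
#'   `distance` (Calpha distance to the nearest hotspot, 0 for direct,
#'   NA when no hotspots were called).
#' @export
map_mutations <- function(sites, profile, representative, proximity = 5.0) {
  stopifnot(inherits(profile, "centrality_profile"))
  resid <- profile$profile$resid
  missing <- setdiff(sites, resid)
  if (length(missing))
    stop("site(s) absent from the network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  xyz <- if (inherits(representative, "conf_ensemble")) {
    model_xyz(subset_residues(representative, resid), 1L)
  } else {
    as.matrix(representative)
  }
  if (nrow(xyz) != length(resid))
    stop("representative coordinates do not match the profile residues",
         call. = FALSE)
  hot_idx <- match(profile$hotspots, resid)
  out <- data.frame(site = sites, status = NA_character_,
                    distance = NA_real_)
  for (r in seq_along(sites)) {
    s <- sites[r]
    if (s %in% profile$hotspots) {
      out$status[r] <- "direct_hotspot"; out$distance[r] <- 0
    } else if (length(hot_idx)) {
      d <- sqrt(colSums((t(xyz[hot_idx, , drop = FALSE]) -
                           xyz[match(s, resid), ])^2))
      out$distance[r] <- min(d)
      out$status[r] <- if (min(d) < proximity) "proximal" else "distal"
    } else {
      out$status[r] <- "distal"
    }
  }
  class(out) <- c("hotspot_mapping", "data.frame")
  out
}

#' Export a residue interaction network as GraphML
#'
#' Writes nodes with residue id, betweenness, Z-score, hotspot flag,
#' community and bridgeness attributes (when the corresponding profiles are
#' supplied), and weighted edges, in the GraphML dialect understood by
#' common network viewers.
#'
#' @param network a `residue_network`.
#' @param path output path.
#' @param centrality optional `centrality_profile`.
#' @param partition optional `community_partition`.
#' @param bridgeness optional `bridgeness_profile`.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, centrality = NULL,
                                  partition = NULL, bridgeness = NULL) {
  stopifnot(inherits(network, "residue_network"))
  n <- network$n_nodes
  bt <- z <- br <- rep(NA_real_, n); cm <- rep(NA_integer_, n)
  hs <- rep(FALSE, n)
  if (!is.null(centrality)) {
    bt <- centrality$profile$betweenness; z <- centrality$profile$z
    hs <- network$resid %in% centrality$hotspots
  }
  if (!is.null(partition)) cm <- as.integer(partition$membership)
  if (!is.null(bridgeness)) br <- bridgeness$profile$bridgeness
  keys <- c(
    '<key id="resid" for="node" attr.name="resid" attr.type="int"/>',
    '<key id="betweenness" for="node" attr.name="betweenness" attr.type="double"/>',
    '<key id="z" for="node" attr.name="z_score" attr.type="double"/>',
    '<key id="hotspot" for="node" attr.name="hotspot" attr.type="boolean"/>',
    '<key id="community" for="node" attr.name="community" attr.type="int"/>',
    '<key id="bridgeness" for="node" attr.name="bridgeness" attr.type="double"/>',
    '<key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '<key id="R" for="edge" attr.name="gc" attr.type="double"/>')
  fmt <- function(x) ifelse(is.na(x), "NaN", format(x, digits = 10))
  nodes <- sprintf(paste0(
    '<node id="n%d"><data key="resid">%d</data><data key="betweenness">%s</data>',
    '<data key="z">%s</data><data key="hotspot">%s</data>',
    '<data key="community">%s</data><data key="bridgeness">%s</data></node>'),
    seq_len(n), network$resid, fmt(bt), fmt(z),
    ifelse(hs, "true", "false"), ifelse(is.na(cm), "0", as.character(cm)),
    fmt(br))
  e <- network$edges
  edges <- sprintf(paste0(
    '<edge source="n%d" target="n%d"><data key="weight">%s</data>',
    '<data key="R">%s</data></edge>'),
    e$i, e$j, fmt(e$weight), fmt(e$R))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               keys,
               '<graph id="rin" edgedefault="undirected">',
               nodes, edges,
               '</graph>', '</graphml>'), path)
  invisible(path)
}
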