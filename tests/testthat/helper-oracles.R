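# Independent oracles and small fixture builders used across the suite.

# random undirected weighted graph as a dense weight matrix (Inf = no edge,
# Inf diagonal) plus its edge list
random_weight_graph <- function(n, p = 0.45, seed = 1) {
  set.seed(seed)
  W <- matrix(Inf, n, n)
  edges <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) {
        w <- round(runif(1, 0.5, 2), 2)
        W[i, j] <- W[j, i] <- w
        edges <- rbind(edges, c(i, j, w))
      }
    }
  }
  list(W = W, edges = edges)
}

# exhaustive enumeration of all minimal-length simple paths between two
# nodes (branch-and-bound DFS; exact for positive weights)
all_shortest_paths_brute <- function(W, from, to, tol = 1e-9) {
  n <- nrow(W)
  best <- Inf
  paths <- list()
  rec <- function(node, visited, len, path) {
    if (len > best + tol) return(invisible())
    if (node == to) {
      if (len < best - tol) {
        best <<- len
        paths <<- list(path)
      } else {
        paths[[length(paths) + 1L]] <<- path
      }
      return(invisible())
    }
    for (nb in which(is.finite(W[node, ]))) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        rec(nb, visited, len + W[node, nb], c(path, nb))
        visited[nb] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  rec(from, visited, 0, from)
  list(dist = best, paths = paths)
}

# betweenness by brute-force path enumeration (endpoints excluded,
# co-optimal paths share credit equally)
brute_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  cb <- numeric(n)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      r <- all_shortest_paths_brute(W, j, k, tol)
      if (!is.finite(r$dist)) next
      g <- length(r$paths)
      for (p in r$paths)
        for (i in setdiff(p, c(j, k))) cb[i] <- cb[i] + 1 / g
    }
  }
  cb
}

# residue_network built directly from an edge table (for toy graphs)
toy_network <- function(edges, n, weight = 1, R = exp(-weight)) {
  edges <- matrix(edges, ncol = 2, byrow = TRUE)
  structure(list(
    resid = seq_len(n),
    edges = data.frame(i = edges[, 1], j = edges[, 2],
                       resid_i = edges[, 1], resid_j = edges[, 2],
                       R = rep_len(R, nrow(edges)),
                       weight = rep_len(weight, nrow(edges))),
    n_nodes = n), class = "residue_network")
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nt <- comb2(sum(tab))
  expected <- si * sj / nt
  (sij - expected) / ((si + sj) / 2 - expected)
}

# flat conf_ensemble where every model is `base` plus given displacements
ensemble_from_displacements <- function(base, disp_list) {
  xyz <- lapply(disp_list, function(d) base + d)
  conf_ensemble(xyz, seq_len(nrow(base)))
}
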