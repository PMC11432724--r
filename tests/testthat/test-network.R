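test_that("network edges carry -log R communication distances", {
  base <- helix_backbone(6) # chain with i,i+2 contacts under a wide cutoff
  ens <- ensemble_from_displacements(base, rep(list(matrix(0, 6, 3)), 4))
  pers <- contact_persistence(ens, cutoff = 7.5)
  gcm <- structure(list(matrix = matrix(exp(-1), 6, 6), resid = 1:6,
                        kind = "gc", estimator = "manual", n_models = 4),
                   class = "correlation_matrix")
  diag(gcm$matrix) <- 1
  gcm$matrix[1, 3] <- gcm$matrix[3, 1] <- 1      # saturated pair
  gcm$matrix[2, 4] <- gcm$matrix[4, 2] <- 0      # uninformative pair
  expect_warning(net <- build_network(pers, gcm), "R = 0")

  e13 <- net$edges[net$edges$i == 1 & net$edges$j == 3, ]
  expect_equal(e13$weight, 1e-12)               # floor at R ~ 1
  e <- net$edges[net$edges$i == 1 & net$edges$j == 3, ]
  expect_equal(nrow(net$edges[net$edges$i == 2 & net$edges$j == 4, ]), 0)
  other <- net$edges[!(net$edges$i == 1 & net$edges$j == 3), ]
  expect_true(all(abs(other$weight - 1) < 1e-12))  # -log(e^-1) = 1
  # edge count: adjacency pairs with R > 0
  expect_equal(nrow(net$edges), sum(pers$adjacency[upper.tri(pers$adjacency)]) - 1)
})

test_that("shortest paths and counts match hand counts and an igraph oracle", {
  # path graph a-b-c
  p <- shortest_paths(toy_network(c(1, 2, 2, 3), 3))
  expect_equal(p$dist[1, 3], 2)
  expect_equal(p$counts[1, 3], 1)

  # 4-cycle: two co-optimal routes between opposite corners
  sq <- shortest_paths(toy_network(c(1, 2, 2, 3, 3, 4, 4, 1), 4))
  expect_equal(sq$dist[1, 3], 2)
  expect_equal(sq$counts[1, 3], 2)
  expect_equal(sq$counts[2, 4], 2)

  skip_if_not_installed("igraph")
  for (s in 1:25) {
    g <- random_weight_graph(sample(4:8, 1), seed = 100 + s)
    if (is.null(g$edges) || nrow(g$edges) < 2) next
    fw <- alloscan:::cpp_floyd_warshall(g$W)
    ig <- igraph::make_graph(t(g$edges[, 1:2, drop = FALSE]),
                             n = nrow(g$W), directed = FALSE)
    D <- igraph::distances(ig, weights = g$edges[, 3])
    expect_equal(fw$dist, unname(D), tolerance = 1e-9)
  }
})

test_that("betweenness matches closed forms on path and star graphs", {
  # 5-node path: center lies on the 4 paths {1,4},{1,5},{2,4},{2,5}
  path5 <- toy_network(c(1, 2, 2, 3, 3, 4, 4, 5), 5)
  prof <- betweenness_profile(shortest_paths(path5), z_threshold = 2)
  expect_equal(prof$profile$betweenness, c(0, 3, 4, 3, 0))

  # star: the hub carries every leaf pair, n(n-1)/2
  n_leaves <- 7
  star <- toy_network(as.vector(rbind(1, 1 + seq_len(n_leaves))),
                      n_leaves + 1)
  hub <- betweenness_profile(shortest_paths(star))
  expect_equal(hub$profile$betweenness[1], n_leaves * (n_leaves - 1) / 2)
  expect_true(all(hub$profile$betweenness[-1] == 0))
  expect_identical(hub$hotspots, 1L)  # hub is the lone Z >= 2 outlier

  # Z-scores standardize exactly over nodes
  z <- prof$profile$z
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  # regular graph: all centralities equal, no hotspots, warning
  ring <- toy_network(c(1, 2, 2, 3, 3, 4, 4, 5, 5, 1), 5)
  expect_warning(flat <- betweenness_profile(shortest_paths(ring)),
                 "equal centrality")
  expect_length(flat$hotspots, 0)
})

test_that("betweenness equals brute-force path enumeration on random graphs", {
  for (s in 1:20) {
    g <- random_weight_graph(sample(4:8, 1), seed = 200 + s)
    if (is.null(g$edges)) next
    fw <- alloscan:::cpp_floyd_warshall(g$W)
    ours <- alloscan:::cpp_node_betweenness(fw$dist, fw$counts)
    expect_equal(ours, brute_betweenness(g$W), tolerance = 1e-9)
  }
})

test_that("edge removal never shortens any path (monotonicity)", {
  g <- random_weight_graph(7, p = 0.6, seed = 300)
  fw0 <- alloscan:::cpp_floyd_warshall(g$W)
  for (e in seq_len(nrow(g$edges))) {
    W2 <- g$W
    W2[g$edges[e, 1], g$edges[e, 2]] <- Inf
    W2[g$edges[e, 2], g$edges[e, 1]] <- Inf
    fw2 <- alloscan:::cpp_floyd_warshall(W2)
    expect_true(all(fw2$dist >= fw0$dist - 1e-12))
  }
})

test_that("community detection recovers canonical and planted partitions", {
  # two 5-cliques joined by a single edge
  cl <- function(off) t(combn(off + 1:5, 2))
  e <- rbind(cl(0), cl(5), c(5, 6))
  net <- toy_network(as.vector(t(e)), 10)
  part <- detect_communities(net)
  expect_equal(part$n_communities, 2)
  expect_equal(unname(part$membership[1:5]), rep(part$membership[[1]], 5))
  expect_equal(unname(part$membership[6:10]), rep(part$membership[[6]], 5))
  skip_if_not_installed("igraph")
  ig <- igraph::graph_from_edgelist(e, directed = FALSE)
  expect_equal(part$modularity,
               igraph::modularity(ig, part$membership), tolerance = 1e-12)

  # complete graph: no split improves on the single community
  k5 <- toy_network(as.vector(combn(1:5, 2)), 5)
  flat <- detect_communities(k5)
  expect_equal(flat$n_communities, 1)
  expect_equal(flat$modularity, 0)

  # planted three-community chain: non-bridge nodes recovered (ARI >= 0.9)
  spec <- planted_network_spec(c(9, 9, 9), intra_corr = 0.6)
  gen <- generate_correlated_ensemble(spec, n_models = 300, seed = 61)
  pers <- contact_persistence(gen$ensemble, cutoff = 5)
  gcm <- gc_matrix(gen$ensemble, superpose = FALSE)
  found <- detect_communities(build_network(pers, gcm))
  keep <- setdiff(seq_len(spec$n_nodes), spec$bridge_nodes)
  expect_gte(adjusted_rand(found$membership[keep], gen$membership[keep]), 0.9)
})

test_that("bridgeness follows the inter-community effective distances", {
  # node with all edges internal scores exactly 0; a sole 1-edge bridge
  # between two triangles scores 1
  e <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4))
  net <- toy_network(as.vector(t(e)), 6)
  part <- c(1, 1, 1, 2, 2, 2)
  br <- bridgeness_profile(net, part)
  expect_equal(br$profile$bridgeness, c(0, 0, 1, 1, 0, 0))

  # hand-computed multi-bridge example: 3 links between the communities
  e2 <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(6, 7), c(4, 7),
              c(1, 4), c(1, 5), c(2, 6))
  net2 <- toy_network(as.vector(t(e2)), 7)
  br2 <- bridgeness_profile(net2, c(1, 1, 1, 2, 2, 2, 2))
  expect_equal(br2$profile$bridgeness,
               c(1/3, 1/3, 0, 1/3, 1/3, 1/3, 0))
  expect_equal(br2$inter_links["1", "2"], 3L)
})

test_that("mutation sites map onto hotspots by identity or proximity", {
  refs <- generate_reference_states(n_models = 10, seed = 62)
  ens <- refs$active$ensemble
  pers <- contact_persistence(ens, cutoff = 7.5)
  gcm <- gc_matrix(ens)
  prof <- betweenness_profile(shortest_paths(build_network(pers, gcm)))

  # the canonical resistance-site panel is accepted on the kinase frame
  sites <- c(269L, 272L, 309L, 320L, 334L, 378L, 389L, 401L, 408L, 415L)
  mp <- map_mutations(sites, prof, ens)
  expect_identical(mp$site, sites)
  expect_true(all(mp$status %in% c("direct_hotspot", "proximal", "distal")))
  expect_true(all(mp$distance[mp$status == "direct_hotspot"] == 0))
  expect_true(all(mp$distance[mp$status == "proximal"] < 5))
  expect_true(all(mp$distance[mp$status == "distal"] >= 5))

  hot <- prof$hotspots[1]
  expect_identical(map_mutations(hot, prof, ens)$status, "direct_hotspot")
  expect_error(map_mutations(9999L, prof, ens), "absent")
})
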