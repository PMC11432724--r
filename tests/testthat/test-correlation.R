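test_that("DCC is exactly +/-1 for perfectly (anti)correlated pairs", {
  base <- helix_backbone(8)
  set.seed(51)
  amp <- rnorm(20)
  disp <- lapply(amp, function(a) {
    d <- matrix(0, 8, 3)
    d[2, ] <- c(a, 0, 0)   # residues 2 and 5 move identically
    d[5, ] <- c(a, 0, 0)
    d[7, ] <- c(-a, 0, 0)  # residue 7 moves in anti-phase
    d[c(1, 3, 4, 6, 8), ] <- matrix(rnorm(15, sd = 0.2), 5, 3)
    d
  })
  ens <- ensemble_from_displacements(base, disp)
  C <- dcc_matrix(ens, superpose = FALSE)$matrix
  expect_equal(C[2, 5], 1, tolerance = 1e-12)
  expect_equal(C[2, 7], -1, tolerance = 1e-12)
  expect_equal(diag(C), rep(1, 8))
  expect_equal(C, t(C))
  expect_true(all(C >= -1 & C <= 1))
})

test_that("planted Gaussian correlation is recovered by DCC and GC", {
  spec <- planted_network_spec(c(8, 8), intra_corr = 0.5)
  gen <- generate_correlated_ensemble(spec, n_models = 500, seed = 52)
  dcc <- dcc_matrix(gen$ensemble, superpose = FALSE)$matrix
  gc <- gc_matrix(gen$ensemble, superpose = FALSE)$matrix
  # within-community planted rho = 0.5; for equal per-dimension correlation
  # the closed-form generalized correlation equals |rho|
  intra_pairs <- rbind(c(1, 2), c(2, 6), c(10, 14), c(12, 16))
  for (r in seq_len(nrow(intra_pairs))) {
    i <- intra_pairs[r, 1]; j <- intra_pairs[r, 2]
    expect_lt(abs(dcc[i, j] - 0.5), 0.1)
    expect_lt(abs(gc[i, j] - 0.5), 0.05)
  }
  # for jointly Gaussian displacements GC captures at least the linear part
  off <- upper.tri(gc)
  expect_true(all(gc[off] >= abs(dcc[off]) - 1e-9))
})

test_that("GC detects independence, saturation, and respects model minima", {
  spec0 <- planted_network_spec(c(8, 8), intra_corr = 0, inter_corr = 0,
                                bridge_corr = 0)
  indep <- generate_correlated_ensemble(spec0, n_models = 500, seed = 53)
  gc0 <- gc_matrix(indep$ensemble, superpose = FALSE)$matrix
  expect_lt(mean(gc0[upper.tri(gc0)]), 0.15)

  # perfect linear dependence saturates toward 1
  base <- helix_backbone(6)
  set.seed(54)
  amp <- rnorm(40)
  disp <- lapply(amp, function(a) {
    d <- matrix(rnorm(18, sd = 0.1), 6, 3)
    d[2, ] <- c(a, 2 * a, -a)
    d[4, ] <- c(-2 * a, a, a)  # linear function of residue 2's motion
    d
  })
  ens <- ensemble_from_displacements(base, disp)
  gcl <- gc_matrix(ens, superpose = FALSE)$matrix
  expect_gte(gcl[2, 4], 0.95)

  expect_error(gc_matrix(ens[1:3], "gaussian"), "at least 5")
  expect_error(gc_matrix(ens[1:10], "knn"), "at least 30")
})

test_that("k-NN estimator separates strong correlation from independence", {
  spec <- planted_network_spec(c(5, 5), intra_corr = 0.8, inter_corr = 0,
                               bridge_corr = 0)
  gen <- generate_correlated_ensemble(spec, n_models = 150, seed = 55)
  gck <- gc_matrix(gen$ensemble, "knn", superpose = FALSE)$matrix
  expect_gt(gck[1, 2], 0.5)          # planted 0.8 within a community
  expect_lt(mean(gck[1, 7:10]), 0.3) # independent across communities
})

test_that("DCC is invariant to a global rigid transform of all models", {
  refs <- generate_reference_states(n_residues = 25, loop_span = c(8, 16),
                                    first_resid = 1, n_models = 12, seed = 56)
  ens <- refs$active$ensemble
  C1 <- dcc_matrix(ens)$matrix
  th <- 0.8
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved_xyz <- ens$xyz
  for (m in seq_len(n_models(ens)))
    moved_xyz[m, , ] <- ens$xyz[m, , ] %*% R +
      matrix(c(-3, 8, 1), n_residues(ens), 3, byrow = TRUE)
  C2 <- dcc_matrix(conf_ensemble(moved_xyz, ens$resid))$matrix
  expect_lt(max(abs(C1 - C2)), 1e-6)
})

test_that("contact persistence counts model fractions exactly", {
  # 5-model toy: residues 1 and 3 within 4 A in a hand-set number of models
  base <- helix_backbone(6) * 3  # spread out so only planted contacts count
  sep <- c(4, 4, 4, 10, 10)      # pair (1,3) close in 3 of 5 models
  disp <- lapply(sep, function(s) {
    d <- matrix(0, 6, 3)
    d[3, ] <- c(s, 0, 0) - (base[3, ] - base[1, ])
    d
  })
  ens <- ensemble_from_displacements(base, disp)
  pers <- contact_persistence(ens, cutoff = 5, min_fraction = 0.75)
  expect_equal(pers$persistence[1, 3], 3 / 5)
  expect_false(pers$adjacency[1, 3])
  expect_equal(diag(pers$persistence), rep(1, 6))
  expect_equal(pers$persistence, t(pers$persistence))

  # threshold boundary: 74% of models -> no edge, 75% -> edge
  mk <- function(n_close, n_total) {
    sep <- c(rep(4, n_close), rep(10, n_total - n_close))
    ensemble_from_displacements(base, lapply(sep, function(s) {
      d <- matrix(0, 6, 3)
      d[3, ] <- c(s, 0, 0) - (base[3, ] - base[1, ])
      d
    }))
  }
  expect_false(contact_persistence(mk(74, 100), 5, 0.75)$adjacency[1, 3])
  expect_true(contact_persistence(mk(75, 100), 5, 0.75)$adjacency[1, 3])

  # chain neighbors are never edges even when permanently in contact
  rigid <- ensemble_from_displacements(helix_backbone(6),
                                       rep(list(matrix(0, 6, 3)), 3))
  p2 <- contact_persistence(rigid, cutoff = 5)
  expect_equal(p2$persistence[1, 2], 1)
  expect_false(p2$adjacency[1, 2])
})
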