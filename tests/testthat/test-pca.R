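test_that("PCA eigen-identities hold on fitted ensembles", {
  refs <- generate_reference_states(n_residues = 50, loop_span = c(15, 35),
                                    first_resid = 1, n_models = 15, seed = 41)
  merged <- merge_ensembles(lapply(refs, `[[`, "ensemble"))
  pca <- fit_reference_pca(merged, confidence_threshold = NULL)

  expect_true(all(diff(pca$eval) <= 1e-9))      # descending
  expect_true(all(pca$eval >= 0))
  gram <- crossprod(pca$evec[, 1:10])
  expect_lt(max(abs(gram - diag(10))), 1e-8)    # orthonormal

  # trace identity: total eigenvalue mass equals total coordinate variance
  fitted <- alloscan:::iterative_superpose(merged)
  X <- alloscan:::flatten_models(fitted$xyz)
  expect_equal(sum(pca$eval), sum(apply(X, 2, var)), tolerance = 1e-6)

  # projecting the fit ensemble reproduces the eigenvalue spectrum
  sc <- project_ensemble(merged, pca, n_components = 4)
  S <- cov(as.matrix(sc[, -1]))
  expect_lt(max(abs(diag(S) - pca$eval[1:4])), 1e-6)
  expect_lt(max(abs(S[upper.tri(S)])), 1e-6)

  # projecting the mean structure lands at the origin
  mean_ens <- conf_ensemble(array(pca$mean, c(1, nrow(pca$mean), 3)),
                            pca$resid)
  expect_lt(max(abs(project_ensemble(mean_ens, pca)[, -1])), 0.01)
})

test_that("identical models give a null spectrum; rank-1 motion loads on PC1", {
  base <- helix_backbone(40)
  same <- conf_ensemble(replicate(5, base, simplify = FALSE), 1:40)
  pca0 <- fit_reference_pca(same, confidence_threshold = NULL)
  expect_lt(max(pca0$eval), 1e-12)

  # displacement along one direction only: PC1 takes > 95% of the variance
  r1 <- generate_reference_states(
    n_residues = 40, loop_span = c(10, 30), first_resid = 1, n_models = 20,
    noise_sd = 0,
    displacements = list(active = c(0, 0, 0), I1 = c(3, 0, 0), I2 = c(6, 0, 0)),
    seed = 42)
  m1 <- merge_ensembles(lapply(r1, `[[`, "ensemble"))
  p1 <- fit_reference_pca(m1, confidence_threshold = NULL)
  expect_gt(p1$eval[1] / sum(p1$eval), 0.95)
})

test_that("PCA scores are invariant to a global rigid transform of the inputs", {
  refs <- generate_reference_states(n_residues = 30, loop_span = c(10, 20),
                                    first_resid = 1, n_models = 10, seed = 43)
  ens <- refs$I2$ensemble
  pca <- fit_reference_pca(merge_ensembles(lapply(refs, `[[`, "ensemble")),
                           confidence_threshold = NULL)
  sc <- project_ensemble(ens, pca)

  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved_xyz <- ens$xyz
  for (m in seq_len(n_models(ens)))
    moved_xyz[m, , ] <- ens$xyz[m, , ] %*% R +
      matrix(c(10, -4, 2), n_residues(ens), 3, byrow = TRUE)
  moved <- conf_ensemble(moved_xyz, ens$resid)
  expect_equal(as.matrix(project_ensemble(moved, pca)[, -1]),
               as.matrix(sc[, -1]), tolerance = 1e-6)
})

test_that("well-separated states form distinct clusters in the score plane", {
  skip_if_not_installed("cluster")
  # displacement-to-noise ratio 10: silhouette in PC space must be high
  refs <- generate_reference_states(
    n_residues = 60, loop_span = c(20, 40), first_resid = 1, n_models = 15,
    noise_sd = 0.3,
    displacements = list(active = c(0, 0, 0), I1 = c(3, 0, 0), I2 = c(0, 3, 3)),
    seed = 44)
  merged <- merge_ensembles(lapply(refs, `[[`, "ensemble"),
                            labels = names(refs))
  sc <- project_ensemble(merged, fit_reference_pca(merged,
                                                   confidence_threshold = NULL))
  sil <- cluster::silhouette(as.integer(factor(sc$label)),
                             dist(as.matrix(sc[, -1])))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("state overlap matches Gaussian geometry and a Monte-Carlo oracle", {
  set.seed(45)
  a <- MASS::mvrnorm(600, c(0, 0), diag(2))
  same <- rbind(a, MASS::mvrnorm(600, c(0, 0), diag(2)))
  lab <- rep(c("g1", "g2"), each = 600)
  ov <- state_overlap(same, lab)
  expect_lt(abs(ov["g1", "g2"] - 0.95), 0.04)

  far <- rbind(a, MASS::mvrnorm(600, c(20, 0), diag(2)))
  expect_lt(max(state_overlap(far, lab)[1, 2],
                state_overlap(far, lab)[2, 1]), 0.01)

  # half-shifted pair: oracle = MC fraction of A inside B's true 95% ellipse
  shift <- c(1.5, 0)
  b <- MASS::mvrnorm(600, shift, diag(2))
  ov2 <- state_overlap(rbind(a, b), lab)
  mc <- mean(rowSums(sweep(MASS::mvrnorm(200000, c(0, 0), diag(2)), 2,
                           shift)^2) <= qchisq(0.95, 2))
  expect_lt(abs(ov2["g1", "g2"] - mc), 0.05)

  degen <- rbind(a, matrix(rep(c(1, 1), 300), ncol = 2, byrow = TRUE))
  expect_error(state_overlap(degen, lab[1:900]), "degenerate")
})
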