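test_that("reference states are identical outside the loop and reproducible", {
  refs <- generate_reference_states(n_residues = 60, loop_span = c(20, 35),
                                    first_resid = 1, n_models = 4,
                                    noise_sd = 0.2, seed = 11)
  refs2 <- generate_reference_states(n_residues = 60, loop_span = c(20, 35),
                                     first_resid = 1, n_models = 4,
                                     noise_sd = 0.2, seed = 11)
  expect_identical(refs, refs2)

  # zero displacement + zero noise: the three ensembles coincide exactly
  flat <- generate_reference_states(n_residues = 40, loop_span = c(10, 20),
                                    first_resid = 1, n_models = 3, noise_sd = 0,
                                    displacements = list(active = c(0, 0, 0),
                                                         I1 = c(0, 0, 0),
                                                         I2 = c(0, 0, 0)),
                                    seed = 1)
  expect_identical(flat$active$ensemble$xyz, flat$I1$ensemble$xyz)
  expect_identical(flat$active$ensemble$xyz, flat$I2$ensemble$xyz)

  # defaults: 20 models each over the kinase-domain numbering frame
  defaults <- generate_reference_states(seed = 2)
  expect_equal(vapply(defaults, function(s) n_models(s$ensemble), 1L),
               c(active = 20L, I1 = 20L, I2 = 20L))
  expect_equal(range(defaults$active$ensemble$resid), c(245L, 531L))

  expect_error(generate_reference_states(n_residues = 50, first_resid = 1,
                                         loop_span = c(40, 60)),
               "outside chain")
})

test_that("noise-free state means obey the closed-form displacement RMSD", {
  refs <- generate_reference_states(noise_sd = 0, n_models = 1, seed = 1)
  k <- 421 - 398 + 1
  N <- 287
  for (st in c("I1", "I2")) {
    d <- sqrt(sum((refs[[st]]$displacement - refs$active$displacement)^2))
    expected <- d * sqrt(k / N)
    got <- rmsd_profile(refs[[st]]$ensemble, refs$active$ensemble, fit = FALSE)
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("mixture sampling hits the requested populations", {
  refs <- generate_reference_states(n_residues = 60, loop_span = c(20, 35),
                                    first_resid = 1, n_models = 5, seed = 3)
  pure <- generate_mixture_ensemble(
    mixture_spec(c(active = 1.0), n_models = 25, seed = 4), refs)
  expect_true(all(pure$labels == "active"))

  pops <- c(I2 = 0.82, I1 = 0.10, active = 0.08)
  mix <- generate_mixture_ensemble(
    mixture_spec(pops, n_models = 1000, seed = 5), refs)
  frac <- table(factor(mix$labels, levels = names(pops))) / 1000
  for (st in names(pops)) {
    band <- 3 * sqrt(pops[[st]] * (1 - pops[[st]]) / 1000)
    expect_lt(abs(frac[[st]] - pops[[st]]), band)
  }
  expect_identical(mix$ensemble$label, mix$labels)

  # default draw size mirrors one prediction run (5 models x 14 structures)
  expect_equal(mixture_spec(c(active = 1))$n_models, 70L)

  expect_error(generate_mixture_ensemble(
    mixture_spec(c(bogus = 1)), refs), "missing reference")
  expect_error(mixture_spec(c(active = 0.5, I1 = 0.4)), "sum to 1")
})

test_that("planted correlation structure is realized and PSD-checked", {
  spec0 <- planted_network_spec(c(6, 6), intra_corr = 0, inter_corr = 0,
                                bridge_corr = 0)
  indep <- generate_correlated_ensemble(spec0, n_models = 400, seed = 6)
  C <- dcc_matrix(indep$ensemble, superpose = FALSE)$matrix
  off <- abs(C[upper.tri(C)])
  expect_lt(mean(off > 3 / sqrt(400)), 0.02)  # ~normal tail at 3 SD

  spec <- planted_network_spec(c(8, 8), intra_corr = 0.5)
  gen <- generate_correlated_ensemble(spec, n_models = 500, seed = 7)
  C <- dcc_matrix(gen$ensemble, superpose = FALSE)$matrix
  expect_lt(abs(C[1, 2] - 0.5), 0.1)

  expect_error(generate_correlated_ensemble(
    planted_network_spec(c(5, 5), intra_corr = 0, inter_corr = 0.9),
    n_models = 10, seed = 1),
    "not positive semi-definite")
  expect_error(planted_network_spec(c(5, 5), intra_corr = 1.0), "\\[0, 1\\)")
  expect_error(planted_network_spec(c(5, 5), bridge_nodes = c(3)),
               "bridge_nodes")
})

test_that("confidence assignment supports uniform, banded and low-model profiles", {
  refs <- generate_reference_states(n_residues = 50, loop_span = c(20, 30),
                                    first_resid = 1, n_models = 8, seed = 8)
  ens <- refs$active$ensemble

  uni <- assign_confidence(ens, core_range = c(90, 90))
  expect_equal(unname(model_confidence(uni)), rep(90, 8))

  banded <- assign_confidence(ens, loop_span = c(20, 30),
                              low_models = c(2, 5), seed = 9)
  in_loop <- banded$resid >= 20 & banded$resid <= 30
  ok_models <- setdiff(seq_len(8), c(2, 5))
  expect_true(all(banded$plddt[ok_models, in_loop] >= 65 &
                    banded$plddt[ok_models, in_loop] <= 85))
  expect_true(all(banded$plddt[ok_models, !in_loop] >= 80))
  expect_true(all(model_confidence(banded)[c(2, 5)] < 70))

  expect_error(assign_confidence(ens, core_range = c(90, 120)), "\\[0, 100\\]")
})
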