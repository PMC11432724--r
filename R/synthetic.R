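#' Synthetic multi-state ensemble generators
#'
#' These generators emulate the study system of the analysis pipeline: a
#' kinase-like chain whose three reference states (active, I1, I2) differ by
#' a displaced loop segment, mixture ensembles with controllable state
#' populations, per-residue confidence tracks, and ensembles with planted
#' pairwise correlations and planted network-bridge residues. Chains are
#' Calpha-only traces on a smooth helix-like parametric backbone: every
#' downstream metric of the pipeline is computed on Calpha atoms, so no
#' further geometric realism is required.
#'
#' @name synthetic
NULL

#' Idealized helical Calpha trace
#'
#' Smooth parametric backbone used by all synthetic generators: radius
#' 2.3 A, rise 1.5 A, 100 degrees per residue, giving the canonical ~3.8 A
#' consecutive-Calpha spacing.
#'
#' @param n_residues number of residues.
#' @return `n_residues x 3` coordinate matrix (Angstrom).
#' @export
helix_backbone <- function(n_residues) {
  t <- seq_len(n_residues) - 1
  ang <- t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

#' Generate the three reference states of a kinase-like chain
#'
#' Builds `active`, `I1` and `I2` reference ensembles over one shared residue
#' numbering. The states are identical outside `loop_span`; inside it, each
#' state's mean structure is rigidly translated by its displacement vector,
#' emulating an activation-loop swing between open and closed conformations.
#' Each ensemble holds `n_models` models (default 20, the size of the NMR
#' ensembles the pipeline is designed around) equal to the state mean plus
#' isotropic Gaussian coordinate noise.
#'
#' With `noise_sd = 0`, the whole-chain unfitted Calpha RMSD between two
#' state means is exactly `d * sqrt(k / N)` for a displacement difference of
#' magnitude `d` over `k` of `N` residues.
#'
#' @param n_residues chain length (default 287, the span of a kinase domain).
#' @param loop_span integer length-2 vector, 1-based inclusive residue-id
#'   interval of the mobile loop (default `c(398, 421)`, the activation loop
#'   in ABL numbering).
#' @param displacements named list of 3-vectors (Angstrom), loop translation
#'   per state. Defaults place `I1` 4 A and `I2` ~8 A from `active` along
#'   different directions, comparable to an open-to-closed loop swing.
#' @param n_models models per state ensemble.
#' @param noise_sd isotropic per-coordinate Gaussian noise, Angstrom.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param first_resid residue id of the first residue (default 245 so the
#'   default loop span falls inside the chain, mirroring ABL numbering).
#'
#' @return named list of three reference states (`active`, `I1`, `I2`); each
#'   is a list with `label`, `ensemble` (a [conf_ensemble()]), `loop_span`,
#'   `displacement`.
#' @export
#' @examples
#' refs <- generate_reference_states(n_models = 5, seed = 1)
#' n_models(refs$active$ensemble)
generate_reference_states <- function(n_residues = 287,
                                      loop_span = c(398L, 421L),
                                      displacements = list(active = c(0, 0, 0),
                                                           I1 = c(4, 0, 0),
                                                           I2 = c(0, 4, 7)),
                                      n_models = 20,
                                      noise_sd = 0.3,
                                      seed = 1,
                                      first_resid = 245L) {
  stopifnot(n_residues >= 3, n_models >= 1, noise_sd >= 0, length(loop_span) == 2)
  resid <- seq.int(first_resid, length.out = n_residues)
  if (loop_span[1] > loop_span[2] ||
      loop_span[1] < resid[1] || loop_span[2] > resid[n_residues])
    stop(sprintf("loop_span [%d, %d] outside chain residues [%d, %d]",
                 loop_span[1], loop_span[2], resid[1], resid[n_residues]),
         call. = FALSE)
  if (!all(c("active", "I1", "I2") %in% names(displacements)))
    stop("displacements must name the states active, I1, I2", call. = FALSE)
  base <- helix_backbone(n_residues)
  loop_idx <- which(resid >= loop_span[1] & resid <= loop_span[2])
  states <- c("active", "I1", "I2")
  out <- lapply(seq_along(states), function(s) {
    st <- states[s]
    d <- displacements[[st]]
    mean_xyz <- base
    mean_xyz[loop_idx, ] <- sweep(mean_xyz[loop_idx, , drop = FALSE], 2, d, `+`)
    xyz <- with_seed(derive_seed(seed, s), {
      arr <- array(NA_real_, c(n_models, n_residues, 3L))
      for (m in seq_len(n_models)) {
        arr[m, , ] <- mean_xyz +
          if (noise_sd > 0) matrix(rnorm(n_residues * 3L, sd = noise_sd),
                                   n_residues, 3L) else 0
      }
      arr
    })
    list(label = st,
         ensemble = conf_ensemble(xyz, resid, label = st),
         loop_span = as.integer(loop_span),
         displacement = as.numeric(d))
  })
  names(out) <- states
  out
}

#' Specification of a mixture ensemble
#'
#' @param populations named numeric vector or list of state fractions in
#'   `[0, 1]`, summing to 1 (within 1e-9).
#' @param n_models number of models to draw (default 70, the output size of
#'   one prediction run: 5 models x 14 structures).
#' @param noise_sd Angstrom, isotropic noise added on top of the drawn
#'   reference model.
#' @param seed integer seed.
#' @return a `mixture_spec` list.
#' @export
mixture_spec <- function(populations, n_models = 70, noise_sd = 0.3, seed = 1) {
  populations <- unlist(populations)
  stopifnot(length(populations) >= 1, !is.null(names(populations)),
            all(populations >= 0 & populations <= 1), n_models >= 1)
  if (abs(sum(populations) - 1) > 1e-9)
    stop("population fractions must sum to 1 (within 1e-9)", call. = FALSE)
  structure(list(populations = populations, n_models = as.integer(n_models),
                 noise_sd = noise_sd, seed = seed),
            class = "mixture_spec")
}

#' Draw a mixture ensemble with known per-model state labels
#'
#' Each model slot samples a state label from `spec$populations`, then a
#' uniformly chosen model of that state's reference ensemble, plus isotropic
#' Gaussian noise. The true labels are returned alongside the ensemble so
#' that downstream classification can be scored against ground truth
#' (population-shift recovery, e.g. an ensemble pushed to ~82% of one state).
#'
#' @param spec a [mixture_spec()].
#' @param references reference states from [generate_reference_states()];
#'   must cover every label in `spec$populations`.
#' @return list with `ensemble` (a [conf_ensemble()], labels set to the true
#'   states) and `labels` (character vector of drawn state labels).
#' @export
generate_mixture_ensemble <- function(spec, references) {
  stopifnot(inherits(spec, "mixture_spec"))
  missing_ref <- setdiff(names(spec$populations), names(references))
  if (length(missing_ref))
    stop("missing reference state(s): ", paste(missing_ref, collapse = ", "),
         call. = FALSE)
  ref0 <- references[[names(spec$populations)[1]]]$ensemble
  n_res <- n_residues(ref0)
  out <- with_seed(spec$seed, {
    labels <- sample(names(spec$populations), spec$n_models, replace = TRUE,
                     prob = spec$populations)
    arr <- array(NA_real_, c(spec$n_models, n_res, 3L))
    for (m in seq_len(spec$n_models)) {
      ref <- references[[labels[m]]]$ensemble
      j <- sample.int(n_models(ref), 1L)
      arr[m, , ] <- model_xyz(ref, j) +
        if (spec$noise_sd > 0) matrix(rnorm(n_res * 3L, sd = spec$noise_sd),
                                      n_res, 3L) else 0
    }
    list(arr = arr, labels = labels)
  })
  list(ensemble = conf_ensemble(out$arr, ref0$resid, label = out$labels),
       labels = out$labels)
}

#' Specification of a planted community/bridge network fixture
#'
#' Describes a chain whose residues form spatially compact communities joined
#' only through designated bridge residues, with a planted block-correlation
#' structure for the per-residue displacements. Node layout along the chain
#' is `community 1, bridge 1, community 2, bridge 2, ..., community K`; the
#' bridge between consecutive communities is the sole spatial link between
#' them, so it must dominate shortest-path betweenness downstream.
#'
#' @param community_sizes integer vector of community sizes (each 5..12; the
#'   compact cluster geometry needs both cluster faces occupied and caps a
#'   community at 12 residues).
#' @param bridge_nodes node indices of the bridge residues; defaults to the
#'   between-block positions implied by `community_sizes` and must equal them.
#' @param intra_corr,inter_corr,bridge_corr planted displacement correlation
#'   within a community, between communities, and between a bridge residue
#'   and all other residues; each in `[0, 1)`.
#' @return a `planted_network_spec` list with the node-to-community map.
#' @export
planted_network_spec <- function(community_sizes,
                                 bridge_nodes = NULL,
                                 intra_corr = 0.5,
                                 inter_corr = 0,
                                 bridge_corr = 0.3) {
  stopifnot(length(community_sizes) >= 1,
            all(community_sizes >= 5), all(community_sizes <= 12))
  k <- length(community_sizes)
  expected_bridges <- if (k > 1) cumsum(community_sizes[-k] + 1L) else integer(0)
  if (is.null(bridge_nodes)) bridge_nodes <- expected_bridges
  n_nodes <- sum(community_sizes) + length(expected_bridges)
  if (!identical(as.integer(bridge_nodes), as.integer(expected_bridges)))
    stop("bridge_nodes must be the between-community positions implied by ",
         "community_sizes: ", paste(expected_bridges, collapse = ","),
         call. = FALSE)
  for (r in c(intra_corr, inter_corr, bridge_corr))
    if (r < 0 || r >= 1) stop("correlation levels must lie in [0, 1)", call. = FALSE)
  # node -> community id; bridges carry the id of their left community
  membership <- integer(n_nodes)
  pos <- 1L
  for (ci in seq_len(k)) {
    membership[pos:(pos + community_sizes[ci] - 1L)] <- ci
    pos <- pos + community_sizes[ci]
    if (ci < k) { membership[pos] <- ci; pos <- pos + 1L }
  }
  structure(list(community_sizes = as.integer(community_sizes),
                 bridge_nodes = as.integer(bridge_nodes),
                 n_nodes = n_nodes, membership = membership,
                 intra_corr = intra_corr, inter_corr = inter_corr,
                 bridge_corr = bridge_corr),
            class = "planted_network_spec")
}

# Mean geometry of the planted-network chain: each community is a compact
# grid cluster (all intra-community pairs < 5 A), consecutive clusters are
# 7 A apart at their closest faces (> 5 A), and each bridge residue sits
# between two clusters within ~3.8 A of the facing grid layers only.
planted_geometry <- function(spec) {
  # fill the two bridge-facing layers (x = 4, then x = 0) before the middle
  # layer so both faces of a cluster are occupied for any allowed size
  slots <- expand.grid(x = c(4, 0, 2), y = c(0, 2), z = c(0, 2))
  slots <- as.matrix(slots[order(match(slots$x, c(4, 0, 2)), slots$y, slots$z), ])
  xyz <- matrix(NA_real_, spec$n_nodes, 3)
  pos <- 1L
  for (ci in seq_along(spec$community_sizes)) {
    sz <- spec$community_sizes[ci]
    off <- c((ci - 1L) * 11, 0, 0)
    xyz[pos:(pos + sz - 1L), ] <- sweep(slots[seq_len(sz), , drop = FALSE], 2, off, `+`)
    pos <- pos + sz
    if (ci < length(spec$community_sizes)) {
      xyz[pos, ] <- c((ci - 1L) * 11 + 7.5, 1, 1)
      pos <- pos + 1L
    }
  }
  xyz
}

# Planted node-node displacement correlation matrix implied by the spec.
planted_correlation <- function(spec) {
  R <- matrix(spec$inter_corr, spec$n_nodes, spec$n_nodes)
  for (ci in seq_along(spec$community_sizes)) {
    idx <- setdiff(which(spec$membership == ci), spec$bridge_nodes)
    R[idx, idx] <- spec$intra_corr
  }
  if (length(spec$bridge_nodes)) {
    R[spec$bridge_nodes, ] <- spec$bridge_corr
    R[, spec$bridge_nodes] <- spec$bridge_corr
  }
  diag(R) <- 1
  R
}

#' Generate an ensemble with planted correlations and bridge residues
#'
#' Draws `n_models` models around the planted-community geometry; for each
#' Cartesian dimension independently, per-residue displacements follow a
#' zero-mean Gaussian with the block correlation structure of `spec`
#' (checked for positive semi-definiteness before sampling). Within-community
#' pairs therefore show dynamic cross-correlation `intra_corr`, and the
#' contact topology routes all inter-community shortest paths through the
#' bridge residues.
#'
#' @param spec a [planted_network_spec()].
#' @param n_models number of models.
#' @param seed integer seed.
#' @param disp_sd displacement standard deviation per coordinate, Angstrom.
#' @return list with `ensemble` (a [conf_ensemble()]), `membership`
#'   (planted community id per node) and `bridge_nodes`.
#' @export
generate_correlated_ensemble <- function(spec, n_models, seed = 1, disp_sd = 0.5) {
  stopifnot(inherits(spec, "planted_network_spec"), n_models >= 2)
  R <- planted_correlation(spec)
  for (ci in seq_along(spec$community_sizes)) {
    idx <- which(spec$membership == ci & !(seq_len(spec$n_nodes) %in% spec$bridge_nodes))
    ev <- eigen(R[idx, idx], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(sprintf("community %d correlation block is not positive semi-definite (min eigenvalue %.3g)",
                   ci, min(ev)), call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("full planted correlation matrix is not positive semi-definite (min eigenvalue %.3g); inter/bridge levels are incompatible",
                 min(ev)), call. = FALSE)
  base <- planted_geometry(spec)
  Sigma <- disp_sd^2 * R
  arr <- with_seed(seed, {
    a <- array(NA_real_, c(n_models, spec$n_nodes, 3L))
    for (d in 1:3) {
      disp <- MASS::mvrnorm(n_models, mu = rep(0, spec$n_nodes), Sigma = Sigma)
      a[, , d] <- matrix(base[, d], n_models, spec$n_nodes, byrow = TRUE) + disp
    }
    a
  })
  list(ensemble = conf_ensemble(arr, seq_len(spec$n_nodes)),
       membership = spec$membership,
       bridge_nodes = spec$bridge_nodes)
}

#' Write a per-residue confidence track into an ensemble
#'
#' Assigns pLDDT-like confidence values: residues inside `loop_span` draw
#' from `loop_range` (mimicking the moderately reduced confidence of a mobile
#' loop), all others from `core_range`. Models listed in `low_models` draw
#' all residues from `low_range` instead, guaranteeing a model-mean below a
#' typical filter threshold of 70 when `max(low_range) < 70` — the fixture
#' for confidence-filter tests.
#'
#' @param ens a [conf_ensemble()].
#' @param loop_span residue-id interval for the reduced-confidence loop, or
#'   `NULL` for no loop region.
#' @param core_range,loop_range,low_range length-2 numeric ranges in
#'   `[0, 100]` (degenerate ranges give constant values).
#' @param low_models integer model indices to mark as low-confidence.
#' @param seed integer seed.
#' @return the ensemble with confidence attached.
#' @export
assign_confidence <- function(ens, loop_span = NULL,
                              core_range = c(80, 100),
                              loop_range = c(65, 85),
                              low_range = c(40, 65),
                              low_models = integer(0),
                              seed = 1) {
  stopifnot(inherits(ens, "conf_ensemble"))
  for (rg in list(core_range, loop_range, low_range)) {
    stopifnot(length(rg) == 2, rg[1] <= rg[2])
    if (rg[1] < 0 || rg[2] > 100)
      stop("confidence profile values must lie in [0, 100]", call. = FALSE)
  }
  if (length(low_models) && (min(low_models) < 1 || max(low_models) > n_models(ens)))
    stop("low_models out of range", call. = FALSE)
  nm <- n_models(ens); nr <- n_residues(ens)
  in_loop <- if (is.null(loop_span)) rep(FALSE, nr) else
    ens$resid >= loop_span[1] & ens$resid <= loop_span[2]
  plddt <- with_seed(seed, {
    p <- matrix(runif(nm * nr, core_range[1], core_range[2]), nm, nr)
    if (any(in_loop))
      p[, in_loop] <- runif(nm * sum(in_loop), loop_range[1], loop_range[2])
    if (length(low_models))
      p[low_models, ] <- runif(length(low_models) * nr, low_range[1], low_range[2])
    p
  })
  ens$plddt <- plddt
  ens
}
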