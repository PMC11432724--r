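#' Dynamic cross-correlation matrix
#'
#' Computes the normalized covariance of paired per-residue displacement
#' vectors over an ensemble,
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2> <dr_j^2>)`, where `dr_i` is the
#' displacement of Calpha `i` from its ensemble-average position and `< >`
#' averages over models. Values lie in `[-1, 1]`; +1 is perfectly in-phase
#' motion, -1 perfectly anti-phase. Models are iteratively superposed onto
#' the ensemble mean first (the same scheme PCA uses) unless
#' `superpose = FALSE`, appropriate for ensembles already generated in a
#' common frame. Residues with zero displacement variance get off-diagonal
#' 0 with a warning.
#'
#' @param ens a [conf_ensemble()] with at least 2 models.
#' @param superpose remove rigid-body motion first (default TRUE).
#' @return a `correlation_matrix`: list with `matrix`, `resid`,
#'   `kind = "dcc"`, `n_models`.
#' @export
dcc_matrix <- function(ens, superpose = TRUE) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (n_models(ens) < 2) stop("need at least 2 models", call. = FALSE)
  xyz <- if (superpose) iterative_superpose(ens)$xyz else ens$xyz
  nm <- dim(xyz)[1]; nr <- dim(xyz)[2]
  mean_xyz <- apply(xyz, c(2, 3), mean)
  S <- matrix(0, nr, nr)
  for (d in 1:3) {
    D <- xyz[, , d] - matrix(mean_xyz[, d], nm, nr, byrow = TRUE)
    S <- S + crossprod(D) / nm
  }
  v <- diag(S)
  zero <- v <= 0
  if (any(zero))
    warning(sum(zero), " residue(s) with zero displacement variance; ",
            "their off-diagonal correlations set to 0")
  denom <- sqrt(pmax(v, .Machine$double.eps))
  C <- S / outer(denom, denom)
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  structure(list(matrix = C, resid = ens$resid, kind = "dcc",
                 estimator = "ensemble-average", n_models = nm),
            class = "correlation_matrix")
}

# analytic-Gaussian mutual information between two 3-D displacement blocks
gaussian_mi_pair <- function(C6) {
  di <- det(C6[1:3, 1:3]); dj <- det(C6[4:6, 4:6]); dij <- det(C6)
  if (dij <= 0 || di <= 0 || dj <= 0) return(Inf)
  max(0.5 * log(di * dj / dij), 0)
}

# Kraskov-type k-NN mutual information (Chebyshev norm, estimator 1)
knn_mi_pair <- function(x, y, k = 4L) {
  m <- nrow(x)
  dx <- as.matrix(stats::dist(x, method = "maximum"))
  dy <- as.matrix(stats::dist(y, method = "maximum"))
  dz <- pmax(dx, dy)
  psi <- digamma
  s <- 0
  for (i in seq_len(m)) {
    eps <- sort(dz[i, -i], partial = k)[k]
    nx <- sum(dx[i, -i] < eps)
    ny <- sum(dy[i, -i] < eps)
    s <- s + psi(nx + 1) + psi(ny + 1)
  }
  max(psi(k) + psi(m) - s / m, 0)
}

#' Generalized correlation matrix from mutual information
#'
#' Computes the mutual-information-based generalized correlation
#' `R(X_i, X_j) = sqrt(1 - exp(-2 I_ij / 3))` between the 3-D displacement
#' vectors of residue pairs, capturing non-linear dependence that the
#' linear cross-correlation misses; for jointly Gaussian displacements with
#' equal per-dimension correlation `rho`, `R` equals `|rho|`. The default
#' analytic-Gaussian estimator computes `I_ij` from the displacement
#' covariance blocks and is robust at ensemble sizes around 70 models; the
#' k-NN (Kraskov, k = 4) estimator is nonparametric and needs larger
#' ensembles (and O(N^2 M^2) time). `R` is clipped to `[0, 1]`.
#'
#' @param ens a [conf_ensemble()]; >= 5 models for `gaussian`, >= 30 for
#'   `knn`.
#' @param estimator `"gaussian"` or `"knn"`.
#' @param superpose remove rigid-body motion first (default TRUE).
#' @return a `correlation_matrix` with `kind = "gc"`.
#' @export
gc_matrix <- function(ens, estimator = c("gaussian", "knn"), superpose = TRUE) {
  stopifnot(inherits(ens, "conf_ensemble"))
  estimator <- match.arg(estimator)
  min_m <- if (estimator == "gaussian") 5L else 30L
  if (n_models(ens) < min_m)
    stop(sprintf("the %s estimator needs at least %d models", estimator, min_m),
         call. = FALSE)
  xyz <- if (superpose) iterative_superpose(ens)$xyz else ens$xyz
  nm <- dim(xyz)[1]; nr <- dim(xyz)[2]
  mean_xyz <- apply(xyz, c(2, 3), mean)
  disp <- xyz - aperm(array(mean_xyz, c(nr, 3, nm)), c(3, 1, 2))
  R <- matrix(0, nr, nr); diag(R) <- 1
  if (estimator == "gaussian") {
    # flatten to models x (3 per residue) and take one covariance
    D <- matrix(0, nm, 3L * nr)
    for (d in 1:3) D[, seq(d, by = 3L, length.out = nr)] <- disp[, , d]
    CC <- crossprod(D) / nm
    for (i in seq_len(nr - 1)) {
      bi <- (3 * (i - 1) + 1):(3 * i)
      for (j in (i + 1):nr) {
        bj <- (3 * (j - 1) + 1):(3 * j)
        I <- gaussian_mi_pair(CC[c(bi, bj), c(bi, bj)])
        R[i, j] <- R[j, i] <- sqrt(1 - exp(-2 * I / 3))
      }
    }
  } else {
    for (i in seq_len(nr - 1)) {
      xi <- disp[, i, ]
      for (j in (i + 1):nr) {
        I <- knn_mi_pair(xi, disp[, j, ], k = 4L)
        R[i, j] <- R[j, i] <- sqrt(1 - exp(-2 * I / 3))
      }
    }
  }
  R <- pmin(pmax(R, 0), 1)
  structure(list(matrix = R, resid = ens$resid, kind = "gc",
                 estimator = estimator, n_models = nm),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("<correlation_matrix> kind=%s (%s), %d residues, %d models; off-diagonal range [%.3f, %.3f]\n",
              x$kind, x$estimator, length(x$resid), x$n_models,
              min(off), max(off)))
  invisible(x)
}

#' Contact-persistence matrix and adjacency
#'
#' For every residue pair, the persistence is the fraction of models in
#' which the Calpha-Calpha distance is within `cutoff`; pairs persisting in
#' at least `min_fraction` of the models define the edges of the residue
#' interaction network (default 5 A in at least 75% of conformations).
#' Chain neighbors (|i - j| <= 1) are excluded from the adjacency: their
#' contacts are covalent, and the network models non-covalent interactions.
#' For Calpha-only traces a larger cutoff (7-8 A) is often preferred; the
#' default follows the 5 A sidechain-contact convention and is configurable.
#'
#' @param ens a [conf_ensemble()].
#' @param cutoff contact distance cutoff, Angstrom.
#' @param min_fraction persistence threshold for an edge.
#' @return a `persistence_matrix`: list with `persistence` (fractions,
#'   diagonal 1), `adjacency` (logical), `cutoff`, `min_fraction`, `resid`.
#' @export
contact_persistence <- function(ens, cutoff = 5.0, min_fraction = 0.75) {
  stopifnot(inherits(ens, "conf_ensemble"), cutoff > 0,
            min_fraction >= 0, min_fraction <= 1)
  nr <- n_residues(ens); nm <- n_models(ens)
  P <- matrix(0, nr, nr)
  for (m in seq_len(nm)) {
    xyz <- model_xyz(ens, m)
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
    P <- P + (d2 <= cutoff^2 + 1e-12)
  }
  P <- P / nm
  diag(P) <- 1
  adjacency <- P >= min_fraction
  seq_sep <- abs(outer(seq_len(nr), seq_len(nr), `-`))
  adjacency[seq_sep <= 1] <- FALSE
  structure(list(persistence = P, adjacency = adjacency, cutoff = cutoff,
                 min_fraction = min_fraction, resid = ens$resid),
            class = "persistence_matrix")
}
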