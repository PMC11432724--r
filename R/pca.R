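# Iteratively superpose all models onto the evolving mean structure
# (at most `max_iter` rounds or until the mean moves < tol A per coordinate).
# Removes rigid-body motion before any covariance-based analysis.
iterative_superpose <- function(ens, max_iter = 10, tol = 1e-4) {
  stopifnot(inherits(ens, "conf_ensemble"))
  nm <- n_models(ens); nr <- n_residues(ens)
  xyz <- ens$xyz
  mean_xyz <- model_xyz(ens, 1L)
  for (it in seq_len(max_iter)) {
    for (m in seq_len(nm)) {
      cur <- xyz[m, , ]
      dim(cur) <- c(nr, 3L)
      xyz[m, , ] <- apply_superposition(cur, superpose(cur, mean_xyz))
    }
    new_mean <- apply(xyz, c(2, 3), mean)
    shift <- max(abs(new_mean - mean_xyz))
    mean_xyz <- new_mean
    if (shift < tol) break
  }
  # final pass: fit every model onto the converged mean so downstream
  # projections reproduce these fits exactly
  for (m in seq_len(nm)) {
    cur <- xyz[m, , ]
    dim(cur) <- c(nr, 3L)
    xyz[m, , ] <- apply_superposition(cur, superpose(cur, mean_xyz))
  }
  list(xyz = xyz, mean = mean_xyz)
}

flatten_models <- function(xyz_arr) {
  nm <- dim(xyz_arr)[1]
  matrix(xyz_arr, nrow = nm)  # column order: residue-major within dimension
}

#' Principal component analysis of a Calpha coordinate ensemble
#'
#' Fits PCA on the Cartesian Calpha coordinates of an ensemble, typically a
#' merged wild-type reference ensemble whose components then serve as the
#' common coordinate frame for projecting other ensembles. All models are
#' iteratively superposed onto the evolving mean structure to remove
#' rigid-body motion; the covariance of the flattened coordinates is then
#' eigendecomposed. Eigenvalues (A^2) are the variances of the collective
#' motions along each component; eigenvector signs are fixed so the
#' largest-magnitude coordinate of each component is positive, making plots
#' reproducible. When the ensemble carries confidence values, models with
#' mean confidence below `confidence_threshold` are excluded before fitting
#' (pass `NULL` to disable).
#'
#' @param ens a [conf_ensemble()] with at least 3 models (after filtering).
#' @param confidence_threshold pLDDT filter applied when confidence is
#'   present (default 70); `NULL` disables.
#' @return a `pca_model`: list with `mean` (n x 3 fit target), `center`
#'   (flattened coordinate means), `evec` (3N x K orthonormal), `eval`
#'   (descending, >= 0), `resid`, `n_fit`.
#' @export
fit_reference_pca <- function(ens, confidence_threshold = 70) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (!is.null(ens$plddt) && !is.null(confidence_threshold))
    ens <- filter_by_confidence(ens, confidence_threshold)
  if (n_models(ens) < 3)
    stop("PCA needs at least 3 models", call. = FALSE)
  fit <- iterative_superpose(ens)
  X <- flatten_models(fit$xyz)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  C <- crossprod(Xc) / (nrow(X) - 1)
  ed <- eigen(C, symmetric = TRUE)
  eval <- pmax(ed$values, 0)
  evec <- ed$vectors
  for (k in seq_len(ncol(evec))) {
    j <- which.max(abs(evec[, k]))
    if (evec[j, k] < 0) evec[, k] <- -evec[, k]
  }
  structure(list(mean = fit$mean, center = center, evec = evec, eval = eval,
                 resid = ens$resid, n_fit = n_models(ens)),
            class = "pca_model")
}

#' Project an ensemble onto reference principal components
#'
#' Superposes each model onto the PCA mean structure, centers, and projects
#' onto the leading eigenvectors, so ensembles from different sources
#' (experimental references, predictor runs) land in one common coordinate
#' system and their conformational coverage can be compared directly.
#'
#' @param ens a [conf_ensemble()] over the same residues as the model.
#' @param pca a `pca_model` from [fit_reference_pca()].
#' @param n_components number of leading components to report (default 2).
#' @return data.frame with per-model provenance `label` and score columns
#'   `PC1..PCk`.
#' @export
project_ensemble <- function(ens, pca, n_components = 2) {
  stopifnot(inherits(ens, "conf_ensemble"), inherits(pca, "pca_model"))
  if (!identical(ens$resid, pca$resid))
    stop("ensemble residues do not match the PCA model", call. = FALSE)
  k <- min(n_components, ncol(pca$evec))
  nr <- n_residues(ens)
  scores <- t(vapply(seq_len(n_models(ens)), function(m) {
    xyz <- model_xyz(ens, m)
    fitted <- apply_superposition(xyz, superpose(xyz, pca$mean))
    drop((as.vector(fitted) - pca$center) %*% pca$evec[, seq_len(k), drop = FALSE])
  }, numeric(k)))
  scores <- matrix(scores, ncol = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  cbind(data.frame(label = ens$label, stringsAsFactors = FALSE),
        as.data.frame(scores))
}

#' Pairwise overlap of projected state distributions
#'
#' For each ordered pair of provenance groups, reports the fraction of one
#' group's points falling inside the 95% Gaussian ellipse of the other,
#' quantifying the visual overlap of state clouds in a component plot.
#'
#' @param scores data.frame from [project_ensemble()] (label + score
#'   columns), or a numeric score matrix.
#' @param labels group labels (taken from `scores$label` when present).
#' @return square matrix `overlap[A, B]` = fraction of A's points inside
#'   B's 95% ellipse. Groups need >= 5 points and non-degenerate covariance.
#' @export
state_overlap <- function(scores, labels = NULL) {
  if (is.data.frame(scores) && "label" %in% names(scores)) {
    labels <- scores$label
    scores <- as.matrix(scores[, setdiff(names(scores), "label"), drop = FALSE])
  }
  scores <- as.matrix(scores)
  stopifnot(!is.null(labels), nrow(scores) == length(labels))
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  q <- qchisq(0.95, df = ncol(scores))
  out <- matrix(NA_real_, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (b in groups) {
    pts_b <- scores[labels == b, , drop = FALSE]
    if (nrow(pts_b) < 5) stop("group ", b, " has fewer than 5 points", call. = FALSE)
    S <- cov(pts_b)
    if (det(S) <= 1e-300)
      stop("group ", b, " has a degenerate (zero-variance) distribution",
           call. = FALSE)
    mu <- colMeans(pts_b)
    for (a in groups) {
      pts_a <- scores[labels == a, , drop = FALSE]
      d2 <- stats::mahalanobis(pts_a, mu, S)
      out[a, b] <- mean(d2 <= q)
    }
  }
  out
}
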