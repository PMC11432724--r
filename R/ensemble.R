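#' Conformational ensemble container
#'
#' A `conf_ensemble` holds an ordered set of structural models over one shared
#' residue numbering frame: per-model Calpha coordinates, optional per-model
#' per-residue confidence on the pLDDT scale (0-100), and a provenance label
#' per model. It is the universal currency of the pipeline: the synthetic
#' generators produce it, the PDB reader returns it, and every analysis stage
#' (RMSD/TM classification, PCA, correlation, networks) consumes it.
#'
#' @param xyz numeric array of dimension `c(n_models, n_residues, 3)`, or a
#'   list of `n_residues x 3` coordinate matrices (one per model), in
#'   Angstrom.
#' @param resid integer vector of residue identifiers (1-based author
#'   numbering, strictly increasing).
#' @param plddt optional numeric matrix `n_models x n_residues` of per-residue
#'   confidence values in `[0, 100]`.
#' @param label optional character vector of per-model provenance labels
#'   (recycled from length 1).
#'
#' @return An object of class `conf_ensemble` with elements `xyz`, `resid`,
#'   `plddt`, `label`.
#' @export
#' @examples
#' xyz <- array(rnorm(2 * 10 * 3), c(2, 10, 3))
#' ens <- conf_ensemble(xyz, resid = 1:10)
#' n_models(ens)
conf_ensemble <- function(xyz, resid, plddt = NULL, label = NULL) {
  if (is.list(xyz)) {
    n_res <- nrow(xyz[[1L]])
    arr <- array(NA_real_, c(length(xyz), n_res, 3L))
    for (m in seq_along(xyz)) {
      xm <- as.matrix(xyz[[m]])
      if (!identical(dim(xm), c(n_res, 3L)) && !identical(dim(xm), as.integer(c(n_res, 3L))))
        stop("all coordinate matrices must be n_residues x 3", call. = FALSE)
      arr[m, , ] <- xm
    }
    xyz <- arr
  }
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop("`xyz` must be an array [n_models, n_residues, 3]", call. = FALSE)
  resid <- as.integer(resid)
  if (length(resid) != dim(xyz)[2])
    stop("length(resid) must equal the number of residues in `xyz`", call. = FALSE)
  if (any(diff(resid) <= 0L))
    stop("`resid` must be strictly increasing", call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite", call. = FALSE)
  n_mod <- dim(xyz)[1]
  if (!is.null(plddt)) {
    plddt <- as.matrix(plddt)
    if (!identical(dim(plddt), as.integer(c(n_mod, length(resid)))))
      stop("`plddt` must be an n_models x n_residues matrix", call. = FALSE)
    if (any(plddt < 0 | plddt > 100, na.rm = TRUE))
      stop("confidence values must lie in [0, 100]", call. = FALSE)
  }
  if (is.null(label)) label <- rep("model", n_mod)
  label <- rep_len(as.character(label), n_mod)
  structure(list(xyz = xyz, resid = resid, plddt = plddt, label = label),
            class = "conf_ensemble")
}

#' Number of models in an ensemble
#' @param ens a [conf_ensemble()].
#' @return integer count of models.
#' @export
n_models <- function(ens) {
  stopifnot(inherits(ens, "conf_ensemble"))
  dim(ens$xyz)[1]
}

#' Number of residues in an ensemble
#' @param ens a [conf_ensemble()].
#' @return integer count of residues.
#' @export
n_residues <- function(ens) {
  stopifnot(inherits(ens, "conf_ensemble"))
  dim(ens$xyz)[2]
}

#' Extract one model's coordinate matrix
#' @param ens a [conf_ensemble()].
#' @param i model index.
#' @return `n_residues x 3` numeric matrix (Angstrom).
#' @export
model_xyz <- function(ens, i) {
  stopifnot(inherits(ens, "conf_ensemble"), i >= 1L, i <= n_models(ens))
  m <- ens$xyz[i, , , drop = FALSE]
  dim(m) <- dim(ens$xyz)[2:3]
  m
}

#' Per-model mean confidence
#'
#' Model-level confidence is the unweighted mean of the per-residue values,
#' the community convention for ranking predictor models by pLDDT.
#'
#' @param ens a [conf_ensemble()] with confidence present.
#' @return numeric vector of per-model means.
#' @export
model_confidence <- function(ens) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (is.null(ens$plddt))
    stop("ensemble carries no confidence values", call. = FALSE)
  rowMeans(ens$plddt)
}

#' Subset models of an ensemble
#' @param x a [conf_ensemble()].
#' @param i model indices (integer or logical).
#' @param ... unused.
#' @return a [conf_ensemble()] with the selected models, order preserved.
#' @export
`[.conf_ensemble` <- function(x, i, ...) {
  idx <- seq_len(n_models(x))[i]
  conf_ensemble(x$xyz[idx, , , drop = FALSE], x$resid,
                plddt = if (!is.null(x$plddt)) x$plddt[idx, , drop = FALSE],
                label = x$label[idx])
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble> %d models x %d residues (resid %d..%d)%s\n",
              n_models(x), n_residues(x), min(x$resid), max(x$resid),
              if (is.null(x$plddt)) "" else ", with confidence"))
  tab <- table(x$label)
  cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# Restrict an ensemble to a subset of residue ids (used for residue-id
# intersection when merging and for region-restricted metrics).
subset_residues <- function(ens, keep_resid) {
  idx <- match(keep_resid, ens$resid)
  if (anyNA(idx)) stop("residue ids absent from ensemble: ",
                       paste(keep_resid[is.na(idx)], collapse = ","), call. = FALSE)
  conf_ensemble(ens$xyz[, idx, , drop = FALSE], ens$resid[idx],
                plddt = if (!is.null(ens$plddt)) ens$plddt[, idx, drop = FALSE],
                label = ens$label)
}
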