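#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the Calpha RMSD of
#' `mobile` onto `reference` over the selected points; reflections are
#' excluded (the rotation determinant is +1). This is the fit underlying all
#' RMSD, TM-score and PCA computations in the package.
#'
#' @param mobile,reference `n x 3` coordinate matrices over the same points.
#' @param selection integer row indices used for the fit (default: all).
#' @return a `superposition_result`: list with `rotation` (3x3, det +1),
#'   `translation` (so that `fitted = mobile %*% rotation + translation`),
#'   `rmsd` (Angstrom, over the selection) and `selection`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3)
    stop("need at least 3 selected points for a rigid fit", call. = FALSE)
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A <- sweep(A, 2, ca); B <- sweep(B, 2, cb)
  sv_chk <- svd(B)$d
  if (sv_chk[2] < 1e-9 * max(sv_chk[1], 1))
    stop("selected reference points are collinear; fit is underdetermined",
         call. = FALSE)
  M <- crossprod(A, B)
  sv <- svd(M)
  s <- sign(det(sv$u) * det(sv$v))
  Q <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  translation <- cb - drop(ca %*% Q)
  fitted <- A %*% Q
  structure(list(rotation = Q,
                 translation = translation,
                 rmsd = sqrt(mean(rowSums((fitted - B)^2))),
                 selection = selection),
            class = "superposition_result")
}

#' Apply a superposition to coordinates
#' @param xyz `n x 3` matrix.
#' @param sp a `superposition_result`.
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(xyz, sp) {
  stopifnot(inherits(sp, "superposition_result"))
  sweep(as.matrix(xyz) %*% sp$rotation, 2, sp$translation, `+`)
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

resid_region_idx <- function(resid, region) {
  if (is.null(region)) return(seq_along(resid))
  idx <- which(resid >= region[1] & resid <= region[2])
  if (!length(idx))
    stop(sprintf("region [%s, %s] selects no residues", region[1], region[2]),
         call. = FALSE)
  idx
}

#' Per-model RMSD of an ensemble against a reference conformation
#'
#' Each model is rigidly superposed onto the reference conformation (by
#' convention the first model of the reference ensemble) over the fit
#' selection, and the RMSD is reported over the report selection. The
#' default fits and reports on all shared Calpha atoms; a region restriction
#' (e.g. the activation loop) reports local deviations after a whole-chain
#' fit, the usual way loop rearrangements are quantified.
#'
#' @param ens a [conf_ensemble()].
#' @param reference a [conf_ensemble()] (its first model is the reference
#'   conformation) or an `n x 3` matrix over the same residues as `ens`.
#' @param fit_region,report_region optional residue-id intervals
#'   `c(start, end)`; `NULL` means all shared residues.
#' @param fit if `FALSE`, skip the superposition and compare coordinates in
#'   the frame they come in (used when ensembles are already aligned, e.g.
#'   synthetic ensembles generated in one frame).
#' @return numeric vector of per-model RMSDs (Angstrom).
#' @export
rmsd_profile <- function(ens, reference, fit_region = NULL,
                         report_region = NULL, fit = TRUE) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (inherits(reference, "conf_ensemble")) {
    shared <- intersect(ens$resid, reference$resid)
    if (length(shared) < 3)
      stop("ensemble and reference share too few residues", call. = FALSE)
    ref_xyz <- model_xyz(subset_residues(reference, shared), 1L)
    ens <- subset_residues(ens, shared)
  } else {
    ref_xyz <- as.matrix(reference)
    if (nrow(ref_xyz) != n_residues(ens))
      stop("reference matrix does not match the ensemble residue count",
           call. = FALSE)
  }
  fit_idx <- resid_region_idx(ens$resid, fit_region)
  rep_idx <- resid_region_idx(ens$resid, report_region)
  vapply(seq_len(n_models(ens)), function(m) {
    xyz <- model_xyz(ens, m)
    if (fit) xyz <- apply_superposition(xyz, superpose(xyz, ref_xyz, fit_idx))
    rmsd_xyz(xyz[rep_idx, , drop = FALSE], ref_xyz[rep_idx, , drop = FALSE])
  }, 1)
}
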