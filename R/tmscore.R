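#' Template-modeling score between two conformations of one chain
#'
#' Computes `TM = (1/L) * sum_i 1 / (1 + (d_i/d0)^2)` maximized over rigid
#' superpositions, with the length-dependent scale
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8` (floored at 0.5 A). The score lies in
#' (0, 1]; 1 is a perfect match and values above 0.5 conventionally indicate
#' the same fold. The maximization uses the standard fragment-seeded
#' iterative scheme: fits seeded from sliding windows of several lengths are
#' refined by repeatedly re-fitting on the residues currently within the
#' distance scale, and the best score over all seeds is kept. Both inputs
#' must cover the same residues of the same protein; the normalization
#' length is the reference chain length.
#'
#' @param model,reference `n x 3` Calpha coordinate matrices over matched
#'   residues, or [conf_ensemble()] objects (first model used, residues
#'   matched by id).
#' @return list with `tm` (the score), `d0`, and `same_fold`
#'   (`tm > 0.5`).
#' @export
#' @examples
#' xyz <- helix_backbone(60)
#' tm_score(xyz, xyz)$tm  # 1
tm_score <- function(model, reference) {
  if (inherits(model, "conf_ensemble") || inherits(reference, "conf_ensemble")) {
    if (!inherits(model, "conf_ensemble")) stop("mixed input types", call. = FALSE)
    shared <- intersect(model$resid, reference$resid)
    model <- model_xyz(subset_residues(model, shared), 1L)
    reference <- model_xyz(subset_residues(reference, shared), 1L)
  }
  model <- as.matrix(model); reference <- as.matrix(reference)
  L <- nrow(reference)
  if (L < 3 || nrow(model) != L)
    stop("need matched chains of at least 3 residues", call. = FALSE)
  d0 <- max(1.24 * max(L - 15, 0)^(1/3) - 1.8, 0.5)
  score_for <- function(xyz) {
    d2 <- rowSums((xyz - reference)^2)
    mean(1 / (1 + d2 / d0^2))
  }
  refine <- function(sel) {
    best <- -Inf
    for (iter in 1:20) {
      sp <- tryCatch(superpose(model, reference, sel), error = function(e) NULL)
      if (is.null(sp)) break
      fitted <- apply_superposition(model, sp)
      sc <- score_for(fitted)
      if (sc > best) best <- sc
      d <- sqrt(rowSums((fitted - reference)^2))
      new_sel <- which(d < max(d0, 3.0))
      if (length(new_sel) < 3 || identical(new_sel, sel)) break
      sel <- new_sel
    }
    best
  }
  frag_lens <- unique(pmax(4L, c(L, L %/% 2L, L %/% 4L)))
  best <- -Inf
  for (fl in frag_lens) {
    starts <- unique(c(seq(1L, L - fl + 1L, by = max(fl %/% 2L, 1L)), L - fl + 1L))
    for (st in starts) {
      sc <- refine(st:(st + fl - 1L))
      if (sc > best) best <- sc
    }
  }
  list(tm = best, d0 = d0, same_fold = best > 0.5)
}
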