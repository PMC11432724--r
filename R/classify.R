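#' Classify ensemble models against reference states
#'
#' Each model is assigned to the nearest reference state by whole-chain
#' Calpha RMSD against the first conformation of each reference ensemble
#' (the reference-conformation convention used throughout the package). A
#' label is assigned only when the nearest RMSD is below `rmsd_threshold`
#' (default 1.5 A, the conventional cut for calling a model "close to" a
#' state); otherwise the model is `unassigned`. Exact RMSD ties (within
#' 1e-9) are broken by the order of `references`, with a message.
#'
#' @param ens a [conf_ensemble()].
#' @param references named list of reference states (as returned by
#'   [generate_reference_states()]) or of [conf_ensemble()] objects.
#' @param rmsd_threshold assignment cutoff, Angstrom.
#' @param fit_region optional residue-id interval used for the fit.
#' @return a `state_classification`: list with `labels` (per model),
#'   `rmsd` (model x state matrix), `populations` (fractions over states
#'   plus `unassigned`, summing to 1) and `threshold`.
#' @export
classify_states <- function(ens, references, rmsd_threshold = 1.5,
                            fit_region = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"), length(references) >= 1,
            !is.null(names(references)), rmsd_threshold >= 0)
  ref_ens <- lapply(references, function(r)
    if (inherits(r, "conf_ensemble")) r else r$ensemble)
  rmsd <- vapply(ref_ens, function(re)
    rmsd_profile(ens, re, fit_region = fit_region), numeric(n_models(ens)))
  rmsd <- matrix(rmsd, nrow = n_models(ens),
                 dimnames = list(NULL, names(references)))
  nearest <- apply(rmsd, 1, which.min)
  best <- rmsd[cbind(seq_len(nrow(rmsd)), nearest)]
  ties <- rowSums(abs(rmsd - best) < 1e-9) > 1L
  if (any(ties))
    message(sum(ties), " model(s) had tied nearest references; ",
            "broken by reference order")
  labels <- ifelse(best < rmsd_threshold, colnames(rmsd)[nearest], "unassigned")
  lev <- c(names(references), "unassigned")
  populations <- as.numeric(table(factor(labels, levels = lev))) / length(labels)
  names(populations) <- lev
  structure(list(labels = labels, rmsd = rmsd, populations = populations,
                 threshold = rmsd_threshold),
            class = "state_classification")
}

#' @export
print.state_classification <- function(x, ...) {
  cat(sprintf("<state_classification> %d models, RMSD threshold %.2f A\n",
              length(x$labels), x$threshold))
  cat("  populations:",
      paste(sprintf("%s %.1f%%", names(x$populations), 100 * x$populations),
            collapse = ", "), "\n")
  invisible(x)
}

#' Gaussian-kernel density summary
#'
#' Kernel density estimate on an explicit grid with Scott's-rule bandwidth
#' `sd(x) * n^(-1/5)`, used to summarize pLDDT, RMSD and TM-score
#' distributions. When all values are identical the density is degenerate; a
#' delta-like spike is returned with a warning.
#'
#' @param values numeric vector (at least 2 finite values).
#' @param grid evaluation grid; default spans the data plus 3 bandwidths.
#' @param n_grid grid size when `grid` is NULL.
#' @return list with `x` (grid), `y` (density), `bw` (bandwidth).
#' @export
density_summary <- function(values, grid = NULL, n_grid = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stop("need at least 2 finite values", call. = FALSE)
  bw <- sd(values) * length(values)^(-1/5)
  if (bw == 0) {
    warning("all values identical; density is degenerate (delta-like output)")
    bw <- max(abs(values[1]) * 1e-8, 1e-8)
  }
  if (is.null(grid))
    grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw, length.out = n_grid)
  y <- vapply(grid, function(g) mean(dnorm(g - values, sd = bw)), 1)
  list(x = grid, y = y, bw = bw)
}
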