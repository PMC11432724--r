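#' Write an ensemble as a multi-model PDB file
#'
#' Emits standard `MODEL`/`ENDMDL` blocks with one Calpha `ATOM` record per
#' residue; per-residue confidence, when present, is written to the B-factor
#' column (the convention used by structure predictors for pLDDT). The
#' fixed-width PDB coordinate field carries 3 decimals and the B-factor field
#' 2, which bounds round-trip precision.
#'
#' @param ens a [conf_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "conf_ensemble"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  nr <- n_residues(ens)
  for (m in seq_len(n_models(ens))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- model_xyz(ens, m)
    b <- if (is.null(ens$plddt)) rep(0, nr) else ens$plddt[m, ]
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nr), ens$resid, xyz[, 1], xyz[, 2], xyz[, 3], 1.00, b), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' Parses `ATOM` records, extracting one Calpha per residue per model
#' (first alternate location only). Files without `MODEL` records are read
#' as a single-model ensemble. The B-factor column is mapped to per-residue
#' confidence when all values lie on the pLDDT scale `[0, 100]`; otherwise
#' confidence is dropped with a warning. Models with inconsistent residue
#' sets are aligned by residue id on their common intersection, with a
#' warning.
#'
#' @param path PDB file path.
#' @param label provenance label recorded on every model (default: file
#'   name without extension).
#' @return a [conf_ensemble()].
#' @export
read_ensemble <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  atom_idx <- which(rec == "ATOM  " | rec == "HETATM")
  if (!length(atom_idx)) stop("no ATOM records parsed from ", path, call. = FALSE)
  # assign each ATOM line to its MODEL block (0 = before any MODEL record)
  block <- if (length(model_starts)) findInterval(atom_idx, model_starts) else
    rep(1L, length(atom_idx))
  if (length(model_starts) && any(block == 0L)) {
    atom_idx <- atom_idx[block > 0L]
    block <- block[block > 0L]
  }
  al <- lines[atom_idx]
  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  keep <- name == "CA" & altloc %in% c(" ", "A", "1")
  if (!any(keep)) stop("no Calpha atoms found in ", path, call. = FALSE)
  al <- al[keep]; block <- block[keep]
  resid <- as.integer(substr(al, 23, 26))
  xyz <- cbind(as.numeric(substr(al, 31, 38)),
               as.numeric(substr(al, 39, 46)),
               as.numeric(substr(al, 47, 54)))
  bfac <- suppressWarnings(as.numeric(substr(al, 61, 66)))
  models <- unique(block)
  per_model_resid <- split(resid, block)
  common <- Reduce(intersect, per_model_resid)
  if (!length(common))
    stop("models in ", path, " share no residue ids", call. = FALSE)
  if (any(vapply(per_model_resid, length, 1L) != length(common)))
    warning("inconsistent residue sets across models in ", basename(path),
            "; using the ", length(common), "-residue intersection")
  common <- sort(common)
  nmod <- length(models)
  arr <- array(NA_real_, c(nmod, length(common), 3L))
  conf <- matrix(NA_real_, nmod, length(common))
  for (k in seq_len(nmod)) {
    sel <- which(block == models[k])
    # first occurrence per residue id within the model (first altloc already
    # selected; duplicated ids would come from insertion codes)
    sel <- sel[!duplicated(resid[sel])]
    idx <- sel[match(common, resid[sel])]
    arr[k, , ] <- xyz[idx, ]
    conf[k, ] <- bfac[idx]
  }
  has_conf <- all(is.finite(conf))
  if (has_conf && (any(conf < 0) || any(conf > 100))) {
    warning("B-factor values outside [0, 100] in ", basename(path),
            "; not interpretable as pLDDT confidence, dropped")
    has_conf <- FALSE
  }
  conf_ensemble(arr, common, plddt = if (has_conf) conf, label = label)
}

#' Filter ensemble models by mean confidence
#'
#' Retains models whose mean per-residue confidence is at least `threshold`
#' (default 70, the conventional pLDDT cut below which predictor models are
#' considered partially misfolded or disordered and excluded from ensemble
#' analyses). Model order is preserved.
#'
#' @param ens a [conf_ensemble()] with confidence present.
#' @param threshold minimum mean confidence to keep a model.
#' @return filtered [conf_ensemble()].
#' @export
filter_by_confidence <- function(ens, threshold = 70) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (is.null(ens$plddt))
    stop("cannot filter by confidence: ensemble carries no confidence values",
         call. = FALSE)
  keep <- model_confidence(ens) >= threshold
  if (!any(keep)) stop("no models pass the confidence threshold ", threshold,
                       call. = FALSE)
  ens[keep]
}

#' Merge ensembles with provenance labels
#'
#' Concatenates models of several ensembles over their common residue ids.
#' Identical residue id lists are required unless the common intersection
#' covers at least 90% of every input's residues, in which case the merge
#' proceeds on the intersection with a warning. Per-model provenance labels
#' are retained (or overridden by `labels`), so merged ensembles can be
#' regrouped downstream, e.g. for projecting predictor ensembles and
#' experimental reference ensembles in one principal-component frame.
#'
#' @param ensembles list of [conf_ensemble()] objects.
#' @param labels optional character vector, one label per ensemble,
#'   overriding the per-model labels of each input.
#' @return merged [conf_ensemble()]. Confidence is retained only when every
#'   input carries it.
#' @export
merge_ensembles <- function(ensembles, labels = NULL) {
  if (!length(ensembles)) stop("empty ensemble list", call. = FALSE)
  stopifnot(all(vapply(ensembles, inherits, TRUE, "conf_ensemble")))
  if (!is.null(labels)) stopifnot(length(labels) == length(ensembles))
  if (length(ensembles) == 1L) {
    out <- ensembles[[1L]]
    if (!is.null(labels)) out$label <- rep(labels, n_models(out))
    return(out)
  }
  ids <- lapply(ensembles, `[[`, "resid")
  common <- sort(Reduce(intersect, ids))
  if (!length(common))
    stop("ensembles share no residue ids (ranges ",
         paste(vapply(ids, function(r) sprintf("%d-%d", min(r), max(r)), ""),
               collapse = " vs "), ")", call. = FALSE)
  frac <- vapply(ids, function(r) length(common) / length(r), 1)
  if (any(frac < 0.9))
    stop(sprintf("residue overlap too small (%.0f%% of input %d); refusing to merge",
                 100 * min(frac), which.min(frac)), call. = FALSE)
  if (any(frac < 1))
    warning(sprintf("merging on a %d-residue common intersection", length(common)))
  parts <- lapply(ensembles, subset_residues, keep_resid = common)
  xyz <- do.call(abind1, lapply(parts, `[[`, "xyz"))
  have_conf <- vapply(parts, function(e) !is.null(e$plddt), TRUE)
  plddt <- if (all(have_conf)) do.call(rbind, lapply(parts, `[[`, "plddt"))
  if (any(have_conf) && !all(have_conf))
    warning("confidence present in only some inputs; dropped from the merge")
  lab <- if (is.null(labels)) unlist(lapply(parts, `[[`, "label")) else
    rep(labels, vapply(parts, n_models, 1L))
  conf_ensemble(xyz, common, plddt = plddt, label = lab)
}

# bind 3-D arrays along the first (model) dimension
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], 1L)), d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Per-model summary table
#'
#' @param ens a [conf_ensemble()].
#' @return data.frame with model index, provenance label and mean confidence
#'   (NA when absent).
#' @export
ensemble_summary <- function(ens) {
  stopifnot(inherits(ens, "conf_ensemble"))
  data.frame(model = seq_len(n_models(ens)),
             label = ens$label,
             mean_confidence = if (is.null(ens$plddt)) NA_real_ else
               model_confidence(ens))
}
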