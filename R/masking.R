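AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for alanine sequence masking
#'
#' In `full_sequence` mode every position is eligible for substitution; in
#' `targeted` mode only positions inside `regions` are. For each eligible
#' position a per-position substitution probability is drawn uniformly from
#' `[p_min, p_max]` and the residue is replaced by alanine with that
#' probability, emulating random alanine mutagenesis of the input sequence
#' before MSA construction. The default bounds 0.05-0.15 substitute 5-15% of
#' positions in expectation (mean 10%).
#'
#' @param mode `"full_sequence"` or `"targeted"`.
#' @param regions list of length-2 integer vectors, 1-based inclusive
#'   position intervals; required in targeted mode.
#' @param p_min,p_max per-position substitution probability bounds,
#'   `0 <= p_min <= p_max <= 1`.
#' @param n_sequences number of independent masked variants to generate
#'   (default 10).
#' @param seed integer seed; each variant uses an independent sub-seed.
#' @return a `masking_config` list.
#' @export
masking_config <- function(mode = c("full_sequence", "targeted"),
                           regions = NULL, p_min = 0.05, p_max = 0.15,
                           n_sequences = 10, seed = 1) {
  mode <- match.arg(mode)
  if (!(p_min >= 0 && p_min <= p_max && p_max <= 1))
    stop("need 0 <= p_min <= p_max <= 1", call. = FALSE)
  if (mode == "targeted") {
    if (is.null(regions) || !length(regions))
      stop("targeted mode requires `regions`", call. = FALSE)
    if (is.numeric(regions)) regions <- list(regions)
    for (rg in regions)
      if (length(rg) != 2 || rg[1] > rg[2] || rg[1] < 1)
        stop("each region must be a 1-based inclusive interval c(start, end)",
             call. = FALSE)
  }
  stopifnot(n_sequences >= 1)
  structure(list(mode = mode, regions = regions, p_min = p_min, p_max = p_max,
                 n_sequences = as.integer(n_sequences), seed = seed),
            class = "masking_config")
}

check_sequence <- function(native) {
  if (!is.character(native) || length(native) != 1L || !nzchar(native))
    stop("`native` must be a non-empty amino-acid string", call. = FALSE)
  chars <- strsplit(native, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("invalid amino-acid characters: ", paste(bad, collapse = ""),
         call. = FALSE)
  chars
}

#' Mask one sequence variant with random alanine substitutions
#'
#' Iterates over the eligible positions of the native sequence, drawing a
#' per-position probability `p_i ~ U(p_min, p_max)` and substituting with
#' alanine with probability `p_i`. Positions outside the configured regions
#' (targeted mode) are never substituted. Positions that are already alanine
#' are eligible draws whose substitution is a no-op; they are recorded like
#' any other hit so the realized rate stays well defined. Deterministic for
#' a fixed `(seed, variant_index)` pair.
#'
#' @param native amino-acid string (one-letter codes).
#' @param config a [masking_config()].
#' @param variant_index index of the variant (selects the sub-seed).
#' @return list with `sequence` (masked string), `positions` (1-based
#'   substituted positions) and `rate` (substituted positions / sequence
#'   length).
#' @export
mask_sequence <- function(native, config, variant_index = 1L) {
  stopifnot(inherits(config, "masking_config"))
  chars <- check_sequence(native)
  n <- length(chars)
  eligible <- if (config$mode == "full_sequence") seq_len(n) else {
    for (rg in config$regions)
      if (rg[2] > n) stop(sprintf("region [%d, %d] outside sequence of length %d",
                                  rg[1], rg[2], n), call. = FALSE)
    sort(unique(unlist(lapply(config$regions, function(rg) rg[1]:rg[2]))))
  }
  hits <- with_seed(derive_seed(config$seed, variant_index), {
    p <- runif(length(eligible), config$p_min, config$p_max)
    eligible[runif(length(eligible)) < p]
  })
  chars[hits] <- "A"
  list(sequence = paste(chars, collapse = ""),
       positions = hits,
       rate = length(hits) / n)
}

#' Generate a set of masked sequence variants
#'
#' @param native amino-acid string.
#' @param config a [masking_config()].
#' @return a `masked_set`: list with `native`, `config` and `variants`, a
#'   list of `config$n_sequences` results from [mask_sequence()] drawn from
#'   independent sub-seeds.
#' @export
#' @examples
#' cfg <- masking_config("targeted", regions = list(c(10, 30)), seed = 7)
#' set <- generate_masked_set(strrep("GL", 25), cfg)
#' length(set$variants)
generate_masked_set <- function(native, config) {
  stopifnot(inherits(config, "masking_config"))
  variants <- lapply(seq_len(config$n_sequences), function(v)
    mask_sequence(native, config, v))
  structure(list(native = native, config = config, variants = variants),
            class = "masked_set")
}

#' @export
print.masked_set <- function(x, ...) {
  rates <- vapply(x$variants, `[[`, 1, "rate")
  cat(sprintf("<masked_set> %d variants of a %d-residue sequence (%s mode)\n",
              length(x$variants), nchar(x$native), x$config$mode))
  cat(sprintf("  realized substitution rate: mean %.1f%%, range %.1f-%.1f%%\n",
              100 * mean(rates), 100 * min(rates), 100 * max(rates)))
  invisible(x)
}
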