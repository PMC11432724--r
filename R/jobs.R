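#' Configuration for a shallow-MSA prediction run
#'
#' Mirrors the subsampling controls of a ColabFold-style predictor:
#' `max_seqs` is the number of MSA sequences passed to the row/column
#' attention track and `extra_seqs` the number additionally processed by the
#' main stack (default 16:32, the shallow depth that maximizes ensemble
#' diversity). With `num_recycles` recycling iterations each model emits one
#' structure per recycle plus a final refined structure, i.e.
#' `num_recycles + 2` structures; the planner enumerates
#' `n_models * num_seed * (num_recycles + 2)` outputs per input sequence
#' (5 x 1 x 14 = 70 with the defaults).
#'
#' @param max_seqs,extra_seqs MSA subsampling depths (counts >= 1).
#' @param num_recycles recycling iterations (>= 0; default 12).
#' @param num_seed number of random seeds iterated (default 1).
#' @param n_models number of pretrained predictor models (default 5).
#' @param use_dropout whether dropout stays active at prediction time.
#' @return a `job_plan_config` list.
#' @export
job_plan_config <- function(max_seqs = 16, extra_seqs = 32, num_recycles = 12,
                            num_seed = 1, n_models = 5, use_dropout = TRUE) {
  stopifnot(max_seqs >= 1, extra_seqs >= 1, num_recycles >= 0,
            num_seed >= 1, n_models >= 1, is.logical(use_dropout))
  structure(list(max_seqs = as.integer(max_seqs),
                 extra_seqs = as.integer(extra_seqs),
                 num_recycles = as.integer(num_recycles),
                 num_seed = as.integer(num_seed),
                 n_models = as.integer(n_models),
                 use_dropout = use_dropout),
            class = "job_plan_config")
}

#' Enumerate the prediction outputs implied by a job configuration
#'
#' @param sequences character vector of input sequences, or a `masked_set`
#'   (its variants are planned, one job per variant).
#' @param config a [job_plan_config()].
#' @return a `prediction_job_plan`: list with `config`, `jobs` (data.frame
#'   enumerating sequence x model x seed x output, where output is
#'   `recycle_0 .. recycle_R` or `final`), `per_sequence` (outputs per
#'   sequence) and `total`.
#' @export
#' @examples
#' plan <- plan_prediction_jobs("MKV", job_plan_config())
#' plan$per_sequence   # 70 with the defaults
plan_prediction_jobs <- function(sequences, config = job_plan_config()) {
  stopifnot(inherits(config, "job_plan_config"))
  if (inherits(sequences, "masked_set"))
    sequences <- vapply(sequences$variants, `[[`, "", "sequence")
  if (!length(sequences)) stop("need at least one sequence", call. = FALSE)
  outputs <- c(paste0("recycle_", 0:config$num_recycles), "final")
  jobs <- expand.grid(output = outputs,
                      seed_id = seq_len(config$num_seed),
                      model_id = seq_len(config$n_models),
                      sequence_id = seq_along(sequences),
                      stringsAsFactors = FALSE)
  jobs <- jobs[, c("sequence_id", "model_id", "seed_id", "output")]
  per_seq <- config$n_models * config$num_seed * (config$num_recycles + 2L)
  stopifnot(nrow(jobs) == per_seq * length(sequences))
  structure(list(config = config, jobs = jobs,
                 n_sequences = length(sequences),
                 per_model = config$num_recycles + 2L,
                 per_sequence = per_seq,
                 total = per_seq * length(sequences)),
            class = "prediction_job_plan")
}

#' @export
print.prediction_job_plan <- function(x, ...) {
  cat(sprintf("<prediction_job_plan> %d sequence(s) x %d model(s) x %d seed(s) x %d structures = %d outputs\n",
              x$n_sequences, x$config$n_models, x$config$num_seed,
              x$per_model, x$total))
  cat(sprintf("  msa subsampling max_seqs:extra_seqs = %d:%d, dropout %s\n",
              x$config$max_seqs, x$config$extra_seqs,
              if (x$config$use_dropout) "on" else "off"))
  invisible(x)
}

#' Write masked variants and a job manifest for an external predictor
#'
#' Writes one FASTA record per masked variant (headers carry the variant
#' index, masking mode and realized substitution rate) and a JSON manifest
#' listing, per job, the MSA subsampling parameters (`max_seqs:extra_seqs`),
#' recycling settings and the enumerated outputs. The manifest is the
#' hand-off contract to an external prediction runner; this package never
#' executes the predictor itself.
#'
#' @param plan a `prediction_job_plan` built from `masked_set`.
#' @param masked_set a `masked_set` from [generate_masked_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, list with paths `fasta` and `manifest`.
#' @export
write_job_manifest <- function(plan, masked_set, dir) {
  stopifnot(inherits(plan, "prediction_job_plan"),
            inherits(masked_set, "masked_set"))
  if (plan$n_sequences != length(masked_set$variants))
    stop("plan and masked set describe different numbers of sequences",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- vapply(masked_set$variants, `[[`, "", "sequence")
  rates <- vapply(masked_set$variants, `[[`, 1, "rate")
  headers <- sprintf("variant_%02d mode=%s rate=%.4f", seq_along(seqs),
                     masked_set$config$mode, rates)
  fasta <- file.path(dir, "masked_variants.fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(setNames(seqs, headers)),
                              filepath = fasta)
  manifest <- list(
    masking = list(mode = masked_set$config$mode,
                   p_min = masked_set$config$p_min,
                   p_max = masked_set$config$p_max,
                   n_sequences = length(seqs),
                   seed = masked_set$config$seed,
                   regions = masked_set$config$regions),
    msa_subsampling = list(
      max_msa = sprintf("%d:%d", plan$config$max_seqs, plan$config$extra_seqs),
      max_seqs = plan$config$max_seqs,
      extra_seqs = plan$config$extra_seqs),
    prediction = list(num_recycles = plan$config$num_recycles,
                      num_seed = plan$config$num_seed,
                      n_models = plan$config$n_models,
                      use_dropout = plan$config$use_dropout,
                      outputs_per_sequence = plan$per_sequence,
                      total_outputs = plan$total),
    jobs = plan$jobs)
  manifest_path <- file.path(dir, "job_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(fasta = fasta, manifest = manifest_path))
}
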