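#' Pipeline configuration
#'
#' Collects the per-stage settings of the end-to-end synthetic run:
#' simulate fixtures, extract and QC foreign reads, estimate bacterial
#' abundance, deconvolve cell fractions, run the differential tables and
#' the three-case classifier. Unknown argument names are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param out_dir artifact directory.
#' @param seed master seed; stage seeds derive from it.
#' @param synth a [synth_spec()].
#' @param qc a [qc_policy()].
#' @param svr an [svr_params()].
#' @param en an [en_config()].
#' @param tune run swarm tuning of the SVR parameters (slow); default FALSE
#'   uses the reference values in [svr_params()].
#' @param swarm a [swarm_config()] used when `tune = TRUE`.
#' @param repeats classifier split repeats.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, synth = synth_spec(seed = seed),
                            qc = qc_policy(), svr = svr_params(),
                            en = en_config(mu = 0.01, seed = seed),
                            tune = FALSE,
                            swarm = swarm_config(n_particles = 10L,
                                                 n_iters = 15L, seed = seed),
                            repeats = 10L, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 qc = qc, svr = svr, en = en, tune = tune, swarm = swarm,
                 repeats = as.integer(repeats), log_level = log_level),
            class = "pipeline_config")
}

pipe_log <- function(config, ...) {
  if (config$log_level != "quiet") message("[tmijoint] ", ...)
}

stage_done <- function(out_dir, files) {
  all(file.exists(file.path(out_dir, files)))
}

#' Run the end-to-end synthetic pipeline
#'
#' Stages (each skipped when its outputs already exist, so a run is
#' resumable after deleting any stage's files):
#' \enumerate{
#'   \item `simulate` — synthetic mixtures, read set and cohort.
#'   \item `abundance` — EM abundance + Shannon diversity of the read set.
#'   \item `deconv` — (optionally swarm-tuned) SVR cell fractions.
#'   \item `diff` — differential tables for both cohort blocks.
#'   \item `classify` — three-case elastic-net accuracies.
#' }
#' A `manifest.json` capturing package version, seed and all parameters is
#' written last; identical config + seed reproduce identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return the artifact directory, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  spec <- config$synth

  sim_files <- c("signature.tsv", "mixture.tsv", "true_fractions.tsv",
                 "reads.fastq", "candidates.tsv", "genome_lengths.tsv",
                 "bacteria.tsv", "cells.tsv", "labels.tsv")
  if (!stage_done(od, sim_files)) {
    pipe_log(config, "stage simulate")
    S <- make_signature(spec)
    mix <- make_mixtures(S, spec)
    rs <- make_read_set(spec)
    cohort <- make_cohort(spec)
    write_matrix_tsv(S, file.path(od, "signature.tsv"), "gene")
    write_matrix_tsv(mix$X, file.path(od, "mixture.tsv"), "gene")
    write_matrix_tsv(mix$fractions, file.path(od, "true_fractions.tsv"),
                     "sample")
    write_fastq(rs$reads, file.path(od, "reads.fastq"))
    e <- rs$cands$entries
    utils::write.table(e, file.path(od, "candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(names(rs$genome_lengths), rs$genome_lengths),
      file.path(od, "genome_lengths.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    write_matrix_tsv(cohort$bacteria, file.path(od, "bacteria.tsv"), "sample")
    write_matrix_tsv(cohort$cells, file.path(od, "cells.tsv"), "sample")
    utils::write.table(
      data.frame(sample = rownames(cohort$bacteria), label = cohort$labels),
      file.path(od, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  } else pipe_log(config, "stage simulate: outputs present, skipped")

  if (!stage_done(od, "abundance.tsv")) {
    pipe_log(config, "stage abundance")
    cands <- parse_alignment_candidates(
      file.path(od, "candidates.tsv"),
      file.path(od, "genome_lengths.tsv"))
    prof <- em_abundance(cands, error_rate = spec$error_rate)
    ab <- data.frame(genome_id = names(prof$abundances),
                     abundance = as.numeric(prof$abundances))
    utils::write.table(ab, file.path(od, "abundance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(format(shannon_diversity(prof), digits = 10),
               file.path(od, "shannon.txt"))
  } else pipe_log(config, "stage abundance: outputs present, skipped")

  if (!stage_done(od, "fractions.tsv")) {
    pipe_log(config, "stage deconv")
    X <- read_matrix_tsv(file.path(od, "mixture.tsv"))
    S <- read_matrix_tsv(file.path(od, "signature.tsv"))
    params <- config$svr
    if (isTRUE(config$tune)) {
      tuned <- tune_svr(X, S, config = config$swarm, seed = config$seed)
      params <- tuned$params
      jsonlite::write_json(unclass(params), file.path(od, "params.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    fr <- deconvolve(X, S, params)
    write_matrix_tsv(fr$fractions, file.path(od, "fractions.tsv"), "sample")
  } else pipe_log(config, "stage deconv: outputs present, skipped")

  if (!stage_done(od, c("diff_bacteria.tsv", "diff_cells.tsv"))) {
    pipe_log(config, "stage diff")
    labels <- read_labels_tsv(file.path(od, "labels.tsv"))
    for (block in c("bacteria", "cells")) {
      m <- read_matrix_tsv(file.path(od, paste0(block, ".tsv")))
      tab <- differential_table(t(m[labels == 0L, , drop = FALSE]),
                                t(m[labels == 1L, , drop = FALSE]))
      utils::write.table(tab, file.path(od, paste0("diff_", block, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else pipe_log(config, "stage diff: outputs present, skipped")

  if (!stage_done(od, "classification.json")) {
    pipe_log(config, "stage classify")
    labels <- read_labels_tsv(file.path(od, "labels.tsv"))
    bact <- read_matrix_tsv(file.path(od, "bacteria.tsv"))
    cells <- read_matrix_tsv(file.path(od, "cells.tsv"))
    res <- evaluate_three_cases(bact, cells, labels, config$en,
                                repeats = config$repeats)
    jsonlite::write_json(
      lapply(res, function(x) x[c("accuracy_mean", "accuracy_sd")]),
      file.path(od, "classification.json"), auto_unbox = TRUE, digits = NA)
  } else pipe_log(config, "stage classify: outputs present, skipped")

  manifest <- list(
    package = "tmijoint",
    version = as.character(utils::packageVersion("tmijoint")),
    seed = config$seed,
    synth = unclass(config$synth),
    qc = unclass(config$qc),
    svr = unclass(config$svr),
    en = unclass(config$en[setdiff(names(config$en), "mu_grid")]),
    tune = config$tune,
    repeats = config$repeats)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  pipe_log(config, "done: ", od)
  invisible(od)
}
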