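#' Default run configuration
#'
#' Collects every tunable of the pipeline in one list: sketching (`k`,
#' `kappa`, `R`, `master_seed`), segmentation (`T`, `tau`), candidate
#' selection, scoring, and simulator settings. Values supplied in `...`
#' override the defaults; the provenance of each value (default vs
#' override) is recorded so artifacts are self-describing.
#'
#' @param ... named overrides of any default field.
#' @return List of class `bh_config`.
#' @export
bishash_config <- function(...) {
  defaults <- list(
    k = 16L, kappa = 2L, R = 4L, master_seed = 42,
    T = 500L, tau = 300L,
    min_votes = 2L, fraction = 0.8, max_candidates = 10L,
    match = 2L, mismatch = -3L, gap_open = -5L, gap_extend = -2L,
    min_score_fraction = 0.66,
    n_contigs = 1L, contig_len = 200000L, gc_content = 0.42,
    cpg_island_density = 0.01,
    methylation_mode = "random", n_reads = 2000L, read_len = 150L,
    error_rate = 0.01, sim_seed = 7,
    threads = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  cfg$provenance <- setNames(ifelse(names(defaults) %in% names(over),
                                    "override", "default"), names(defaults))
  class(cfg) <- "bh_config"
  cfg
}

config_json <- function(cfg) {
  jsonlite::toJSON(cfg[setdiff(names(cfg), "provenance")], auto_unbox = TRUE)
}

#' Run the full simulate-index-align-evaluate pipeline
#'
#' One-shot desk-scale experiment: generate (or load) a reference, assign a
#' methylation landscape, simulate directional bisulfite reads, build the
#' CT/GA genome index, align, and evaluate against the ground truth. All
#' artifacts are written under `out_dir`; the JSON summary embeds the full
#' configuration.
#'
#' @param config a [bishash_config()].
#' @param out_dir output directory (created if needed).
#' @param reference optional named character vector of contigs; when `NULL`
#'   a synthetic reference is generated from the config.
#' @return List with `eval` (the [evaluate_alignments()] report), `summary`
#'   (align counts), and the artifact `paths`.
#' @export
run_pipeline <- function(config = bishash_config(), out_dir = tempfile("bishash_run_"),
                         reference = NULL) {
  stopifnot(inherits(config, "bh_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(ref = file.path(out_dir, "ref.fa"),
                fastq = file.path(out_dir, "reads.fq"),
                truth = file.path(out_dir, "truth.tsv"),
                index = file.path(out_dir, "ref.bhx"),
                sam = file.path(out_dir, "aligned.sam"),
                json = file.path(out_dir, "summary.json"))
  if (is.null(reference))
    reference <- generate_reference(config$n_contigs, config$contig_len,
                                    config$gc_content, config$cpg_island_density,
                                    seed = config$sim_seed)
  write_fasta(reference, paths$ref)
  profile <- assign_methylation(reference, config$methylation_mode,
                                seed = config$sim_seed + 1)
  sim <- simulate_reads(reference, profile, config$n_reads, config$read_len,
                        config$error_rate, seed = config$sim_seed + 2)
  write_fastq(sim$reads, paths$fastq)
  write_truth(sim$truth, paths$truth)
  params <- index_params(config$T, config$tau,
                         sketch_config(config$k, config$kappa,
                                       master_seed = config$master_seed,
                                       R = config$R))
  gindex <- build_genome_index(reference, params)
  write_index(gindex, paths$index)
  summary <- align_file(paths$fastq, gindex, paths$sam,
                        rule = candidate_rule(config$min_votes, config$fraction,
                                              config$max_candidates),
                        scoring = scoring_scheme(config$match, config$mismatch,
                                                 config$gap_open, config$gap_extend),
                        min_score_fraction = config$min_score_fraction,
                        threads = config$threads)
  ev <- evaluate_alignments(paths$sam, paths$truth, tolerance_bp = 1L)
  jsonlite::write_json(list(config = config[setdiff(names(config), "provenance")],
                            summary = summary, evaluation = unclass(ev)),
                       paths$json, auto_unbox = TRUE, digits = NA)
  list(eval = ev, summary = summary, paths = paths)
}
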