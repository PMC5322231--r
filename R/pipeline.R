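# Pipeline configuration and the end-to-end driver.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the analysis constants as
#' defaults, so a bare run is the reference analysis: trimming at an error
#' probability limit of 0.01 and a 36-base length floor, contig placement at
#' mismatch/gap costs 2/3 with length fraction 0.5 and identity 0.8, read
#' mapping at identity 0.9, a 50-base covered-length presence filter,
#' significance at q = 0.05 and enrichment at |log2 fold change| >= 2.
#' Simulator defaults reproduce the study conditions: four libraries at
#' 50k/175k/205k/55k reads (preserving the real depth asymmetry at desk
#' scale), differential effect of 3 log2 units, and a 5% escaper leak.
#'
#' @param n_transcripts,length_range,gc transcriptome model.
#' @param class_mix,effect_log2,abundance_meanlog,abundance_sdlog truth
#'   model; see [sim_truth()].
#' @param tier1_coverage,tier1_identity,tier2_coverage,tier2_identity
#'   reference-panel model; see [sim_reference_panel()].
#' @param library_sizes,escaper_leak,error_rate,read_length,quality_model
#'   read model; see [sim_read_libraries()].
#' @param mean_fragment,min_fragment contig fragmentation model.
#' @param quality_limit,min_read_length,adapters trimming parameters.
#' @param mismatch_cost,gap_cost,contig_min_identity,min_length_fraction
#'   contig-placement parameters.
#' @param read_min_identity read-mapping identity threshold.
#' @param min_covered_length presence-filter threshold in bases.
#' @param q_cut,fc_cut subtraction cutoffs.
#' @param pi0_lambda lambda grid for the pi0 estimate.
#' @return a validated list of class `ssh_config`.
#' @export
ssh_config <- function(n_transcripts = 1000L,
                       length_range = c(200L, 2000L),
                       gc = 0.5,
                       class_mix = ssh_default_class_mix(),
                       effect_log2 = 3,
                       abundance_meanlog = 0,
                       abundance_sdlog = 1.5,
                       tier1_coverage = 0.6,
                       tier1_identity = 0.9,
                       tier2_coverage = 0.85,
                       tier2_identity = 0.98,
                       library_sizes = c(DF = 50000L, DR = 175000L,
                                         RF = 205000L, RR = 55000L),
                       escaper_leak = 0.05,
                       error_rate = 0.005,
                       read_length = c(36L, 151L),
                       quality_model = "constant",
                       mean_fragment = 500L,
                       min_fragment = 200L,
                       quality_limit = 0.01,
                       min_read_length = 36L,
                       adapters = NULL,
                       mismatch_cost = 2,
                       gap_cost = 3,
                       contig_min_identity = 0.8,
                       min_length_fraction = 0.5,
                       read_min_identity = 0.9,
                       min_covered_length = 50L,
                       q_cut = 0.05,
                       fc_cut = 2,
                       pi0_lambda = seq(0.05, 0.95, by = 0.05)) {
  cfg <- as.list(environment())
  with(cfg, {
    if (quality_limit <= 0 || quality_limit >= 1)
      stop_config("quality_limit must be in (0, 1)")
    if (contig_min_identity <= 0 || contig_min_identity > 1 ||
        read_min_identity <= 0 || read_min_identity > 1)
      stop_config("identity thresholds must be in (0, 1]")
    if (min_length_fraction <= 0 || min_length_fraction > 1)
      stop_config("min_length_fraction must be in (0, 1]")
    if (q_cut <= 0 || q_cut > 1) stop_config("q_cut must be in (0, 1]")
    if (fc_cut < 0) stop_config("fc_cut must be >= 0")
    if (min_covered_length < 0) stop_config("min_covered_length must be >= 0")
  })
  structure(cfg, class = c("ssh_config", "list"))
}

#' Run the full SSH differential-set pipeline on simulated data
#'
#' Executes the stages in order: simulate (transcriptome, panel, truth,
#' reads, contigs), build the tiered reference, trim and map the four
#' libraries, compare the pairs, and build the nS/SnE/SE sets.  The whole
#' run is a pure function of `(config, seed)`.
#'
#' @param config an [ssh_config()].
#' @param seed integer seed.
#' @param outdir optional directory; when given, all report tables and the
#'   run manifest are written there.
#' @param verbose print per-stage progress to standard error.
#' @return object of class `ssh_run`: list with `sim`, `reference`,
#'   `trim_reports`, `quants`, `sets`, `set_table`, `venn`,
#'   `mapping_summary`, `recovery` (truth evaluation), `config`, `seed`.
#' @export
run_ssh_pipeline <- function(config = ssh_config(), seed = 1,
                             outdir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating SSH experiment (n_transcripts=%d, %d reads)",
      config$n_transcripts, sum(config$library_sizes))
  sim <- simulate_ssh_experiment(config, seed = seed)

  say("building tiered reference from %d contigs", length(sim$contigs))
  reference <- build_tiered_reference(
    sim$contigs, sim$panel$tier1, sim$panel$tier2,
    mismatch_cost = config$mismatch_cost, gap_cost = config$gap_cost,
    min_length_fraction = config$min_length_fraction,
    min_identity = config$contig_min_identity)

  trim_reports <- list()
  quants <- list()
  for (lib in ssh_library_ids()) {
    say("trimming and mapping %s (%d reads)", lib,
        nrow(sim$libraries[[lib]]))
    tr <- trim_reads(sim$libraries[[lib]],
                     quality_limit = config$quality_limit,
                     min_length = config$min_read_length,
                     adapters = config$adapters)
    trim_reports[[lib]] <- tr$report
    quants[[lib]] <- map_reads(tr$reads, reference,
                               min_identity = config$read_min_identity,
                               min_length_fraction = config$min_length_fraction)
  }
  trim_reports <- do.call(rbind, trim_reports)

  say("building nS/SnE/SE sets")
  sets <- build_ssh_sets(quants,
                         min_covered_length = config$min_covered_length,
                         q_cut = config$q_cut, fc_cut = config$fc_cut,
                         pi0_lambda = config$pi0_lambda)
  recovery <- truth_recovery(sets, reference, sim$fragments, sim$truth)

  run <- structure(list(
    sim = sim, reference = reference,
    trim_reports = trim_reports, quants = quants, sets = sets,
    set_table = compile_set_table(sets),
    venn = venn_overlap(sets),
    mapping_summary = mapping_summary(quants, trim_reports),
    recovery = recovery,
    config = config, seed = seed), class = "ssh_run")
  if (!is.null(outdir)) write_pipeline_outputs(run, outdir)
  run
}

#' Write the report tables of a pipeline run
#'
#' Emits the combined reference (FASTA), its provenance and summary, the
#' per-library count tables, the two pair comparisons, the set assignment
#' with membership strings, the set-size and Venn tables, the mapping
#' summary, the truth table, and a run manifest listing every output file
#' with its MD5 checksum.  On failure, partial outputs are removed.
#'
#' @param run an `ssh_run` object.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_pipeline_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    emit <- function(path) written <<- c(written, path)
    emit(write_fasta(run$reference$sequences,
                     file.path(outdir, "reference.fasta")))
    emit(write_tsv(run$reference$provenance,
                   file.path(outdir, "reference_provenance.tsv")))
    emit(write_tsv(run$reference$summary,
                   file.path(outdir, "reference_summary.tsv")))
    counts <- do.call(rbind, lapply(ssh_library_ids(), function(lib) {
      df <- run$quants[[lib]]$counts
      df$library <- lib
      df[, c("contig_id", "library", "read_count", "covered_length", "rpkm")]
    }))
    emit(write_tsv(counts, file.path(outdir, "counts.tsv")))
    emit(write_tsv(run$trim_reports, file.path(outdir, "trim_summary.tsv")))
    emit(write_tsv(run$mapping_summary,
                   file.path(outdir, "mapping_summary.tsv")))
    emit(write_tsv(run$sets$diff_drought,
                   file.path(outdir, "diff_drought.tsv")))
    emit(write_tsv(run$sets$diff_recovery,
                   file.path(outdir, "diff_recovery.tsv")))
    assignment <- merge(run$sets$membership, membership_strings(run$sets),
                        by = "contig_id", sort = TRUE)
    emit(write_tsv(assignment, file.path(outdir, "set_assignment.tsv")))
    emit(write_tsv(run$set_table, file.path(outdir, "set_sizes.tsv")))
    emit(write_tsv(run$venn, file.path(outdir, "venn_regions.tsv")))
    emit(write_tsv(run$sim$truth, file.path(outdir, "truth.tsv")))
    manifest <- data.frame(
      file = basename(written),
      md5 = unname(tools::md5sum(written)),
      stringsAsFactors = FALSE)
    manifest <- rbind(manifest,
                      data.frame(file = "seed", md5 = as.character(run$seed),
                                 stringsAsFactors = FALSE))
    write_tsv(manifest, file.path(outdir, "manifest.tsv"))
    invisible(manifest)
  }, error = on_fail)
}

#' @export
print.ssh_run <- function(x, ...) {
  cat(sprintf("SSH pipeline run (seed %s)\n", x$seed))
  cat(sprintf("  transcripts: %d, contigs: %d, reference sequences: %d\n",
              length(x$sim$transcripts), length(x$sim$contigs),
              length(x$reference$sequences)))
  print(x$set_table, row.names = FALSE)
  invisible(x)
}
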