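# Bundled run-summary inputs and report arithmetic.
#
# The package ships, as plain TSV under extdata, the run-level summary
# numbers of the four-library MiSeq experiment the pipeline models (read
# totals before/after trimming, per-library mapping totals, the tier counts
# of the combined reference, and a 20-contig worked example of RPKM
# quadruples with their published set-membership strings).  The report
# functions recompute every derived total and percentage from those inputs.

#' Bundled run-summary tables
#'
#' @return list with `trim` (per-library read totals before and after
#'   trimming, plus orphaned reads), `mapping` (per-library mapped-read
#'   totals against the combined reference), `tiers` (count / mean length /
#'   bases per reference tier), and `assembly` (key/value quantities of the
#'   de novo assembly).
#' @export
ssh_run_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "sshdiff",
                                  mustWork = TRUE)
  list(
    trim = read_tsv(path("miseq_trim_table.tsv"),
                    required = c("library", "paired_reads", "retained_reads",
                                 "broken_reads")),
    mapping = read_tsv(path("miseq_mapping_table.tsv"),
                       required = c("library", "mapped_reads")),
    tiers = read_tsv(path("assembly_tiers.tsv"),
                     required = c("tier", "count", "total_bases")),
    assembly = read_tsv(path("denovo_assembly.tsv"),
                        required = c("quantity", "value")))
}

#' Bundled worked example: 20 RPKM quadruples with published set strings
#'
#' Twenty contigs spanning low to high expression, with their RPKM values
#' in the four libraries and the nS/SnE/SE membership strings they were
#' assigned.  Two rows are flagged `excluded`: their published SE strings
#' cannot be produced from the printed RPKM values by the stated
#' |log2 fold change| >= 2 rule and are documented as known discrepancies
#' rather than special-cased.
#'
#' @return data.frame with `contig_id`, `DF`, `DR`, `RF`, `RR`, `nS`,
#'   `SnE`, `SE`, `excluded`.
#' @export
worked_example_rpkm <- function() {
  read_tsv(system.file("extdata", "worked_example_rpkm.tsv",
                       package = "sshdiff", mustWork = TRUE),
           required = c("contig_id", "DF", "DR", "RF", "RR",
                        "nS", "SnE", "SE", "excluded"))
}

#' Recompute the run-summary arithmetic from the bundled inputs
#'
#' Derives, from the bundled printed inputs, every total and percentage of
#' the run-level summaries: total reads entering the assembly, per-library
#' percent retained and percent mapped, the combined reference size and
#' mean length, the de novo mean contig length, the orphan-tier count, and
#' the mean base coverage.
#'
#' @param tables output of [ssh_run_tables()].
#' @return list of derived quantities.
#' @export
run_summary_arithmetic <- function(tables = ssh_run_tables()) {
  tr <- tables$trim
  mp <- tables$mapping
  ti <- tables$tiers
  asmb <- setNames(tables$assembly$value, tables$assembly$quantity)
  stopifnot(identical(tr$library, mp$library))
  list(
    total_reads_assembled = sum(tr$retained_reads) + sum(tr$broken_reads),
    percent_retained = setNames(
      percent_retained(tr$paired_reads, tr$retained_reads), tr$library),
    percent_mapped = setNames(
      percent_mapped(mp$mapped_reads, tr$retained_reads, tr$broken_reads),
      tr$library),
    reference_contig_count = sum(ti$count),
    reference_total_bases = sum(ti$total_bases),
    reference_mean_length = sum(ti$total_bases) / sum(ti$count),
    denovo_mean_contig_length =
      asmb[["total_contig_bases"]] / asmb[["n_contigs"]],
    tier_orphan_count = asmb[["n_contigs"]] -
      asmb[["tier1_mapped_contigs"]] - asmb[["tier2_mapped_contigs"]],
    mean_base_coverage = mean_base_coverage(
      asmb[["mapped_reads"]], asmb[["mean_read_length"]],
      asmb[["total_contig_bases"]]))
}
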