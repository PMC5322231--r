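# Read trimming, best-hit mapping and RPKM quantification.

#' Quality- and adapter-trim a read library
#'
#' Applies modified-Mott quality trimming on the per-base error
#' probabilities implied by the Phred+33 qualities (running score
#' `limit - e_i`, keeping the maximal-scoring segment), then removes 3'
#' adapters by seeded suffix-prefix matching (at least 10 matching bases,
#' at most one mismatch), and finally drops reads shorter than
#' `min_length`.
#'
#' @param reads an `ssh_reads` data.frame (`read_id`, `sequence`,
#'   `quality`, optional `source_id`).
#' @param quality_limit Mott error-probability limit in `(0, 1)`.
#' @param min_length minimum retained read length in bases.
#' @param adapters optional character vector of 3' adapter sequences.
#' @return list with `reads` (the trimmed library) and `report` (one-row
#'   data.frame: `library_id`, `input_reads`, `retained_reads`,
#'   `percent_retained` rounded to integer, `mean_length_before`,
#'   `mean_length_after`).
#' @export
trim_reads <- function(reads, quality_limit = 0.01, min_length = 36L,
                       adapters = NULL) {
  if (quality_limit <= 0 || quality_limit >= 1)
    stop_config("quality_limit must be in (0, 1)")
  stopifnot(is.data.frame(reads),
            all(c("sequence", "quality") %in% names(reads)))
  lib <- attr(reads, "library_id")
  if (is.null(lib)) lib <- NA_character_
  n_in <- nrow(reads)
  len_before <- if (n_in) mean(nchar(reads$sequence)) else 0

  out <- reads
  if (n_in) {
    b <- .mott_bounds_cpp(out$quality, quality_limit)
    out$sequence <- substring(out$sequence, b[, 1], b[, 2])
    out$quality <- substring(out$quality, b[, 1], b[, 2])
    for (ad in adapters) {
      keep <- .adapter_cut_cpp(out$sequence, toupper(ad), 10L, 1L)
      out$sequence <- substring(out$sequence, 1L, keep)
      out$quality <- substring(out$quality, 1L, keep)
    }
    out <- out[nchar(out$sequence) >= min_length, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "library_id") <- lib
  class(out) <- c("ssh_reads", "data.frame")
  report <- data.frame(
    library_id = lib,
    input_reads = n_in,
    retained_reads = nrow(out),
    percent_retained = percent_retained(n_in, nrow(out)),
    mean_length_before = len_before,
    mean_length_after = if (nrow(out)) mean(nchar(out$sequence)) else 0,
    stringsAsFactors = FALSE)
  list(reads = out, report = report)
}

#' Percentage of reads retained by trimming
#'
#' Rounded to the nearest integer, the convention of run-summary tables.
#' @param input_reads,retained_reads read counts.
#' @return integer percentage (vectorised).
#' @export
percent_retained <- function(input_reads, retained_reads) {
  ifelse(input_reads > 0, round(100 * retained_reads / input_reads), 0)
}

#' Map a read library to a combined reference
#'
#' Best-hit, seeded, ungapped read placement: k-mer seeds vote for
#' (reference, diagonal) candidates, every candidate is verified by direct
#' base comparison, and a read is assigned to the single best-scoring
#' reference provided its aligned fraction is at least
#' `min_length_fraction` and its identity at least `min_identity`.  Reads
#' whose best score is tied between two references are discarded as
#' unresolved ties and counted separately, keeping counts deterministic.
#'
#' @param reads an `ssh_reads` data.frame.
#' @param reference an `ssh_reference` from [build_tiered_reference()], or a
#'   plain DNAStringSet.
#' @param min_identity minimum identity over the read/reference overlap.
#' @param min_length_fraction minimum aligned fraction of the read.
#' @param seed_k seeding k-mer size.
#' @return object of class `ssh_quant`: list with `counts` (data.frame
#'   `contig_id`, `length`, `read_count`, `covered_length`, `rpkm`),
#'   `library_id`, `library_total_mapped`, `n_unmapped`, `n_tie`,
#'   `mean_mapped_read_length`, and `assignment` (per-read reference index;
#'   0 unmapped, -1 tie).
#' @export
map_reads <- function(reads, reference, min_identity = 0.9,
                      min_length_fraction = 0.5, seed_k = 15L) {
  seqs <- if (inherits(reference, "ssh_reference")) reference$sequences
  else reference
  if (length(seqs) == 0) stop_config("reference is empty")
  lens <- Biostrings::width(seqs)
  lib <- attr(reads, "library_id")
  if (nrow(reads) == 0) {
    counts <- data.frame(contig_id = names(seqs), length = lens,
                         read_count = 0L, covered_length = 0L, rpkm = 0,
                         stringsAsFactors = FALSE)
    return(structure(list(counts = counts, library_id = lib,
                          library_total_mapped = 0L, n_unmapped = 0L,
                          n_tie = 0L, mean_mapped_read_length = 0,
                          assignment = integer(0)),
                     class = "ssh_quant"))
  }
  res <- .map_reads_cpp(reads$sequence, as.character(seqs),
                        as.integer(seed_k), min_identity,
                        min_length_fraction)
  total <- res$n_mapped
  counts <- data.frame(
    contig_id = names(seqs), length = lens,
    read_count = res$counts, covered_length = res$covered_length,
    rpkm = if (total > 0) compute_rpkm(res$counts, lens, total) else
      rep(0, length(seqs)),
    stringsAsFactors = FALSE)
  structure(list(
    counts = counts, library_id = lib,
    library_total_mapped = total,
    n_unmapped = sum(res$assignment == 0L),
    n_tie = res$n_tie,
    mean_mapped_read_length = if (total > 0) res$mapped_length_sum / total
    else 0,
    assignment = res$assignment),
    class = "ssh_quant")
}

#' Reads Per Kilobase per Million mapped reads
#'
#' `rpkm = read_count * 1e9 / (contig_length * library_total_mapped)`, the
#' standard depth- and length-normalised expression unit.  The length term
#' is the full reference contig length, not the covered length.
#'
#' @param read_count mapped reads on the contig (vectorised).
#' @param contig_length contig length in bases (> 0).
#' @param library_total_mapped total mapped reads in the library (> 0).
#' @return numeric RPKM values.
#' @export
#' @examples
#' compute_rpkm(10, 1000, 1e6)  # 10
compute_rpkm <- function(read_count, contig_length, library_total_mapped) {
  if (any(contig_length <= 0)) stop_config("contig_length must be > 0")
  if (any(library_total_mapped <= 0))
    stop_config("library_total_mapped must be > 0")
  # double arithmetic: length x total overflows 32-bit integers at depth
  read_count * 1e9 / (as.numeric(contig_length) * library_total_mapped)
}

#' Per-contig presence flags for one library
#'
#' A contig counts as present (detected) in a library when it has at least
#' one mapped read and at least `min_covered_length` covered bases, the
#' filter that removes contigs supported by less than 50 bp of read
#' coverage.
#'
#' @param quant an `ssh_quant` object.
#' @param min_covered_length minimum covered bases.
#' @return data.frame `contig_id`, `present`.
#' @export
presence_filter <- function(quant, min_covered_length = 50L) {
  data.frame(contig_id = quant$counts$contig_id,
             present = quant$counts$read_count >= 1L &
               quant$counts$covered_length >= min_covered_length,
             stringsAsFactors = FALSE)
}

#' Mean base coverage of an assembly
#'
#' `(number of reads mapped * average read length) / total length of
#' contigs`.
#'
#' @param mapped_reads number of mapped reads.
#' @param mean_read_length average mapped read length in bases.
#' @param total_contig_bases total assembly length in bases (> 0).
#' @return coverage multiplier.
#' @export
mean_base_coverage <- function(mapped_reads, mean_read_length,
                               total_contig_bases) {
  if (any(total_contig_bases <= 0))
    stop_config("total_contig_bases must be > 0")
  as.numeric(mapped_reads) * mean_read_length / total_contig_bases
}

#' Percentage of reads mapped, as reported in mapping summaries
#'
#' The denominator is the retained read count plus the orphaned ("broken
#' pair") reads that enter the assembly alongside them; reported at two
#' decimal places.
#'
#' @param mapped,retained,broken read counts (vectorised).
#' @return numeric percentage, 2 decimal places.
#' @export
percent_mapped <- function(mapped, retained, broken = 0) {
  denom <- retained + broken
  ifelse(denom > 0, round(100 * mapped / denom, 2), 0)
}

#' Library mapping summary table
#'
#' One row per library with mapped-read counts, percent mapped, mean mapped
#' read length, and the covered-contig statistics (number of contigs
#' detected, their mean covered length and total covered bases).
#'
#' @param quants named list of `ssh_quant` objects.
#' @param trim_reports data.frame of trim reports (rbind of
#'   [trim_reads()] reports) with `library_id` and `retained_reads`.
#' @param broken named vector of orphan-read counts entering the mapping
#'   denominator (default 0, the single-end case).
#' @return data.frame, one row per library.
#' @export
mapping_summary <- function(quants, trim_reports, broken = NULL) {
  libs <- names(quants)
  if (is.null(broken)) broken <- setNames(rep(0, length(libs)), libs)
  rows <- lapply(libs, function(lib) {
    q <- quants[[lib]]
    retained <- trim_reports$retained_reads[trim_reports$library_id == lib]
    det <- q$counts$read_count >= 1L
    data.frame(
      library_id = lib,
      mapped_reads = q$library_total_mapped,
      percent_mapped = percent_mapped(q$library_total_mapped, retained,
                                      broken[[lib]]),
      mean_read_length = round(q$mean_mapped_read_length, 2),
      contigs_detected = sum(det),
      mean_covered_length = if (any(det))
        round(mean(q$counts$covered_length[det]), 2) else 0,
      covered_bases = sum(q$counts$covered_length),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assembly-level overview numbers
#'
#' The de novo assembly overview: total input reads (retained plus orphan
#' reads across libraries), mean contig length, and mean base coverage.
#'
#' @param retained_reads,broken_reads per-library read counts.
#' @param n_contigs,total_contig_bases contig count and total bases.
#' @param mapped_reads,mean_read_length reads mapped to the assembly and
#'   their average length.
#' @return one-row data.frame with `total_input_reads`,
#'   `mean_contig_length`, `mean_base_coverage`.
#' @export
assembly_overview <- function(retained_reads, broken_reads,
                              n_contigs, total_contig_bases,
                              mapped_reads, mean_read_length) {
  data.frame(
    total_input_reads = sum(retained_reads) + sum(broken_reads),
    mean_contig_length = total_contig_bases / n_contigs,
    mean_base_coverage = mean_base_coverage(mapped_reads, mean_read_length,
                                            total_contig_bases))
}
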