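# Readers and writers for the package's on-disk formats: FASTA, FASTQ
# (Phred+33) and TSV-with-header.  Thin wrappers over Biostrings and base
# utilities that normalise errors to name the offending file (and column,
# for TSV schemas).

#' Read a FASTA file
#' @param path file path.
#' @return DNAStringSet.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_config("input file not found: %s", path)
  tryCatch(Biostrings::readDNAStringSet(path),
           error = function(e)
             stop_config("malformed FASTA in %s: %s", path, conditionMessage(e)))
}

#' Write sequences to FASTA (60-column wrapping)
#' @param x DNAStringSet (or named character vector).
#' @param path file path.
#' @export
write_fasta <- function(x, path) {
  if (!inherits(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file into an `ssh_reads` data.frame
#' @param path file path.
#' @param library_id optional library label attached to the result.
#' @return `ssh_reads` data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path, library_id = NULL) {
  if (!file.exists(path)) stop_config("input file not found: %s", path)
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qx <- S4Vectors::mcols(x)$qualities
    mismatch <- which(Biostrings::width(qx) != Biostrings::width(x))
    if (length(mismatch))
      stop(sprintf("sequence/quality length mismatch at record %d (%s)",
                   mismatch[1], names(x)[mismatch[1]]))
    list(x = x, qual = as.character(qx))
  }, error = function(e)
    stop_config("malformed FASTQ in %s: %s", path, conditionMessage(e)))
  x <- parsed$x
  qual <- parsed$qual
  df <- data.frame(read_id = names(x), sequence = as.character(x),
                   quality = qual, stringsAsFactors = FALSE)
  attr(df, "library_id") <- library_id
  class(df) <- c("ssh_reads", "data.frame")
  df
}

#' Write an `ssh_reads` data.frame to FASTQ (Phred+33)
#' @param reads `ssh_reads` data.frame.
#' @param path file path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a TSV with a required schema
#' @param path file path.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop_config("input file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_config("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
  df
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated SSH experiment to a directory
#'
#' Emits the transcriptome, the two reference tiers, the contigs (FASTA),
#' the four read libraries (FASTQ, Phred+33) and the truth and fragment
#' provenance tables (TSV).
#'
#' @param sim result of [simulate_ssh_experiment()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_fasta(sim$transcripts, file.path(outdir, "transcripts.fasta")),
    write_fasta(sim$panel$tier1, file.path(outdir, "reference_tier1.fasta")),
    write_fasta(sim$panel$tier2, file.path(outdir, "reference_tier2.fasta")),
    write_fasta(sim$contigs, file.path(outdir, "contigs.fasta")),
    write_tsv(sim$truth, file.path(outdir, "truth.tsv")),
    write_tsv(sim$fragments, file.path(outdir, "fragments.tsv")))
  for (lib in names(sim$libraries)) {
    files <- c(files, write_fastq(sim$libraries[[lib]],
                                  file.path(outdir, paste0(lib, ".fastq"))))
  }
  invisible(files)
}
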