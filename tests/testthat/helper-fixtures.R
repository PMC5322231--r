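# Shared fixtures, all generated in code under fixed seeds.

# A desk-scale configuration: one fifth of the default depths, 200
# transcripts.  Used for smoke and determinism tests where the full study
# depth is not needed.
small_config <- function(...) {
  ssh_config(n_transcripts = 200L,
             library_sizes = c(DF = 10000L, DR = 35000L,
                               RF = 41000L, RR = 11000L),
             ...)
}

# Memoised small pipeline run so several test files can share it.
.fixture_env <- new.env(parent = emptyenv())
small_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- run_ssh_pipeline(small_config(), seed = 7)
  }
  .fixture_env$run
}

# Mutate a sequence to an exact identity with deterministic, evenly spaced
# substitutions (independent of the simulator's mutation code).
mutate_evenly <- function(seq, identity) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_sub <- round((1 - identity) * length(chars))
  if (n_sub == 0) return(seq)
  pos <- round(seq(1, length(chars), length.out = n_sub))
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  chars[pos] <- rot[chars[pos]]
  paste(chars, collapse = "")
}

# Random-position variant (uses the session RNG); unlike mutate_evenly it
# leaves long exact runs for seed k-mers with high probability.
mutate_random <- function(seq, identity) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_sub <- round((1 - identity) * length(chars))
  if (n_sub == 0) return(seq)
  pos <- sample.int(length(chars), n_sub)
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  chars[pos] <- rot[chars[pos]]
  paste(chars, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent full-dynamic-programming alignment oracle built on
# Biostrings::pairwiseAlignment with the same scoring scheme (match +1,
# mismatch -2, flat gap -3); returns the accept decision and score under
# the identity/length-fraction rule.
oracle_align <- function(contig, ref, min_identity = 0.8,
                         min_length_fraction = 0.5) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  best <- NULL
  for (q in c(contig, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig))))) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = q, subject = ref, type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 3)
    if (is.null(best) || Biostrings::score(aln) > best$score) {
      pat <- as.character(Biostrings::alignedPattern(aln))
      cols <- nchar(pat)
      best <- list(score = Biostrings::score(aln),
                   identity = Biostrings::nmatch(aln) / cols,
                   af = nchar(gsub("-", "", pat)) / nchar(contig))
    }
  }
  best$accepted <- best$identity >= min_identity &&
    best$af >= min_length_fraction
  best
}

# Build an ssh_quant object directly from per-contig counts, for tests
# that exercise the set logic without a mapping run.
quant_from_counts <- function(contig_id, length, read_count, covered_length,
                              library_id = NA_character_) {
  total <- sum(read_count)
  structure(list(
    counts = data.frame(
      contig_id = contig_id, length = length, read_count = read_count,
      covered_length = covered_length,
      rpkm = if (total > 0) compute_rpkm(read_count, length, total) else
        rep(0, length(read_count)),
      stringsAsFactors = FALSE),
    library_id = library_id,
    library_total_mapped = total,
    n_unmapped = 0L, n_tie = 0L,
    mean_mapped_read_length = 100,
    assignment = integer(0)), class = "ssh_quant")
}
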