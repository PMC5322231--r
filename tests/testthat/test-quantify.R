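mk_reads <- function(seqs, quals = NULL, lib = "DF") {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  df <- data.frame(read_id = sprintf("r%d", seq_along(seqs)),
                   sequence = seqs, quality = quals,
                   stringsAsFactors = FALSE)
  attr(df, "library_id") <- lib
  class(df) <- c("ssh_reads", "data.frame")
  df
}

test_that("trimming keeps clean reads, drops short ones, cuts bad tails and adapters", {
  set.seed(31)
  clean <- mk_reads(vapply(rep(80, 5), random_dna, ""))
  tr <- trim_reads(clean)
  expect_identical(tr$reads$sequence, clean$sequence)  # identity on clean input
  expect_equal(tr$report$percent_retained, 100)

  short <- mk_reads(random_dna(35))
  expect_equal(nrow(trim_reads(short)$reads), 0)

  # low-quality tail (Q2, error prob 0.63 >> limit) is trimmed off
  mixed <- mk_reads(random_dna(100),
                    quals = paste0(strrep("I", 60), strrep("#", 40)))
  out <- trim_reads(mixed)
  expect_equal(nchar(out$reads$sequence), 60)

  # a 3' adapter (12 exact bases) is removed
  adapter <- "CTGTCTCTTATACACATCT"
  withad <- mk_reads(paste0(random_dna(70), substr(adapter, 1, 12)))
  out <- trim_reads(withad, adapters = adapter)
  expect_equal(nchar(out$reads$sequence), 70)

  expect_error(trim_reads(clean, quality_limit = 0), "quality_limit")
})

test_that("percent retained matches the run-summary convention", {
  # the four libraries of the sequencing runs the pipeline models
  tabs <- ssh_run_tables()$trim
  expect_equal(percent_retained(tabs$paired_reads, tabs$retained_reads),
               c(85, 88, 87, 85), ignore_attr = TRUE)
})

test_that("read mapping is best-hit with identity and coverage semantics", {
  set.seed(32)
  refs <- Biostrings::DNAStringSet(c(A = random_dna(500), B = random_dna(400)))
  sub <- substr(as.character(refs[["A"]]), 101, 200)
  q <- map_reads(mk_reads(sub), refs)
  expect_equal(q$counts$read_count, c(1L, 0L))
  expect_equal(q$counts$covered_length, c(100L, 0L))
  expect_equal(q$library_total_mapped, 1L)

  # 15% substitutions: below the 0.9 identity floor, unmapped
  noisy <- mutate_random(sub, 0.85)
  q <- map_reads(mk_reads(noisy), refs)
  expect_equal(q$library_total_mapped, 0L)
  expect_equal(q$n_unmapped, 1L)

  # reverse-strand reads map to the same place
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  q <- map_reads(mk_reads(rc), refs)
  expect_equal(q$counts$read_count[1], 1L)

  # empty read set yields zeroed quantities
  q <- map_reads(mk_reads(character(0)), refs)
  expect_equal(q$library_total_mapped, 0L)
  expect_true(all(q$counts$rpkm == 0))
})

test_that("error-free libraries reproduce the simulator's provenance counts", {
  tx <- sim_transcriptome(40, c(300, 800), seed = 33)
  truth <- sim_truth(tx, seed = 34)
  libs <- sim_read_libraries(tx, truth,
                             library_sizes = c(DF = 4000L, DR = 0L,
                                               RF = 0L, RR = 0L),
                             escaper_leak = 0, error_rate = 0, seed = 35)
  q <- map_reads(libs$DF, tx)   # transcripts themselves as the reference
  expected <- table(factor(libs$DF$source_id, levels = names(tx)))
  expect_equal(q$counts$read_count, as.integer(expected))
  expect_equal(q$library_total_mapped + q$n_unmapped + q$n_tie, 4000L)
  expect_equal(q$n_unmapped, 0L)
})

test_that("RPKM follows its definition and scale invariance", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 500, 1e6), 0)
  expect_error(compute_rpkm(1, 0, 10), "contig_length")
  expect_error(compute_rpkm(1, 10, 0), "library_total")

  set.seed(36)
  k <- sample(0:500, 50, replace = TRUE)
  len <- sample(50:5000, 50, replace = TRUE)
  tot <- sample(1e4:1e7, 50, replace = TRUE)
  oracle <- (k / tot) / (len / 1e3) * 1e6   # independently coded formula
  expect_equal(compute_rpkm(k, len, tot), oracle, tolerance = 1e-12)

  # multiplying counts and totals by a common factor leaves RPKM unchanged
  expect_equal(compute_rpkm(7 * k, len, 7 * tot),
               compute_rpkm(k, len, tot), tolerance = 1e-12)
})

test_that("the presence filter needs a read and 50 covered bases", {
  q <- quant_from_counts(c("a", "b", "c", "d"), length = c(300, 300, 300, 40),
                         read_count = c(1L, 1L, 0L, 5L),
                         covered_length = c(49L, 50L, 0L, 40L))
  pres <- presence_filter(q)
  expect_equal(pres$present, c(FALSE, TRUE, FALSE, FALSE))
  # absence is exactly the RPKM-0-or-short-coverage condition
  expect_true(all(q$counts$rpkm[!pres$present & q$counts$covered_length == 0]
                  == 0))
})

test_that("mean base coverage implements the footnote formula", {
  expect_equal(mean_base_coverage(100, 100, 10000), 1)
  # on the printed assembly inputs the formula gives ~389.4x
  expect_equal(mean_base_coverage(35823839, 110, 10119208),
               35823839 * 110 / 10119208)
  expect_equal(round(mean_base_coverage(35823839, 110, 10119208), 1), 389.4)
  # linearity in mapped reads
  expect_equal(mean_base_coverage(200, 100, 10000),
               2 * mean_base_coverage(100, 100, 10000))
})

test_that("percent mapped uses the retained-plus-orphan denominator", {
  expect_equal(percent_mapped(3151998, 4905542, 228878), 61.39)
  expect_equal(percent_mapped(3511609, 5360350, 250814), 62.58)
  expect_equal(percent_mapped(0, 100, 0), 0)
  tabs <- ssh_run_tables()
  expect_equal(percent_mapped(tabs$mapping$mapped_reads,
                              tabs$trim$retained_reads,
                              tabs$trim$broken_reads),
               c(61.39, 76.33, 69.28, 62.58), ignore_attr = TRUE)
})

test_that("mapping conserves reads and coverage stays within contigs", {
  tx <- sim_transcriptome(30, c(300, 700), seed = 37)
  truth <- sim_truth(tx, seed = 38)
  libs <- sim_read_libraries(tx, truth,
                             library_sizes = c(DF = 3000L, DR = 3000L,
                                               RF = 0L, RR = 0L),
                             error_rate = 0.01, seed = 39)
  frag <- sim_fragment_contigs(tx, seed = 40)
  panel <- sim_reference_panel(tx, seed = 41)
  ref <- build_tiered_reference(frag$contigs, panel$tier1, panel$tier2)
  for (lib in c("DF", "DR")) {
    tr <- trim_reads(libs[[lib]])
    q <- map_reads(tr$reads, ref)
    expect_equal(q$library_total_mapped + q$n_unmapped + q$n_tie,
                 nrow(tr$reads))
    expect_true(all(q$counts$covered_length <= q$counts$length))
    expect_equal(sum(q$counts$read_count), q$library_total_mapped)
  }
})
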