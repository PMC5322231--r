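test_that("transcriptome generation respects bounds and is reproducible", {
  one <- sim_transcriptome(1, c(200, 200), seed = 7)
  expect_length(one, 1)
  expect_equal(Biostrings::width(one), 200)

  tx <- sim_transcriptome(100, c(200, 2000), seed = 1)
  expect_length(tx, 100)
  expect_true(all(Biostrings::width(tx) >= 200 &
                    Biostrings::width(tx) <= 2000))
  expect_false(anyDuplicated(names(tx)) > 0)
  expect_true(all(strsplit(paste(as.character(tx), collapse = ""),
                           "")[[1]] %in% c("A", "C", "G", "T")))

  again <- sim_transcriptome(100, c(200, 2000), seed = 1)
  expect_identical(as.character(tx), as.character(again))

  expect_error(sim_transcriptome(5, c(100, 2000)), "200")
  expect_error(sim_transcriptome(5, c(500, 200)), "increasing")
})

test_that("reference panel realizes coverage fractions and identity", {
  tx <- sim_transcriptome(1000, c(200, 300), seed = 2)
  panel <- sim_reference_panel(tx, tier1_coverage = 0.6,
                               tier1_identity = 0.9, seed = 3)
  expect_length(panel$tier1, 600)  # deterministic count, random choice

  # realized identity by direct per-base comparison on the known pairing
  map1 <- panel$homology_map[panel$homology_map$tier == 1, ]
  hamming <- vapply(seq_len(nrow(map1)), function(i) {
    a <- strsplit(as.character(tx[[map1$transcript_id[i]]]), "")[[1]]
    b <- strsplit(as.character(panel$tier1[[map1$reference_id[i]]]), "")[[1]]
    mean(a == b)
  }, 0)
  expect_true(all(abs(hamming - 0.9) <= 0.01))
  expect_equal(hamming, map1$identity, tolerance = 1e-12)

  ident <- sim_reference_panel(tx, tier1_identity = 1.0, seed = 4)
  map1 <- ident$homology_map[ident$homology_map$tier == 1, ]
  expect_identical(as.character(ident$tier1[map1$reference_id]),
                   setNames(as.character(tx[map1$transcript_id]),
                            map1$reference_id))

  expect_error(sim_reference_panel(tx, tier1_coverage = 0.7,
                                   tier2_coverage = 0.7,
                                   allow_overlap = FALSE, seed = 1),
               "overlap")
})

test_that("truth tables honour the class mix, effects and abundance model", {
  tx <- sim_transcriptome(10000, c(200, 250), seed = 5)

  bg <- sim_truth(tx, class_mix = c(nonDE_background = 1), seed = 6)
  expect_true(all(bg$effect == 0))
  expect_equal(sum(bg$base_abundance), 1)
  # the log-abundances are exactly normal: location/scale match the model
  # (renormalisation only shifts the location)
  lw <- log(bg$base_abundance)
  expect_lt(abs(stats::sd(lw) - 1.5), 1.5 * 0.05)
  # empirical coefficient of variation against the closed-form lognormal
  # CV, at dispersions where the sample CV is a stable statistic
  for (sigma in c(0.5, 1.0)) {
    t2 <- sim_truth(tx, class_mix = c(nonDE_background = 1),
                    abundance_sdlog = sigma, seed = 6)
    cv_emp <- stats::sd(t2$base_abundance) / mean(t2$base_abundance)
    cv_true <- sqrt(exp(sigma^2) - 1)
    expect_lt(abs(cv_emp / cv_true - 1), 0.1)
  }

  truth <- sim_truth(tx, seed = 7)
  expect_setequal(unique(truth$reg_class), ssh_reg_classes())
  tab <- table(truth$reg_class)
  expect_equal(as.integer(tab[names(ssh_default_class_mix())]),
               as.integer(round(ssh_default_class_mix() * 10000)))
  # tails: rare transcripts sit below escapers by construction
  expect_lt(max(truth$base_abundance[truth$reg_class == "nonDE_rare"]),
            min(truth$base_abundance[
              truth$reg_class == "nonDE_abundant_escaper"]))
  expect_true(all(truth$effect[grepl("^nonDE", truth$reg_class)] == 0))
})

test_that("library weights realize the log2 effect as an abundance ratio", {
  truth <- data.frame(
    transcript_id = c("t_up", "t_bg"),
    reg_class = c("up_drought", "nonDE_background"),
    base_abundance = c(0.5, 0.5), effect = c(2, 0),
    stringsAsFactors = FALSE)
  w_df <- library_weights(truth, "DF", escaper_leak = 0)
  w_dr <- library_weights(truth, "DR", escaper_leak = 0)
  # odds of the up transcript against the background are 4x higher in DF
  expect_equal((w_df[1] / w_df[2]) / (w_dr[1] / w_dr[2]), 4)
  # and untouched in the recovery pair
  w_rf <- library_weights(truth, "RF", escaper_leak = 0)
  expect_equal(w_rf[1] / w_rf[2], 1)
})

test_that("read libraries realize effects, conserve totals and are byte-reproducible", {
  tx <- sim_transcriptome(2, c(500, 500), seed = 8)
  truth <- data.frame(
    transcript_id = names(tx),
    reg_class = c("up_drought", "nonDE_background"),
    base_abundance = c(0.5, 0.5), effect = c(2, 0),
    stringsAsFactors = FALSE)
  class(truth) <- c("ssh_truth", "data.frame")
  sizes <- c(DF = 30000L, DR = 30000L, RF = 0L, RR = 0L)
  libs <- sim_read_libraries(tx, truth, library_sizes = sizes,
                             escaper_leak = 0, error_rate = 0,
                             read_length = c(100, 100), seed = 9)
  expect_equal(nrow(libs$DF), 30000)   # conservation
  expect_equal(nrow(libs$RF), 0)       # empty library
  k_df <- table(factor(libs$DF$source_id, levels = names(tx)))
  k_dr <- table(factor(libs$DR$source_id, levels = names(tx)))
  odds_ratio <- (k_df[1] / k_df[2]) / (k_dr[1] / k_dr[2])
  expect_lt(abs(odds_ratio - 4), 0.35)  # multinomial expectation at 30k reads

  # same seed, identical FASTQ bytes
  again <- sim_read_libraries(tx, truth, library_sizes = sizes,
                              escaper_leak = 0, error_rate = 0,
                              read_length = c(100, 100), seed = 9)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(libs$DF, f1); write_fastq(again$DF, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))

  expect_error(
    sim_read_libraries(tx, truth, library_sizes = sizes,
                       read_length = c(36, 600), seed = 1),
    "shortest transcript")
})

test_that("escapers reach all four libraries when the leak is open", {
  tx <- sim_transcriptome(20, c(300, 400), seed = 10)
  truth <- sim_truth(tx, class_mix = c(nonDE_abundant_escaper = 0.25,
                                       nonDE_background = 0.75), seed = 11)
  libs <- sim_read_libraries(tx, truth,
                             library_sizes = c(DF = 4000L, DR = 4000L,
                                               RF = 4000L, RR = 4000L),
                             escaper_leak = 0.05, error_rate = 0,
                             seed = 12)
  esc <- truth$transcript_id[truth$reg_class == "nonDE_abundant_escaper"]
  for (lib in names(libs)) {
    expect_true(all(esc %in% libs[[lib]]$source_id))
  }
})

test_that("fragmentation conserves sequence and hits the target mean length", {
  tx <- sim_transcriptome(1, c(400, 400), seed = 13)
  frag <- sim_fragment_contigs(tx, mean_fragment = 500, seed = 14)
  expect_length(frag$contigs, 1)  # shorter than the target: single fragment
  expect_identical(as.character(frag$contigs[[1]]), as.character(tx[[1]]))

  tx <- sim_transcriptome(300, c(200, 2000), seed = 15)
  frag <- sim_fragment_contigs(tx, seed = 16)
  # concatenation in order reconstructs every transcript
  prov <- frag$provenance
  rebuilt <- vapply(split(seq_len(nrow(prov)), prov$transcript_id),
                    function(i) paste(as.character(
                      frag$contigs[prov$contig_id[i]]), collapse = ""), "")
  expect_identical(unname(rebuilt[names(tx)]),
                   unname(as.character(tx)))
  # base count conservation per transcript
  expect_equal(as.integer(tapply(prov$end - prov$start + 1,
                                 prov$transcript_id, sum)[names(tx)]),
               unname(Biostrings::width(tx)))

  tx10k <- sim_transcriptome(10000, c(200, 2000), seed = 17)
  frag <- sim_fragment_contigs(tx10k, seed = 18)
  mean_len <- mean(Biostrings::width(frag$contigs))
  expect_lt(abs(mean_len / 482 - 1), 0.05)
})
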