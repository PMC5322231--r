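mk_diff <- function(log2fc, q) data.frame(log2fc = log2fc, q = q, p = q)

test_that("nS sets are exactly the presence flags", {
  pres <- lapply(c(DF = 1, DR = 2, RF = 3, RR = 4), function(i)
    data.frame(contig_id = c("a", "b", "c"),
               present = c(TRUE, i %% 2 == 0, FALSE),
               stringsAsFactors = FALSE))
  ns <- build_ns(pres)
  expect_true(all(unlist(ns[1, -1])))                 # present everywhere
  expect_equal(unname(unlist(ns[ns$contig_id == "b", -1])),
               c(FALSE, TRUE, FALSE, TRUE))
  expect_false(any(unlist(ns[3, -1])))                # absent everywhere
})

test_that("pairwise subtraction routes unique, rescued and discarded contigs", {
  pres_f <- c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  pres_r <- c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  d <- mk_diff(log2fc = c(Inf, -Inf, 3.1, -2.5, 0.2, NA),
               q = c(0.001, 0.001, 0.01, 0.04, 0.9, 1))
  s <- pairwise_subtract(pres_f, pres_r, d)
  expect_equal(s$sne_f, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(s$sne_r, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(s$se_f, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$se_r, c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(s$reason,
               c("unique", "unique", "rescued_by_enrichment",
                 "rescued_by_enrichment", "discarded_shared", "absent"))

  # a significant fold change below the cutoff is still discarded
  s2 <- pairwise_subtract(TRUE, TRUE, mk_diff(1.5, 0.001))
  expect_false(s2$se_f | s2$se_r)
  # a large fold change without significance is discarded too
  s3 <- pairwise_subtract(TRUE, TRUE, mk_diff(3.5, 0.2))
  expect_false(s3$se_f | s3$se_r)
})

test_that("sequential subtraction converts masked contigs into RR-unique calls", {
  # one contig in SE_DF, present in both RF and RR -> SE_RR
  rec <- sequential_recovery_subtraction(
    pres_rf = TRUE, pres_rr = TRUE, diff = mk_diff(0.5, 0.5),
    mask_sne = FALSE, mask_se = TRUE)
  expect_false(rec$se_f)
  expect_true(rec$se_r)
  expect_equal(rec$reason_se, "removed_by_cross_subtraction")
  # but at the SnE tier the shared contig is simply shared
  expect_false(rec$sne_f || rec$sne_r)

  # not in any DF set, recovery pair enriched towards RF -> SE_RF
  rec <- sequential_recovery_subtraction(
    pres_rf = TRUE, pres_rr = TRUE, diff = mk_diff(2.8, 0.01),
    mask_sne = FALSE, mask_se = FALSE)
  expect_true(rec$se_f)
  expect_false(rec$se_r)

  # absent from the DF set and unique to RF -> SE_RF by uniqueness
  rec <- sequential_recovery_subtraction(
    pres_rf = TRUE, pres_rr = FALSE, diff = mk_diff(Inf, 0.001),
    mask_sne = FALSE, mask_se = FALSE)
  expect_true(rec$sne_f && rec$se_f)

  # rescued into SE_DF only and unique to RF: blocked at both tiers,
  # keeping SnE nested inside SE
  rec <- sequential_recovery_subtraction(
    pres_rf = TRUE, pres_rr = FALSE, diff = mk_diff(Inf, 0.001),
    mask_sne = FALSE, mask_se = TRUE)
  expect_false(rec$sne_f)
  expect_false(rec$se_f)

  expect_error(sequential_recovery_subtraction(
    TRUE, TRUE, mk_diff(0, 1), mask_sne = TRUE, mask_se = FALSE),
    "subset")
})

test_that("printed RPKM quadruples reproduce the published membership strings", {
  we <- worked_example_rpkm()
  pred <- rpkm_profile_sets(we)
  ok <- pred$nS == we$nS & pred$SnE == we$SnE & pred$SE == we$SE
  # full concordance outside the two documented discrepancy rows
  expect_true(all(ok[!we$excluded]))
  expect_equal(sum(ok), 18)
  # the discrepancy rows disagree only in the SE column
  expect_true(all(pred$nS == we$nS))
  expect_true(all(pred$SnE == we$SnE))
})

test_that("set tiers stay nested and pairs exclusive on randomized inputs", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 300
    ids <- sprintf("c%04d", 1:n)
    quants <- lapply(c(DF = 1, DR = 2, RF = 3, RR = 4), function(i) {
      counts <- rpois(n, lambda = sample(c(0.5, 2, 20), n, replace = TRUE))
      covered <- ifelse(counts > 0,
                        sample(c(30L, 60L, 200L), n, replace = TRUE), 0L)
      quant_from_counts(ids, length = rep(400L, n),
                        read_count = counts, covered_length = covered)
    })
    sets <- build_ssh_sets(quants)
    m <- sets$membership
    for (lib in c("DF", "DR", "RF", "RR")) {
      sne <- m[[paste0("SnE_", lib)]]
      se <- m[[paste0("SE_", lib)]]
      ns <- m[[paste0("nS_", lib)]]
      expect_true(all(se[sne]), info = paste("SnE in SE,", lib))
      expect_true(all(ns[se]), info = paste("SE in nS,", lib))
    }
    expect_false(any(m$SnE_DF & m$SnE_DR))
    expect_false(any(m$SE_DF & m$SE_DR))
    expect_false(any(m$SnE_RF & m$SnE_RR))
    expect_false(any(m$SE_RF & m$SE_RR))
    # cross-subtraction exclusivity
    expect_false(any(m$SE_RF & m$SE_DF))
    expect_false(any(m$SnE_RF & m$SnE_DF))
    # set-size table consistency: SE at least as large as SnE
    tab <- compile_set_table(sets)
    expect_true(all(unlist(tab[tab$set == "SE", -1]) >=
                      unlist(tab[tab$set == "SnE", -1])))
  }
})

test_that("a null simulation leaves the enriched sets nearly empty", {
  tx <- sim_transcriptome(200, c(300, 900), seed = 62)
  truth <- sim_truth(tx, class_mix = c(nonDE_background = 1),
                     abundance_sdlog = 0.5, seed = 63)
  libs <- sim_read_libraries(tx, truth,
                             library_sizes = c(DF = 20000L, DR = 20000L,
                                               RF = 20000L, RR = 20000L),
                             escaper_leak = 0, error_rate = 0, seed = 64)
  quants <- lapply(libs, map_reads, reference = tx)
  sets <- build_ssh_sets(quants)
  tab <- compile_set_table(sets)
  ns_total <- sum(unlist(tab[tab$set == "nS", -1]))
  se_total <- sum(unlist(tab[tab$set == "SE", -1]))
  expect_gt(ns_total, 700)              # everything is detected everywhere
  expect_lt(se_total / ns_total, 0.02)  # only test false positives survive
})

test_that("Venn regions match an enumeration oracle and sum to the union", {
  same <- list(A = letters[1:5], B = letters[1:5],
               C = letters[1:5], D = letters[1:5])
  v <- venn_overlap(same)
  expect_equal(v$count[v$region == "A:B:C:D"], 5)
  expect_equal(sum(v$count), 5)

  disjoint <- list(A = "a", B = "b", C = "c", D = "d")
  v <- venn_overlap(disjoint)
  expect_true(all(v$count[v$region %in% c("A", "B", "C", "D")] == 1))
  expect_equal(sum(v$count), 4)

  set.seed(65)
  for (rep in 1:10) {
    sets <- lapply(setNames(1:4, c("A", "B", "C", "D")), function(i)
      sample(letters[1:20], sample(0:15, 1)))
    v <- venn_overlap(sets)
    # enumeration oracle: classify every id by its membership pattern
    ids <- unique(unlist(sets))
    pat <- vapply(ids, function(id)
      paste(names(sets)[vapply(sets, function(s) id %in% s, TRUE)],
            collapse = ":"), "")
    oracle <- table(pat)
    for (r in v$region) {
      expect_equal(v$count[v$region == r],
                   if (r %in% names(oracle)) as.integer(oracle[[r]]) else 0L)
    }
    expect_equal(sum(v$count), length(ids))
  }
})

test_that("membership strings follow the upper/lower/absent notation", {
  q <- list(
    DF = quant_from_counts("x", 300L, 5L, 200L),
    DR = quant_from_counts("x", 300L, 0L, 0L),
    RF = quant_from_counts("x", 300L, 7L, 200L),
    RR = quant_from_counts("x", 300L, 6L, 200L))
  sets <- build_ssh_sets(q)
  s <- membership_strings(sets)
  expect_equal(s$nS, "DF-RFRR")
  # x is DF-unique, so the drought-forward set masks RF: RR-unique
  expect_equal(s$SnE, "DF-rfRR")
  expect_equal(s$SE, "DF-rfRR")
})
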