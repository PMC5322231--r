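# nS / SnE / SE set construction with sequential in-silico subtraction.
#
# Three set tiers per library:
#   nS  (non-Subtracted):        every contig detected in the library.
#   SnE (Subtracted non-Enriched): contigs unique to one library of a
#        forward/reverse pair.
#   SE  (Subtracted Enriched):   the unique contigs plus shared contigs
#        rescued by a significant count difference (q <= q_cut) with
#        |log2 fold change| >= fc_cut on RPKM.
# The drought pair (DF/DR) is processed first; the recovery pair (RF/RR) is
# then processed with the same-tier drought-forward set subtracted from the
# RF side, so a contig already claimed by DF cannot re-enter through RF and,
# if still present in RR, becomes RR-unique.

#' Non-subtracted (nS) sets
#'
#' One logical column per library: the contigs present (detected) in it.
#'
#' @param presence named list of presence data.frames from
#'   [presence_filter()], one per library, on the same contigs.
#' @return data.frame `contig_id` plus one logical column per library.
#' @export
build_ns <- function(presence) {
  ids <- presence[[1]]$contig_id
  out <- data.frame(contig_id = ids, stringsAsFactors = FALSE)
  for (lib in names(presence)) {
    stopifnot(identical(presence[[lib]]$contig_id, ids))
    out[[lib]] <- presence[[lib]]$present
  }
  out
}

# Core subtraction logic for one forward/reverse pair.  pres_f may already
# be masked by a cross-subtraction.  fc and significant come from the pair's
# DiffResult; uniqueness bypasses the significance test.
.pair_sets <- function(pres_f, pres_r, log2fc, significant,
                       q_gate = TRUE, fc_cut = 2) {
  n <- length(pres_f)
  sne_f <- pres_f & !pres_r
  sne_r <- pres_r & !pres_f
  shared <- pres_f & pres_r
  gate <- if (q_gate) significant else rep(TRUE, n)
  resc_f <- shared & gate & !is.na(log2fc) & log2fc >= fc_cut
  resc_r <- shared & gate & !is.na(log2fc) & log2fc <= -fc_cut
  reason <- rep("absent", n)
  reason[sne_f | sne_r] <- "unique"
  reason[shared] <- "discarded_shared"
  reason[resc_f | resc_r] <- "rescued_by_enrichment"
  list(sne_f = sne_f, sne_r = sne_r,
       se_f = sne_f | resc_f, se_r = sne_r | resc_r,
       reason = reason)
}

#' Subtract a forward/reverse library pair
#'
#' Contigs unique to one library enter its SnE and SE sets (reason
#' `unique`; uniqueness is decided on presence and bypasses the
#' significance test).  Shared contigs are excluded from SnE; they are
#' rescued into SE on the forward side when the count difference is
#' significant (`q <= q_cut`) and `log2fc >= fc_cut`, on the reverse side
#' when significant and `log2fc <= -fc_cut`, and otherwise discarded.
#'
#' @param pres_f,pres_r logical presence vectors over the same contigs.
#' @param diff `ssh_diff` comparison of the pair (forward vs reverse).
#' @param q_cut significance cutoff (inclusive); the `significant` column
#'   of `diff` is recomputed against it.
#' @param fc_cut log2 fold-change cutoff.
#' @return list `sne_f`, `sne_r`, `se_f`, `se_r` (logical vectors) and
#'   `reason` (character).
#' @export
pairwise_subtract <- function(pres_f, pres_r, diff, q_cut = 0.05,
                              fc_cut = 2) {
  stopifnot(length(pres_f) == nrow(diff), length(pres_r) == nrow(diff))
  if (any((pres_f | pres_r) & is.na(diff$p)))
    stop_config("presence without statistics for some contigs")
  .pair_sets(pres_f, pres_r, diff$log2fc, diff$q <= q_cut,
             q_gate = TRUE, fc_cut = fc_cut)
}

#' Recovery-pair subtraction after removing the drought-forward set
#'
#' The subtracted drought-forward library (its SE set) is removed in silico
#' from the recovery-forward side before the RF/RR comparison: a contig
#' claimed by DF can never be called RF, at any tier (reason
#' `removed_by_cross_subtraction`).  The conversion of a masked contig into
#' an RR-unique call is applied per tier with the same-tier drought-forward
#' set: a contig in the SnE (resp. SE) drought-forward set that is still
#' present in RR becomes RR-unique in the SnE (resp. SE) recovery set.
#' This is the only masking scheme under which the set tiers stay nested
#' (`SnE` inside `SE` inside `nS`) for the recovery libraries while the
#' forward/reverse exclusivity of the cross-subtraction is preserved.
#'
#' @param pres_rf,pres_rr logical presence vectors for RF and RR.
#' @param diff `ssh_diff` comparison RF vs RR (on unmasked counts).
#' @param mask_sne,mask_se logical vectors: the drought-forward SnE and SE
#'   sets (`mask_sne` must be a subset of `mask_se`).
#' @param q_cut,fc_cut cutoffs as in [pairwise_subtract()].
#' @return list `sne_f`, `sne_r`, `se_f`, `se_r`, `reason_sne`,
#'   `reason_se`, `masked_sne`, `masked_se`.
#' @export
sequential_recovery_subtraction <- function(pres_rf, pres_rr, diff,
                                            mask_sne, mask_se,
                                            q_cut = 0.05, fc_cut = 2) {
  if (any(mask_sne & !mask_se))
    stop_config("the SnE mask must be a subset of the SE mask")
  masked_sne <- pres_rf & mask_sne
  masked_se <- pres_rf & mask_se
  sig <- diff$q <= q_cut
  tier_sne <- .pair_sets(pres_rf & !mask_sne, pres_rr, diff$log2fc, sig,
                         q_gate = TRUE, fc_cut = fc_cut)
  tier_se <- .pair_sets(pres_rf & !mask_se, pres_rr, diff$log2fc, sig,
                        q_gate = TRUE, fc_cut = fc_cut)
  # the full subtracted drought-forward library blocks RF candidacy at the
  # SnE tier too; without this, a contig rescued into SE_DF but unique to RF
  # would sit in SnE_RF while being excluded from SE_RF
  sne_f <- tier_sne$sne_f & !mask_se
  reason_sne <- tier_sne$reason
  reason_sne[masked_sne | (tier_sne$sne_f & !sne_f)] <-
    "removed_by_cross_subtraction"
  reason_se <- tier_se$reason
  reason_se[masked_se] <- "removed_by_cross_subtraction"
  list(sne_f = sne_f, sne_r = tier_sne$sne_r,
       se_f = tier_se$se_f, se_r = tier_se$se_r,
       reason_sne = reason_sne, reason_se = reason_se,
       masked_sne = masked_sne, masked_se = masked_se)
}

#' Build the full nS/SnE/SE set assignment for the four libraries
#'
#' Runs the drought pair, then the recovery pair with sequential
#' subtraction of the drought-forward sets, and assembles the 12 membership
#' columns.
#'
#' @param quants named list of `ssh_quant` objects (`DF`, `DR`, `RF`,
#'   `RR`) on the same reference.
#' @param min_covered_length presence filter threshold in bases.
#' @param q_cut,fc_cut subtraction cutoffs.
#' @param pi0_lambda passed to [compare_libraries()].
#' @return object of class `ssh_sets`: list with `membership` (data.frame
#'   `contig_id`, `nS_DF` ... `SE_RR`, `reason_drought`,
#'   `reason_recovery_sne`, `reason_recovery_se`), `diff_drought`,
#'   `diff_recovery`, and the parameters used.
#' @export
build_ssh_sets <- function(quants, min_covered_length = 50L,
                           q_cut = 0.05, fc_cut = 2,
                           pi0_lambda = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(setequal(names(quants), ssh_library_ids()))
  presence <- lapply(quants[ssh_library_ids()], presence_filter,
                     min_covered_length = min_covered_length)
  ns <- build_ns(presence)
  diff_d <- compare_libraries(quants$DF, quants$DR, q_cut = q_cut,
                              pi0_lambda = pi0_lambda)
  diff_r <- compare_libraries(quants$RF, quants$RR, q_cut = q_cut,
                              pi0_lambda = pi0_lambda)
  drought <- pairwise_subtract(ns$DF, ns$DR, diff_d, q_cut, fc_cut)
  recovery <- sequential_recovery_subtraction(
    ns$RF, ns$RR, diff_r,
    mask_sne = drought$sne_f, mask_se = drought$se_f,
    q_cut = q_cut, fc_cut = fc_cut)

  membership <- data.frame(
    contig_id = ns$contig_id,
    nS_DF = ns$DF, nS_DR = ns$DR, nS_RF = ns$RF, nS_RR = ns$RR,
    SnE_DF = drought$sne_f, SnE_DR = drought$sne_r,
    SnE_RF = recovery$sne_f, SnE_RR = recovery$sne_r,
    SE_DF = drought$se_f, SE_DR = drought$se_r,
    SE_RF = recovery$se_f, SE_RR = recovery$se_r,
    reason_drought = drought$reason,
    reason_recovery_sne = recovery$reason_sne,
    reason_recovery_se = recovery$reason_se,
    stringsAsFactors = FALSE)
  structure(list(membership = membership,
                 diff_drought = diff_d, diff_recovery = diff_r,
                 q_cut = q_cut, fc_cut = fc_cut,
                 min_covered_length = min_covered_length),
            class = "ssh_sets")
}

#' Set-size table
#'
#' Counts of contigs per set tier and library, the shape of a library-set
#' summary table.
#'
#' @param sets an `ssh_sets` object (or its `membership` data.frame).
#' @return data.frame with rows nS/SnE/SE and one column per library.
#' @export
compile_set_table <- function(sets) {
  m <- if (inherits(sets, "ssh_sets")) sets$membership else sets
  tiers <- c("nS", "SnE", "SE")
  out <- data.frame(set = tiers, stringsAsFactors = FALSE)
  for (lib in ssh_library_ids()) {
    out[[lib]] <- vapply(tiers, function(t) sum(m[[paste(t, lib, sep = "_")]]),
                         0L)
  }
  out
}

#' Region counts of a four-set Venn decomposition
#'
#' Exact cardinalities of the 15 non-empty membership regions of four sets;
#' the regions partition the union.
#'
#' @param sets named list of four vectors (set members), or an `ssh_sets`
#'   object, in which case the four nS sets are decomposed.
#' @return data.frame `region` (member names joined by `:`) and `count`,
#'   including zero-count regions.
#' @export
venn_overlap <- function(sets) {
  if (inherits(sets, "ssh_sets")) {
    m <- sets$membership
    sets <- lapply(ssh_library_ids(), function(lib)
      m$contig_id[m[[paste0("nS_", lib)]]])
    names(sets) <- ssh_library_ids()
  }
  stopifnot(length(sets) == 4, !is.null(names(sets)))
  ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 4))[-1, ]
  colnames(patterns) <- names(sets)
  region <- apply(patterns, 1, function(p)
    paste(names(sets)[as.logical(p)], collapse = ":"))
  count <- apply(patterns, 1, function(p) {
    if (length(ids) == 0) return(0L)
    sum(colSums(t(member) == as.logical(p)) == 4)
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Membership strings and the printed-RPKM classification path.
# ---------------------------------------------------------------------------

#' Membership strings in upper/lower-case notation
#'
#' For each contig and each set tier, a string over the four library slots
#' (DF, DR, RF, RR): upper case when the contig is in the set, lower case
#' when it is present in the library but was lost from the set during
#' processing, and `-` when it is absent from the library.
#'
#' @param sets an `ssh_sets` object.
#' @return data.frame `contig_id`, `nS`, `SnE`, `SE`.
#' @export
membership_strings <- function(sets) {
  m <- sets$membership
  slot <- function(lib, present, in_set) {
    ifelse(!present, "-", ifelse(in_set, lib, tolower(lib)))
  }
  tier_string <- function(tier) {
    parts <- lapply(ssh_library_ids(), function(lib)
      slot(lib, m[[paste0("nS_", lib)]], m[[paste(tier, lib, sep = "_")]]))
    do.call(paste0, parts)
  }
  data.frame(contig_id = m$contig_id,
             nS = tier_string("nS"),
             SnE = tier_string("SnE"),
             SE = tier_string("SE"),
             stringsAsFactors = FALSE)
}

#' Classify contigs from a table of four RPKM values
#'
#' Reproduces the set-assignment pathway from printed RPKM quadruples
#' alone: presence is RPKM > 0, uniqueness drives SnE, shared contigs are
#' assigned by `|log2fc| >= fc_cut`, and the drought-forward sets are
#' subtracted sequentially from the RF side before the recovery comparison.
#' Because a printed RPKM table carries no read counts, the significance
#' gate cannot be evaluated and is treated as passed; this is the
#' worked-example path, not the pipeline path (which uses
#' [build_ssh_sets()] on counts).
#'
#' @param rpkm data.frame with columns `DF`, `DR`, `RF`, `RR` (and
#'   optionally `contig_id`).
#' @param fc_cut log2 fold-change cutoff.
#' @return data.frame `contig_id`, `nS`, `SnE`, `SE` membership strings.
#' @export
rpkm_profile_sets <- function(rpkm, fc_cut = 2) {
  stopifnot(all(ssh_library_ids() %in% names(rpkm)))
  ids <- if ("contig_id" %in% names(rpkm)) rpkm$contig_id
  else sprintf("contig_%d", seq_len(nrow(rpkm)))
  pres <- lapply(ssh_library_ids(), function(lib) rpkm[[lib]] > 0)
  names(pres) <- ssh_library_ids()
  n <- nrow(rpkm)
  fc_d <- log2_fold_change(rpkm$DF, rpkm$DR)
  fc_r <- log2_fold_change(rpkm$RF, rpkm$RR)
  all_sig <- rep(TRUE, n)
  drought <- .pair_sets(pres$DF, pres$DR, fc_d, all_sig, fc_cut = fc_cut)
  fake_diff <- data.frame(log2fc = fc_r, q = 0)
  recovery <- sequential_recovery_subtraction(
    pres$RF, pres$RR, fake_diff,
    mask_sne = drought$sne_f, mask_se = drought$se_f,
    q_cut = 1, fc_cut = fc_cut)
  m <- data.frame(
    contig_id = ids,
    nS_DF = pres$DF, nS_DR = pres$DR, nS_RF = pres$RF, nS_RR = pres$RR,
    SnE_DF = drought$sne_f, SnE_DR = drought$sne_r,
    SnE_RF = recovery$sne_f, SnE_RR = recovery$sne_r,
    SE_DF = drought$se_f, SE_DR = drought$se_r,
    SE_RF = recovery$se_f, SE_RR = recovery$se_r,
    stringsAsFactors = FALSE)
  membership_strings(structure(list(membership = m), class = "ssh_sets"))
}

# ---------------------------------------------------------------------------
# Truth-table evaluation on simulations.
# ---------------------------------------------------------------------------

#' Evaluate set assignments against simulator ground truth
#'
#' Chains provenance from output reference sequences through contigs to
#' source transcripts, and reports, per regulation class, the fraction of
#' transcripts recovered in each set/library (a transcript is recovered
#' when any reference sequence carrying its fragments is in the set), plus
#' union-over-libraries recovery per tier.
#'
#' @param sets an `ssh_sets` object.
#' @param reference the `ssh_reference` the quantification ran against.
#' @param fragments fragment provenance from [sim_fragment_contigs()]
#'   (`contig_id`, `transcript_id`).
#' @param truth the `ssh_truth` table.
#' @return list with `transcript_membership` (per-transcript logical
#'   matrix over the 12 set columns plus `nS_any`, `SnE_any`, `SE_any`)
#'   and `class_recovery` (per-class means of those columns).
#' @export
truth_recovery <- function(sets, reference, fragments, truth) {
  m <- sets$membership
  cmap <- reference$contig_map
  tx_of_contig <- setNames(fragments$transcript_id, fragments$contig_id)
  cons_tx <- data.frame(consensus_id = cmap$consensus_id,
                        transcript_id = unname(tx_of_contig[cmap$contig_id]),
                        stringsAsFactors = FALSE)
  cons_tx <- unique(cons_tx[!is.na(cons_tx$transcript_id), ])
  cols <- setdiff(names(m), c("contig_id", "reason_drought",
                              "reason_recovery_sne", "reason_recovery_se"))
  idx <- match(cons_tx$consensus_id, m$contig_id)
  keep <- !is.na(idx)
  cons_tx <- cons_tx[keep, ]
  idx <- idx[keep]
  tx_ids <- truth$transcript_id
  out <- matrix(FALSE, nrow = length(tx_ids), ncol = length(cols),
                dimnames = list(tx_ids, cols))
  for (col in cols) {
    hit <- cons_tx$transcript_id[m[[col]][idx]]
    out[unique(hit), col] <- TRUE
  }
  tm <- as.data.frame(out)
  tm$transcript_id <- tx_ids
  tm$reg_class <- truth$reg_class
  for (tier in c("nS", "SnE", "SE")) {
    tm[[paste0(tier, "_any")]] <-
      Reduce(`|`, lapply(ssh_library_ids(), function(lib)
        out[, paste(tier, lib, sep = "_")]))
  }
  num_cols <- setdiff(names(tm), c("transcript_id", "reg_class"))
  cr <- do.call(rbind, lapply(split(tm[num_cols], tm$reg_class), colMeans))
  class_recovery <- data.frame(reg_class = rownames(cr), cr,
                               row.names = NULL, stringsAsFactors = FALSE)
  list(transcript_membership = tm, class_recovery = class_recovery)
}

#' @export
print.ssh_sets <- function(x, ...) {
  cat("SSH differential set assignment\n")
  print(compile_set_table(x), row.names = FALSE)
  invisible(x)
}
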