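# Tiered reference assignment and consensus extraction.
#
# Contigs are cascaded through a two-tier reference panel: those placing on
# the tier-1 homolog set become tier "M" consensuses, tier-1 rejects placing
# on the tier-2 same-species set become tier "W" consensuses, and the rest
# are carried through unchanged as tier "A" orphans.  Multiple contigs
# placing on the same reference are merged into a single consensus per
# reference; ambiguous columns get IUPAC codes, uncovered columns inside the
# placed span get "N".

#' Glocal alignment of a contig against one reference sequence
#'
#' Aligns the contig (both strands) against the reference by local dynamic
#' programming with a match reward of 1, the given mismatch cost and a flat
#' gap cost for opening and extending.  The placement is accepted only if
#' the aligned fraction of the contig is at least `min_length_fraction` and
#' the identity over alignment columns (gap columns counting as mismatches)
#' is at least `min_identity`; rejection returns `NULL`, not an error.
#'
#' @param contig a single sequence (character or DNAString); a name, if
#'   present, is carried into the placement.
#' @param reference a single reference sequence.
#' @param mismatch_cost,gap_cost positive alignment costs (defaults 2 and 3;
#'   the gap cost applies to both opening and extension).
#' @param min_length_fraction minimum aligned fraction of the contig.
#' @param min_identity minimum identity over alignment columns.
#' @param band half-width of the alignment band, or `NULL` for the exact
#'   full dynamic program.
#' @return a list of class `ssh_placement` (`contig_id`, `reference_id`,
#'   `r_start`/`r_end` 0-based half-open, `strand`, `score`, `identity`,
#'   `aligned_fraction`, `col_ref`, `col_base`) or `NULL` if rejected.
#' @export
align_contig <- function(contig, reference,
                         mismatch_cost = 2, gap_cost = 3,
                         min_length_fraction = 0.5, min_identity = 0.8,
                         band = NULL) {
  cid <- names(contig)
  rid <- names(reference)
  q <- toupper(as.character(contig)[[1]])
  r <- toupper(as.character(reference)[[1]])
  if (nchar(q) == 0 || nchar(r) == 0)
    stop_config("contig and reference must be non-empty")
  if (is.null(band)) band <- -1L
  best <- NULL
  for (strand in c("+", "-")) {
    qq <- if (strand == "+") q else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    a <- .sw_align_cpp(qq, r, 1L, -as.integer(mismatch_cost),
                       -as.integer(gap_cost), 0L, as.integer(band))
    if (!a$valid) next
    if (is.null(best) || a$score > best$score) {
      best <- a
      best$strand <- strand
    }
  }
  if (is.null(best) || best$columns == 0) return(NULL)
  identity <- best$matches / best$columns
  af <- (best$q_end - best$q_start) / nchar(q)
  if (af < min_length_fraction || identity < min_identity) return(NULL)
  structure(list(
    contig_id = if (is.null(cid)) NA_character_ else cid,
    reference_id = if (is.null(rid)) NA_character_ else rid,
    r_start = best$r_start, r_end = best$r_end,
    strand = best$strand, score = best$score,
    identity = identity, aligned_fraction = af,
    col_ref = best$col_ref, col_base = best$col_base),
    class = "ssh_placement")
}

# Consensus over one reference from aligned columns of >= 1 placements.
# col_ref_list: list of integer vectors (0-based reference positions),
# col_base_list: matching single strings of contig bases.
consensus_from_columns <- function(col_ref_list, col_base_list) {
  span_lo <- min(vapply(col_ref_list, min, 0L))
  span_hi <- max(vapply(col_ref_list, max, 0L))
  len <- span_hi - span_lo + 1L
  mask <- integer(len)
  for (i in seq_along(col_ref_list)) {
    pos <- col_ref_list[[i]] - span_lo + 1L
    bases <- strsplit(col_base_list[[i]], "", fixed = TRUE)[[1]]
    bits <- .base_mask[bases]
    keep <- !is.na(bits)   # non-ACGT contig symbols carry no information
    if (!all(keep)) { pos <- pos[keep]; bits <- bits[keep] }
    mask[pos] <- bitwOr(mask[pos], as.integer(bits))
  }
  lut <- c("N", iupac_from_mask())    # mask 0 -> N (covered span, no base)
  list(sequence = paste(lut[mask + 1L], collapse = ""),
       start = span_lo, end = span_hi + 1L)
}

#' Extract a consensus sequence from placements on one reference
#'
#' Collapses one or more contig placements on the same reference into a
#' single consensus spanning the union of the placed intervals.  Columns
#' carrying exactly one distinct base take that base; columns where
#' placements disagree take the IUPAC code of the observed base set;
#' columns inside the span covered by no placement (including deletion
#' columns) take `N`.
#'
#' @param reference the reference sequence the placements refer to (only its
#'   identity is checked; character or DNAString with a name, or a plain id
#'   string).
#' @param placements list of `ssh_placement` objects on that reference.
#' @return list with `consensus_id`, `sequence`, `start`, `end` (0-based
#'   half-open span on the reference) and `contig_ids`.
#' @export
extract_consensus <- function(reference, placements) {
  if (length(placements) < 1)
    stop_config("at least one placement is required")
  rid <- names(reference)
  ref_ids <- vapply(placements, `[[`, "", "reference_id")
  if (length(unique(ref_ids)) != 1)
    stop_config("placements refer to different references")
  if (!is.null(rid) && !is.na(ref_ids[1]) && !is.na(rid) && rid != ref_ids[1])
    stop_config("placements do not refer to the given reference")
  cons <- consensus_from_columns(lapply(placements, `[[`, "col_ref"),
                                 lapply(placements, `[[`, "col_base"))
  list(consensus_id = ref_ids[1], sequence = cons$sequence,
       start = cons$start, end = cons$end,
       contig_ids = vapply(placements, `[[`, "", "contig_id"))
}

#' Seeded best-hit placement of many contigs on a reference panel
#'
#' The production placement path of the tier builder: k-mer seeds nominate
#' candidate references and diagonals, each candidate is aligned by banded
#' dynamic programming around the seeded diagonal, and the best accepted
#' placement per contig is kept (score ties across references broken by the
#' lowest reference index and flagged ambiguous).  With a generous band
#' this reproduces the decisions of the full dynamic program provided the
#' contig shares at least one seed k-mer with its reference.
#'
#' @param contigs,references DNAStringSets (or character vectors).
#' @param mismatch_cost,gap_cost,min_length_fraction,min_identity acceptance
#'   parameters as in [align_contig()].
#' @param seed_k seeding k-mer size.
#' @param band band half-width around the seeded diagonal.
#' @return data.frame with one row per contig: `contig_id`, `accepted`,
#'   `reference_id`, `strand`, `score`, `identity`, `aligned_fraction`,
#'   `r_start`, `r_end`, `ambiguous`.
#' @export
place_contigs <- function(contigs, references,
                          mismatch_cost = 2, gap_cost = 3,
                          min_length_fraction = 0.5, min_identity = 0.8,
                          seed_k = 13L, band = 48L) {
  hits <- .map_contigs_cpp(as.character(contigs), as.character(references),
                           as.integer(seed_k), as.integer(band),
                           1L, -as.integer(mismatch_cost),
                           -as.integer(gap_cost),
                           min_identity, min_length_fraction)
  ref_ids <- names(references)
  if (is.null(ref_ids)) ref_ids <- as.character(seq_along(references))
  data.frame(
    contig_id = if (is.null(names(contigs))) as.character(seq_along(contigs))
    else names(contigs),
    accepted = !is.na(hits$ref),
    reference_id = ifelse(is.na(hits$ref), NA_character_,
                          ref_ids[hits$ref]),
    strand = hits$strand, score = hits$score,
    identity = hits$identity, aligned_fraction = hits$aligned_fraction,
    r_start = hits$r_start, r_end = hits$r_end,
    ambiguous = hits$ambiguous,
    stringsAsFactors = FALSE)
}

# Run the seeded mapper for one tier and build per-reference consensuses.
.tier_pass <- function(contigs, refs, tier, prefix, params) {
  n <- length(contigs)
  if (n == 0 || length(refs) == 0) {
    return(list(
      consensus = Biostrings::DNAStringSet(),
      provenance = data.frame(consensus_id = character(), tier = character(),
                              contig_ids = character(),
                              n_contigs = integer(),
                              ambiguous = logical(),
                              stringsAsFactors = FALSE),
      contig_map = data.frame(contig_id = character(),
                              consensus_id = character(),
                              stringsAsFactors = FALSE),
      unplaced = contigs))
  }
  hits <- .map_contigs_cpp(as.character(contigs), as.character(refs),
                           as.integer(params$seed_k),
                           as.integer(params$band),
                           1L, -as.integer(params$mismatch_cost),
                           -as.integer(params$gap_cost),
                           params$min_identity, params$min_length_fraction)
  placed <- !is.na(hits$ref)
  out_cons <- character(0)
  out_names <- character(0)
  prov <- list()
  cmap <- list()
  if (any(placed)) {
    by_ref <- split(which(placed), hits$ref[placed])
    ref_ids <- names(refs)
    for (ri_chr in names(by_ref)) {
      ri <- as.integer(ri_chr)
      members <- by_ref[[ri_chr]]
      cons <- consensus_from_columns(hits$col_ref[members],
                                     as.list(unlist(hits$col_base[members])))
      cid <- paste0(prefix, ref_ids[ri])
      out_cons <- c(out_cons, cons$sequence)
      out_names <- c(out_names, cid)
      prov[[cid]] <- data.frame(
        consensus_id = cid, tier = tier,
        contig_ids = paste(names(contigs)[members], collapse = ","),
        n_contigs = length(members),
        ambiguous = any(hits$ambiguous[members]),
        stringsAsFactors = FALSE)
      cmap[[cid]] <- data.frame(contig_id = names(contigs)[members],
                                consensus_id = cid,
                                stringsAsFactors = FALSE)
    }
  }
  cons_set <- Biostrings::DNAStringSet(out_cons)
  names(cons_set) <- out_names
  list(consensus = cons_set,
       provenance = if (length(prov)) do.call(rbind, c(prov, make.row.names = FALSE))
       else data.frame(consensus_id = character(), tier = character(),
                       contig_ids = character(), n_contigs = integer(),
                       ambiguous = logical(), stringsAsFactors = FALSE),
       contig_map = if (length(cmap)) do.call(rbind, c(cmap, make.row.names = FALSE))
       else data.frame(contig_id = character(), consensus_id = character(),
                       stringsAsFactors = FALSE),
       unplaced = contigs[!placed])
}

#' Build the combined tiered reference from contigs and a reference panel
#'
#' Three-pass cascade: contigs are first placed on the tier-1 homolog set
#' (tier `M`), the rejects on the tier-2 same-species set (tier `W`), and
#' the remaining orphans are kept unchanged (tier `A`).  Contigs placing on
#' the same reference sequence are merged into one consensus, which is why
#' the combined reference usually holds fewer sequences than there were
#' contigs.
#'
#' @param contigs DNAStringSet of assembled contigs.
#' @param tier1,tier2 DNAStringSets of the two reference tiers (an
#'   [sim_reference_panel()] provides both).
#' @param mismatch_cost,gap_cost,min_length_fraction,min_identity alignment
#'   acceptance parameters, see [align_contig()].
#' @param seed_k k-mer size used to seed candidate references.
#' @param band alignment band half-width around the seeded diagonal.
#' @return object of class `ssh_reference`: list with `sequences`
#'   (DNAStringSet of consensuses and orphans), `provenance` (one row per
#'   output sequence), `contig_map` (contig to output sequence), and
#'   `summary` (per-tier and combined counts, mean lengths and total bases).
#' @export
build_tiered_reference <- function(contigs, tier1, tier2,
                                   mismatch_cost = 2, gap_cost = 3,
                                   min_length_fraction = 0.5,
                                   min_identity = 0.8,
                                   seed_k = 13L, band = 48L) {
  params <- list(mismatch_cost = mismatch_cost, gap_cost = gap_cost,
                 min_length_fraction = min_length_fraction,
                 min_identity = min_identity, seed_k = seed_k, band = band)
  pM <- .tier_pass(contigs, tier1, "M", "refM_", params)
  pW <- .tier_pass(pM$unplaced, tier2, "W", "refW_", params)
  orphans <- pW$unplaced
  orphan_prov <- data.frame(
    consensus_id = names(orphans),
    tier = rep("A", length(orphans)),
    contig_ids = names(orphans),
    n_contigs = rep(1L, length(orphans)),
    ambiguous = rep(FALSE, length(orphans)),
    stringsAsFactors = FALSE)
  orphan_map <- data.frame(contig_id = names(orphans),
                           consensus_id = names(orphans),
                           stringsAsFactors = FALSE)

  sequences <- c(pM$consensus, pW$consensus, orphans)
  provenance <- rbind(pM$provenance, pW$provenance, orphan_prov)
  contig_map <- rbind(pM$contig_map, pW$contig_map, orphan_map)

  structure(list(sequences = sequences, provenance = provenance,
                 contig_map = contig_map,
                 summary = reference_summary_table(sequences, provenance),
                 params = params),
            class = "ssh_reference")
}

#' Per-tier summary of a combined reference
#'
#' Counts, mean lengths and total bases per tier plus the combined totals,
#' in the shape of a reference-assembly summary table.
#'
#' @param sequences DNAStringSet of the combined reference.
#' @param provenance provenance data.frame with a `tier` column.
#' @return data.frame with rows `M`, `W`, `A`, `combined`.
#' @export
reference_summary_table <- function(sequences, provenance) {
  stopifnot(length(sequences) == nrow(provenance))
  widths <- Biostrings::width(sequences)
  rows <- lapply(c("M", "W", "A"), function(t) {
    sel <- provenance$tier == t
    data.frame(tier = t, count = sum(sel),
               mean_length = if (any(sel)) mean(widths[sel]) else 0,
               total_bases = sum(widths[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(tier = "combined", count = length(sequences),
                        mean_length = if (length(sequences)) mean(widths) else 0,
                        total_bases = sum(widths),
                        stringsAsFactors = FALSE))
}

#' @export
print.ssh_reference <- function(x, ...) {
  cat("Combined tiered SSH reference\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
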