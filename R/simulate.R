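# Synthetic SSH experiment generator.
#
# The simulator emulates the shape of a four-library SSH deep-sequencing
# experiment: a transcriptome of short transcripts, a two-tier reference
# panel (a diverged cross-species homolog set and a close same-species
# transcriptome), a truth table of regulation classes with lognormal
# abundances, four read libraries with very different depths, and the
# fragmented contigs an assembler would produce from SSH cDNA.

#' Simulate a transcript set
#'
#' Generates `n_transcripts` random nucleotide sequences with lengths drawn
#' uniformly from `length_range`.  Base composition is uniform unless `gc`
#' is changed.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param length_range integer pair, minimum and maximum transcript length in
#'   bases; the minimum must be >= 200 (shorter sequences are below the
#'   usual minimum contig length of SSH assemblies).
#' @param gc GC content in `[0, 1]`.
#' @param seed integer seed for reproducibility, or `NULL` to use the
#'   current RNG stream.
#' @return a [Biostrings::DNAStringSet] with unique names `tx00001, ...`.
#' @export
#' @examples
#' tx <- sim_transcriptome(5, c(200, 400), seed = 1)
#' width(tx)
sim_transcriptome <- function(n_transcripts, length_range = c(200L, 2000L),
                              gc = 0.5, seed = NULL) {
  if (length(n_transcripts) != 1 || n_transcripts < 1)
    stop_config("n_transcripts must be a single value >= 1")
  if (length(length_range) != 2 || length_range[1] > length_range[2])
    stop_config("length_range must be an increasing pair")
  if (length_range[1] < 200)
    stop_config("minimum transcript length must be >= 200 bases")
  if (gc < 0 || gc > 1) stop_config("gc must be in [0, 1]")
  n <- as.integer(n_transcripts)
  with_seed(seed, {
    lens <- sample.int(length_range[2] - length_range[1] + 1L, n,
                       replace = TRUE) + length_range[1] - 1L
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    all <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE,
                  prob = prob)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs <- substring(paste(all, collapse = ""), starts, ends)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("tx%05d", seq_len(n))
    out
  })
}

# Mutate a sequence to a target identity by random substitutions; returns
# the mutated string and the realized identity.
.mutate_to_identity <- function(seq, identity) {
  len <- nchar(seq)
  n_sub <- round((1 - identity) * len)
  if (n_sub == 0) return(list(seq = seq, identity = 1))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(len, n_sub)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), identity = 1 - n_sub / len)
}

#' Simulate a two-tier reference panel
#'
#' Builds the two reference sets a tiered assembly cascades through: a
#' tier-1 set of diverged homologs (the cross-species coding-sequence
#' analogue) covering a fraction of the transcripts at a configurable
#' sequence identity, and a tier-2 set of near-identical same-species
#' sequences.  Transcripts covered by neither tier remain orphans.
#' Divergence is introduced by substitutions only.
#'
#' @param transcripts a [Biostrings::DNAStringSet] from [sim_transcriptome()].
#' @param tier1_coverage,tier2_coverage fraction of transcripts with a
#'   homolog in each tier; the number of covered transcripts is the rounded
#'   count (deterministic), the choice of transcripts is random.
#' @param tier1_identity,tier2_identity per-base identity of each homolog to
#'   its source transcript.
#' @param allow_overlap if `TRUE` (default) the two tiers are drawn
#'   independently and may cover the same transcript; if `FALSE` they are
#'   disjoint and their coverages must sum to at most 1.
#' @param seed integer seed or `NULL`.
#' @return a list of class `ssh_ref_panel` with elements `tier1`, `tier2`
#'   (DNAStringSets) and `homology_map` (data.frame with `transcript_id`,
#'   `tier`, `reference_id`, `identity`).
#' @export
sim_reference_panel <- function(transcripts,
                                tier1_coverage = 0.6, tier1_identity = 0.9,
                                tier2_coverage = 0.85, tier2_identity = 0.98,
                                allow_overlap = TRUE, seed = NULL) {
  for (v in c(tier1_coverage, tier1_identity, tier2_coverage, tier2_identity))
    if (v <= 0 || v > 1) stop_config("coverages and identities must be in (0, 1]")
  n <- length(transcripts)
  if (!allow_overlap && tier1_coverage + tier2_coverage > 1)
    stop_config("tier coverages exceed 1 and tiers may not overlap")
  with_seed(seed, {
    n1 <- round(tier1_coverage * n)
    n2 <- round(tier2_coverage * n)
    pick1 <- sort(sample.int(n, n1))
    pool2 <- if (allow_overlap) seq_len(n) else setdiff(seq_len(n), pick1)
    pick2 <- sort(sample(pool2, min(n2, length(pool2))))
    seqs <- as.character(transcripts)
    ids <- names(transcripts)

    make_tier <- function(pick, identity, prefix, tier) {
      mut <- lapply(seqs[pick], .mutate_to_identity, identity = identity)
      set <- Biostrings::DNAStringSet(vapply(mut, `[[`, "", "seq"))
      names(set) <- paste0(prefix, ids[pick])
      map <- data.frame(
        transcript_id = ids[pick], tier = tier,
        reference_id = names(set),
        identity = vapply(mut, `[[`, 0, "identity"),
        row.names = NULL, stringsAsFactors = FALSE)
      list(set = set, map = map)
    }
    t1 <- make_tier(pick1, tier1_identity, "hom_", 1L)
    t2 <- make_tier(pick2, tier2_identity, "sps_", 2L)
    structure(list(tier1 = t1$set, tier2 = t2$set,
                   homology_map = rbind(t1$map, t2$map)),
              class = "ssh_ref_panel")
  })
}

#' Regulation classes recognised by the simulator
#' @export
ssh_reg_classes <- function() {
  c("up_drought", "down_drought", "up_recovery", "down_recovery",
    "nonDE_rare", "nonDE_abundant_escaper", "nonDE_background")
}

#' Default regulation-class mixture
#'
#' Ten percent of transcripts in each of the four differential classes, a
#' substantial pool of rare non-differential transcripts (the dominant
#' false-positive class of SSH experiments), a small pool of abundant
#' transcripts that escape subtraction, and a non-differential background.
#' @export
ssh_default_class_mix <- function() {
  c(up_drought = 0.10, down_drought = 0.10,
    up_recovery = 0.10, down_recovery = 0.10,
    nonDE_rare = 0.15, nonDE_abundant_escaper = 0.05,
    nonDE_background = 0.40)
}

#' Assign ground-truth regulation classes and abundances
#'
#' Draws a regulation class for every transcript according to `class_mix`
#' (exact counts by largest remainder, random placement) and a relative
#' abundance from a lognormal model.  Rare non-differential transcripts are
#' drawn from the low tail of the abundance distribution and abundant
#' escapers from the high tail, reproducing the two contamination classes
#' that generate false positives in SSH libraries.  Differential classes
#' carry a log2 effect applied in their forward/reverse contrast; all
#' non-differential classes have effect 0.
#'
#' @param transcripts DNAStringSet of transcripts.
#' @param class_mix named proportions over [ssh_reg_classes()]; must sum to 1.
#' @param effect_log2 magnitude (>= 0) of the log2 fold change of
#'   differential transcripts.
#' @param abundance_meanlog,abundance_sdlog lognormal abundance parameters.
#' @param rare_quantile,escaper_quantile tail quantiles from which the rare
#'   and escaper abundances are drawn.
#' @param seed integer seed or `NULL`.
#' @return data.frame of class `ssh_truth` with columns `transcript_id`,
#'   `reg_class`, `base_abundance` (weights summing to 1) and `effect`.
#' @export
sim_truth <- function(transcripts, class_mix = ssh_default_class_mix(),
                      effect_log2 = 3,
                      abundance_meanlog = 0, abundance_sdlog = 1.5,
                      rare_quantile = 0.1, escaper_quantile = 0.9,
                      seed = NULL) {
  n <- length(transcripts)
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% ssh_reg_classes()))
    stop_config("class_mix must be named with recognised regulation classes")
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop_config("class_mix must sum to 1")
  if (effect_log2 < 0) stop_config("effect_log2 must be >= 0")
  with_seed(seed, {
    # exact class counts by largest remainder, then random placement
    raw <- class_mix * n
    cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    cls <- sample(rep(names(class_mix), times = cnt))

    ab <- rlnorm(n, abundance_meanlog, abundance_sdlog)
    is_rare <- cls == "nonDE_rare"
    is_esc <- cls == "nonDE_abundant_escaper"
    if (any(is_rare))
      ab[is_rare] <- qlnorm(runif(sum(is_rare), 0, rare_quantile),
                            abundance_meanlog, abundance_sdlog)
    if (any(is_esc))
      ab[is_esc] <- qlnorm(runif(sum(is_esc), escaper_quantile, 1),
                           abundance_meanlog, abundance_sdlog)

    eff <- ifelse(cls %in% c("up_drought", "down_drought",
                             "up_recovery", "down_recovery"),
                  effect_log2, 0)
    out <- data.frame(transcript_id = names(transcripts),
                      reg_class = cls,
                      base_abundance = ab / sum(ab),
                      effect = eff,
                      row.names = NULL, stringsAsFactors = FALSE)
    class(out) <- c("ssh_truth", "data.frame")
    out
  })
}

# Which truth class is enriched in which library.
.enriched_class <- c(DF = "up_drought", DR = "down_drought",
                     RF = "up_recovery", RR = "down_recovery")

#' Per-library transcript sampling weights
#'
#' Applies the regulation effects and the escaper leak to the base
#' abundances of a truth table and renormalises, giving the multinomial
#' sampling weights of one library.  A differential transcript is
#' `2^effect`-fold enriched in the library that captures it and stays at its
#' base abundance elsewhere.  With `escaper_leak > 0`, abundant escapers
#' contribute the leaked fraction of their abundance to every library; with
#' `escaper_leak = 0` they follow the plain abundance model.
#'
#' @param truth an `ssh_truth` data.frame.
#' @param library_id one of `"DF"`, `"DR"`, `"RF"`, `"RR"`.
#' @param escaper_leak fraction in `[0, 1]`.
#' @return numeric weights summing to 1.
#' @export
library_weights <- function(truth, library_id, escaper_leak = 0.05) {
  library_id <- match.arg(library_id, ssh_library_ids())
  w <- truth$base_abundance
  hit <- truth$reg_class == .enriched_class[[library_id]]
  w[hit] <- w[hit] * 2^truth$effect[hit]
  if (escaper_leak > 0) {
    esc <- truth$reg_class == "nonDE_abundant_escaper"
    w[esc] <- truth$base_abundance[esc] * escaper_leak
  }
  if (sum(w) == 0) stop_config("degenerate truth table: all weights zero")
  w / sum(w)
}

.qual_string <- function(lens, model, q_high = 40L, q_low = 15L) {
  if (model == "constant") {
    return(strrep(rawToChar(as.raw(q_high + 33L)), lens))
  }
  # linear decay from q_high to q_low along the read, with unit jitter
  vapply(lens, function(L) {
    q <- round(seq(q_high, q_low, length.out = L)) +
      sample(-1:1, L, replace = TRUE)
    q <- pmax(2L, pmin(41L, q))
    rawToChar(as.raw(q + 33L))
  }, "")
}

#' Simulate the four SSH read libraries
#'
#' Draws single-end reads multinomially from the class- and effect-adjusted
#' transcript abundances of each library (see [library_weights()]), with
#' uniform start positions, random strand, uniform read lengths within
#' `read_length`, and per-base substitution errors at `error_rate`.  The
#' default library depths preserve the strong depth asymmetry of the two
#' sequencing runs the four libraries came from, scaled to desk size.
#'
#' @param transcripts DNAStringSet.
#' @param truth `ssh_truth` table for the same transcripts.
#' @param library_sizes named integer vector of reads per library.
#' @param escaper_leak fraction of an abundant escaper's cDNA escaping
#'   subtraction (applies to every library); see [library_weights()].
#' @param error_rate per-base substitution probability in `[0, 0.1]`.
#' @param read_length integer pair: read length range; the maximum must not
#'   exceed the shortest transcript.
#' @param quality `"constant"` (default, Q40) or `"decay"` for a 3'-decaying
#'   quality model that gives the trimmer something to trim.
#' @param seed integer seed or `NULL`.
#' @return list of class `ssh_libraries`: one data.frame per library with
#'   columns `read_id`, `sequence`, `quality`, `source_id` and attribute
#'   `library_id`.
#' @export
sim_read_libraries <- function(transcripts, truth,
                               library_sizes = c(DF = 50000L, DR = 175000L,
                                                 RF = 205000L, RR = 55000L),
                               escaper_leak = 0.05, error_rate = 0.005,
                               read_length = c(36L, 151L),
                               quality = c("constant", "decay"),
                               seed = NULL) {
  quality <- match.arg(quality)
  if (is.null(names(library_sizes)) ||
      !setequal(names(library_sizes), ssh_library_ids()))
    stop_config("library_sizes must be named DF, DR, RF, RR")
  if (any(library_sizes < 0)) stop_config("library sizes must be >= 0")
  if (error_rate < 0 || error_rate > 0.1)
    stop_config("error_rate must be in [0, 0.1]")
  if (length(read_length) == 1) read_length <- c(read_length, read_length)
  if (read_length[1] < 1 || read_length[1] > read_length[2])
    stop_config("read_length must be an increasing positive pair")
  if (read_length[2] > min(Biostrings::width(transcripts)))
    stop_config("maximum read length exceeds the shortest transcript")
  if (!identical(truth$transcript_id, names(transcripts)))
    stop_config("truth table does not match the transcript set")

  seqs <- as.character(transcripts)
  lens <- Biostrings::width(transcripts)
  with_seed(seed, {
    out <- lapply(ssh_library_ids(), function(lib) {
      size <- as.integer(library_sizes[[lib]])
      if (size == 0) {
        df <- data.frame(read_id = character(), sequence = character(),
                         quality = character(), source_id = character(),
                         stringsAsFactors = FALSE)
        attr(df, "library_id") <- lib
        class(df) <- c("ssh_reads", "data.frame")
        return(df)
      }
      w <- library_weights(truth, lib, escaper_leak)
      idx <- sample.int(length(seqs), size, replace = TRUE, prob = w)
      rl <- sample.int(read_length[2] - read_length[1] + 1L, size,
                       replace = TRUE) + read_length[1] - 1L
      start <- 1L + floor(runif(size) * (lens[idx] - rl + 1))
      reads <- substring(seqs[idx], start, start + rl - 1L)
      rev <- runif(size) < 0.5
      if (any(rev)) {
        reads[rev] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(reads[rev])))
      }
      reads <- as.character(.mutate_seqs_cpp(reads, error_rate))
      df <- data.frame(
        read_id = sprintf("%s_r%07d", lib, seq_len(size)),
        sequence = reads,
        quality = .qual_string(rl, quality),
        source_id = names(transcripts)[idx],
        stringsAsFactors = FALSE)
      attr(df, "library_id") <- lib
      class(df) <- c("ssh_reads", "data.frame")
      df
    })
    names(out) <- ssh_library_ids()
    class(out) <- c("ssh_libraries", "list")
    out
  })
}

#' Fragment transcripts into SSH-style contigs
#'
#' Cuts every transcript into one or more non-overlapping fragments whose
#' concatenation reconstructs the transcript, emulating the highly
#' fragmented contigs that de novo assembly of SSH cDNA produces (most
#' genes end up represented by several non-overlapping contigs).  The
#' number of fragments is `round(length / mean_fragment)` (at least one, and
#' never so many that a fragment would fall below `min_fragment`); cut
#' points are uniform among valid partitions.  The defaults are tuned so
#' that, under the default transcript length model, the realized mean
#' fragment length is close to 482 bases.
#'
#' @param transcripts DNAStringSet.
#' @param mean_fragment target mean fragment length in bases.
#' @param min_fragment minimum fragment length in bases.
#' @param seed integer seed or `NULL`.
#' @return list with `contigs` (DNAStringSet named `<transcript>_c<i>`) and
#'   `provenance` (data.frame `contig_id`, `transcript_id`, `start`, `end`,
#'   1-based inclusive).
#' @export
sim_fragment_contigs <- function(transcripts, mean_fragment = 500L,
                                 min_fragment = 200L, seed = NULL) {
  if (min_fragment < 1) stop_config("min_fragment must be >= 1")
  if (mean_fragment < min_fragment)
    stop_config("mean_fragment must be >= min_fragment")
  lens <- Biostrings::width(transcripts)
  ids <- names(transcripts)
  with_seed(seed, {
    res_id <- vector("list", length(lens))
    res_seq <- vector("list", length(lens))
    res_prov <- vector("list", length(lens))
    seqs <- as.character(transcripts)
    for (i in seq_along(lens)) {
      L <- lens[i]
      nf <- min(max(1L, as.integer(round(L / mean_fragment))),
                max(1L, L %/% min_fragment))
      if (nf == 1L) {
        fl <- L
      } else {
        extra <- L - nf * min_fragment
        cuts <- sort(sample.int(extra + 1L, nf - 1L, replace = TRUE) - 1L)
        fl <- min_fragment + diff(c(0L, cuts, extra))
      }
      ends <- cumsum(fl)
      starts <- ends - fl + 1L
      res_id[[i]] <- sprintf("%s_c%d", ids[i], seq_len(nf))
      res_seq[[i]] <- substring(seqs[i], starts, ends)
      res_prov[[i]] <- data.frame(
        contig_id = res_id[[i]], transcript_id = ids[i],
        start = starts, end = ends, stringsAsFactors = FALSE)
    }
    contigs <- Biostrings::DNAStringSet(unlist(res_seq))
    names(contigs) <- unlist(res_id)
    list(contigs = contigs,
         provenance = do.call(rbind, res_prov))
  })
}

#' Simulate a complete SSH experiment and optionally write it to disk
#'
#' Convenience wrapper running the whole generator: transcriptome, reference
#' panel, truth table, four read libraries, and fragmented contigs, all from
#' one seed.  When `outdir` is given, FASTA/FASTQ/TSV files are written
#' there.
#'
#' @param config an [ssh_config()] list.
#' @param seed integer seed.
#' @param outdir optional output directory.
#' @return list with `transcripts`, `panel`, `truth`, `libraries`,
#'   `contigs`, `fragments` (fragment provenance).
#' @export
simulate_ssh_experiment <- function(config = ssh_config(), seed = 1,
                                    outdir = NULL) {
  with_seed(seed, {
    tx <- sim_transcriptome(config$n_transcripts, config$length_range,
                            gc = config$gc)
    panel <- sim_reference_panel(tx,
                                 tier1_coverage = config$tier1_coverage,
                                 tier1_identity = config$tier1_identity,
                                 tier2_coverage = config$tier2_coverage,
                                 tier2_identity = config$tier2_identity)
    truth <- sim_truth(tx, class_mix = config$class_mix,
                       effect_log2 = config$effect_log2,
                       abundance_meanlog = config$abundance_meanlog,
                       abundance_sdlog = config$abundance_sdlog)
    libs <- sim_read_libraries(tx, truth,
                               library_sizes = config$library_sizes,
                               escaper_leak = config$escaper_leak,
                               error_rate = config$error_rate,
                               read_length = config$read_length,
                               quality = config$quality_model)
    frag <- sim_fragment_contigs(tx, mean_fragment = config$mean_fragment,
                                 min_fragment = config$min_fragment)
    sim <- list(transcripts = tx, panel = panel, truth = truth,
                libraries = libs, contigs = frag$contigs,
                fragments = frag$provenance)
    if (!is.null(outdir)) write_simulation(sim, outdir)
    sim
  })
}
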