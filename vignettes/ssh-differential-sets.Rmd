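---
title: "Differential transcript sets from deep-sequenced SSH libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential transcript sets from deep-sequenced SSH libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sshdiff)
```

## The problem

Suppression subtractive hybridisation (SSH) enriches cDNA fragments that
differ in abundance between a *tester* and a *driver* sample.  A forward
library captures transcripts up-regulated in the treatment, the reverse
library the down-regulated ones.  When SSH libraries are deep-sequenced
rather than cloned, two contamination classes dominate the false-positive
load: **rare transcripts that are not differentially expressed** (their
scarcity lets them survive the subtraction and their sampling noise makes
them look library-specific) and **abundant transcripts that escape both
subtraction and normalisation** (typically highly expressed housekeeping or
photosynthetic genes, which then appear in *every* library).

`sshdiff` implements the downstream analysis for a four-library design —
drought-forward (DF), drought-reverse (DR), recovery-forward (RF) and
recovery-reverse (RR) — and grades every contig into three nested sets per
library:

* **nS** (non-subtracted): every contig detected in the library;
* **SnE** (subtracted, non-enriched): contigs unique to one member of a
  forward/reverse pair;
* **SE** (subtracted and enriched): the unique contigs plus shared contigs
  rescued by a significant count difference with
  $|\log_2 \mathrm{FC}| \ge 2$ on RPKM.

## Models and procedures

### Tiered reference assembly

SSH cDNA is fragmented (RsaI digestion), so de novo assembly leaves most
genes represented by several non-overlapping contigs.  To collapse this
redundancy the contigs are cascaded over two reference tiers: a diverged
homolog coding-sequence set (tier M; cross-species, around 90% identity)
and a same-species transcriptome (tier W); what maps to neither is carried
through as an orphan (tier A).  Placement uses local alignment with match
$+1$, mismatch $-2$, a flat gap cost of $3$, and is accepted when at least
half of the contig aligns at identity $\ge 0.8$ (identity is
matches/columns, with gap columns counted as mismatches; this definition is
stated because "similarity" is tool-specific in assembly software).
Contigs placing on the same reference are merged into one consensus per
reference: a column covered by one distinct base takes that base,
conflicting columns take the IUPAC code of the observed base set, and
uncovered columns inside the placed span take `N`.  The rule is: `N` means
*no information*, an IUPAC code means *conflicting information*.

The production aligner seeds candidate references with exact k-mers
(k = 13) and runs banded dynamic programming (half-width 48) around the
best-voted diagonal; a contig with no seed hit anywhere in the panel falls
back to the exact full dynamic program, so seeded and exhaustive alignment
make identical accept/reject decisions (a property the test suite checks
against an independent `Biostrings::pairwiseAlignment` oracle and against
the package's own full DP on hundreds of simulated pairs).

### Quantification

Reads are quality-trimmed by the modified-Mott algorithm on the per-base
error probabilities (limit 0.01), 3' adapters are removed by seeded
suffix–prefix matching (ten or more matching bases, at most one mismatch),
and reads shorter than 36 bases are dropped.  Mapping to the combined
reference is best-hit and ungapped (SSH reads are short and the simulator
injects substitutions only): seeds vote for (reference, diagonal)
candidates, candidates are verified base-by-base, and a read is kept when
at least half of it aligns at identity $\ge 0.9$.  Reads whose best score
ties between two references are discarded and counted, which keeps counts
deterministic.  Expression is reported as
$\mathrm{RPKM} = 10^9 k / (L \cdot N)$ with $k$ the contig's mapped reads,
$L$ the *full* contig length and $N$ the library's mapped total.  The
length term deliberately uses the full reference length (the standard RPKM
definition); the per-library *covered* length is kept separately and drives
the presence filter: a contig is "present" in a library when it has at
least one mapped read and at least 50 covered bases.

### Library comparison

Counts, not RPKM, carry the statistics: for each contig the forward and
reverse counts are compared with the classical two-proportion Z test on
pooled variance (no continuity correction, so $z^2$ equals the 2×2
chi-square statistic — an identity the tests verify exhaustively for all
margins up to 50).  False discovery rates use Storey's q-values: $\pi_0$
is estimated on the grid $\lambda \in \{0.05, \dots, 0.95\}$, smoothed with
a cubic spline (3 df) and read off at the largest $\lambda$; q-values are
the step-up minimisation $q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)}/j$,
which reduces exactly to Benjamini–Hochberg at $\pi_0 = 1$.  Fold changes
are computed on RPKM, with $\pm\infty$ when only one side is expressed.
Significance is $q \le 0.05$ inclusive.

### Sequential subtraction

The drought pair is processed first.  Unique contigs enter SnE and SE with
reason `unique`; uniqueness is decided on presence and bypasses the
significance gate.  Shared contigs are excluded from SnE and rescued into
SE only when significant *and* past the fold-change cutoff, otherwise
discarded.  The recovery pair is then processed with the drought-forward
set subtracted in silico from the RF side, so transcripts already claimed
by the drought response cannot re-enter through early recovery; a contig
masked out of RF but still present in RR becomes RR-unique.

One design point here was genuinely open.  Masking strictly per tier
(SnE\_DF masks the SnE comparison, SE\_DF the SE one) reproduces the
package's worked example, but violates the tier nesting
$\mathrm{SnE} \subseteq \mathrm{SE}$ for RF: a contig *rescued* into SE\_DF
(so not in SnE\_DF) that is RF-present and RR-absent would enter SnE\_RF
while being masked out of SE\_RF.  The package therefore lets the full
subtracted drought-forward library (SE\_DF) block RF *candidacy* at both
tiers, while the conversion of a masked contig into an RR-unique call stays
per-tier.  Writing $P_L$ for presence, the recovery SnE sets are
$\mathrm{SnE}_{RF} = P_{RF} \wedge \neg P_{RR} \wedge \neg \mathrm{SE}_{DF}$
and $\mathrm{SnE}_{RR} = P_{RR} \wedge \neg(P_{RF} \wedge \neg
\mathrm{SnE}_{DF})$; since $\mathrm{SnE}_{DF} \subseteq \mathrm{SE}_{DF}$,
both recovery SnE sets are subsets of their SE counterparts on every input,
forward/reverse exclusivity is preserved, and the worked-example strings
are unchanged.

### What the simulator emulates

The generator produces the study conditions end to end: a transcriptome of
200–2000 base transcripts; a reference panel with 60% tier-1 coverage at
90% identity (substitutions only) and 85% tier-2 coverage at 98% identity,
drawn independently so some transcripts have neither; a truth table over
seven regulation classes (10% in each differential class, 15% rare
non-differential, 5% abundant escapers, 40% background) with lognormal
abundances (meanlog 0, sdlog 1.5) whose rare and escaper classes are drawn
from the lower and upper deciles; four single-end read libraries of
50k/175k/205k/55k reads — the real runs' depth asymmetry at roughly 1/100
scale, which is what makes RPKM normalisation matter — with uniform read
lengths 36–151, substitution errors at 0.5%, and constant Q40 qualities by
default (a decaying-quality model exists so the trimmer has something to
trim); and contigs cut from the transcripts so that the realized mean
fragment length is about 482 bases under the default length model.

A differential transcript with effect $e$ is $2^e$-fold enriched in the
library that captures it (default $e = 3$) and sits at its base abundance
elsewhere.  An abundant escaper contributes `escaper_leak` (default 5%, a
free choice exposed in the configuration — the escape literature is
qualitative) of its abundance to *every* library; with the leak at zero it
follows the plain abundance model.  Both regimes place escapers in all four
nS sets; the leak only attenuates them.

What the simulator does **not** model: hybridisation kinetics, adaptor
chemistry and RsaI digestion (enrichment acts at the abundance level
only), paired-end inserts, PCR duplicates, indel sequencing errors, and
cross-hybridisation between paralogs.  Passing tests therefore demonstrate
the pipeline's logic and statistics, not robustness to assembly artefacts
or paralog interference in real libraries.

## Numerical choices and degenerate inputs

* Empty count tables, empty libraries and empty contig sets yield zeroed
  reports, not errors; rejected placements are values (`NULL`), not
  conditions.
* A table with pooled proportion 0 or 1 gets $z = 0$, $p = 1$.
* $\pi_0$ is clamped to $(0, 1]$; a single-$\lambda$ grid skips the
  smoother.
* Contigs with reads in neither library of a pair get $q = 1$ and reason
  `absent`.
* Multi-mapping ties are discarded (never randomly assigned); ambiguous
  best-hit ties during contig placement keep the lowest reference index
  and are flagged in provenance.
* Coordinates are 0-based half-open internally and 1-based inclusive in
  human-readable tables.
* RPKM and coverage arithmetic is done in doubles; the products overflow
  32-bit integers at real depths.

## Problem sizes used by the test suite

The unit suites run on simulations of 30–300 transcripts.  The
parameter-recovery check runs the full default configuration — 1000
transcripts, 485,000 reads — once, and the determinism check runs a
150-transcript configuration twice.  The statistical suites use 10,000
replicates (type-I error), an exhaustive sweep of 2×2 tables with margins
up to 50, and 500 simulated alignment pairs up to 2 kb.

## A worked run

```{r, eval = FALSE}
library(sshdiff)
run <- run_ssh_pipeline(ssh_config(), seed = 1, outdir = "ssh_out")
print(run)
run$recovery$class_recovery
```

On seed 1 this reports 2,229 contigs collapsing to 1,081 reference
sequences, SE sensitivity 0.95 for drought-induced transcripts, all 50
abundant escapers in the nS sets but only 4% of them surviving into any SE
set — the quantitative version of the claim that the subtracted-and-
enriched pathway removes the contamination that deep sequencing makes
visible in raw SSH sets.

## Known limitations

* The two-proportion test is asymptotic; for contigs with a handful of
  reads its p-values are conservative rather than exact (no
  Audic–Claverie or exact binomial alternative in this version).
* Identity is computed over alignment columns with gaps as mismatches;
  tools that define similarity differently will draw the 0.8/0.9
  boundaries slightly differently.
* The escaper contamination rate of the SE sets is a small-sample binomial
  quantity (50 escapers by default); run-to-run variation of a few
  percentage points around its ~4–5% expectation is expected.
* The worked-example table contains two rows whose published SE strings
  cannot be produced from their printed RPKM values under the stated
  fold-change rule; they are documented as discrepancies and excluded from
  the concordance count rather than special-cased.
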