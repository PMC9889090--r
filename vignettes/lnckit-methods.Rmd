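---
title: "Methods and design of lnckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of lnckit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lnckit` collects the small, bespoke computations that accumulate around
the experimental characterization of a long non-coding RNA locus. This
vignette explains each procedure, its assumptions, the tunable parameters
and their defaults, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was genuinely
open.

## 1. Restriction fragment maps

4C-seq counts contacts per restriction fragment, so everything starts
from an in-silico digestion. `digest()` places a fragment boundary at the
start coordinate of every occurrence of the primary recognition motif
(NlaIII, `CATG`, by default), scanning left to right and allowing
overlapping occurrences; fragments tile `[0, L)` in 0-based half-open
coordinates. We deliberately put the boundary at the motif start rather
than at the biochemical cut offset: counts are aggregated per fragment,
so any fixed offset convention yields identical profiles, and
motif-start boundaries make every fragment (except possibly the first)
begin with the recognition sequence, which is easy to verify. Motifs
never match across `N`.

A fragment with no secondary-cutter site (DpnII, `GATC`) is *blind*: it
cannot be re-digested during library preparation, so reads in it are
unreliable. We call a fragment *valid* when it is non-blind **and** at
least `min_len` bp long (default 40 bp). The length floor is standard 4C
practice; both criteria are configurable (`min_len = 1` keeps every
non-blind fragment), and invalid fragments are retained in the map,
flagged, and merely excluded from counting.

## 2. The 4C viewpoint pipeline

The read-processing contract is: (i) the viewpoint primer must match the
5' end of a read within a mismatch budget of `floor(len * 0.05)`
(indel-free matching; full adapter semantics are out of scope), reads
without a match are discarded, and reads shorter than 25 nt after
trimming are dropped; (ii) mapping is iterative — a read that fails to
map loses exactly 5 nt from its 3' end and is retried, terminating at
success or below 25 bp. This trimming loop is the part worth testing
carefully: the invariants (mapped length ≥ 25, trims in exact 5-nt
steps) are asserted over simulated libraries.

The package ships an exact-match aligner (hashed fixed-width substring
tables per chromosome, both strands) rather than wrapping an external
short-read aligner: on synthetic genomes exact matching is the correct
oracle, it keeps the loop hermetic, and any function honouring the same
contract (sequence in, `mapped/chrom/pos/strand` out) can be substituted.
A sequence occurring more than once across both strands is reported
unmapped — the conservative choice for a contact assay.

Assignment uses the read's 5'-most genomic coordinate (leftmost for `+`,
rightmost for `-`), since 4C reads start at the restriction site.
Counts are normalized to reads per million; smoothing replaces each
fragment's value with the mean over the centered five-fragment index
window `i-2 … i+2`, truncated at chromosome ends, never crossing
chromosomes. We read "closest five fragments" as the index window; the
alternative reading (nearest five by genomic midpoint distance) is
available via `smooth_profile(method = "distance")` and coincides with
the index window on evenly tiled maps. Smoothing is applied to the RPM
track by default, matching the stated order of operations
(normalize, then smooth); `smooth_raw = TRUE` smooths raw counts.

## 3. Synthetic 4C data and what recovery tests show

`simulate_fourc_reads()` draws reads from valid-fragment 5' ends with
weight

w_i = (b + (1 + d_i)^-α) · f_i,

where `d_i` is fragment-index distance to the viewpoint, α = 1 the decay
exponent, `b = 0.05` an additive uniform-ligation floor, and `f_i = 1`
except at a planted interaction. The planted interaction has a small
footprint — full fold (default 10×) at its center fragment, decaying
0.5/0.25 into the two flanking fragments each side — because a looping
contact enriches a multi-kilobase region, not a geometric point; a
single-fragment spike would make the smoothed maximum a coin toss among
the five windows containing it. A configured fraction of reads (default
30%) carries 5/10/15 junk 3' nucleotides whose first base mismatches the
genome, forcing exactly 1–3 iterative trims.

Recovery is scored with `peak_fragment()`, the argmax of the smoothed
track with the viewpoint-proximal ±15 fragments masked, mirroring the
universal 4C practice of excluding the self-ligation zone; the planted
site is drawn ≥ 20 fragments from the viewpoint (scaled down on small
maps) and ≥ 4 fragments from chromosome ends so its smoothing window is
never truncated. Under the default conditions (50 kb genome, ~100
fragments, 10,000 reads) the planted fragment is recovered in ≈ 99 of
100 seeds. These simulations validate the pipeline's arithmetic and the
recovery logic; they do not emulate PCR duplicates, mappability
variation, trans contacts, or replicate variance, so they say nothing
about statistical interaction calling on real data — which is explicitly
out of scope.

## 4. Splice-junction isoform classification

Junctions are stored 1-based as (last aligned base, first aligned base)
flanking the gap and canonicalized so `left < right`; the conversion
from 0-based half-open blocks is unit-tested. Alignment gaps shorter
than `min_intron = 20` nt are treated as deletions and merged — nanopore
alignments are indel-rich, and without this floor every small deletion
would count as a junction. A read is assigned to the first definition
(list order = priority) whose junctions are all present within the
tolerance; the default tolerance is 0 (exact coordinates), with a ±5 nt
preset recommended for raw nanopore junction wobble. Classification is
strand-agnostic: junction coordinates identify the isoform on either
strand.

The packaged *T-REX17* definitions follow the published hg19
coordinates literally (Ex1+2: 55,125,601 ↔ 55,140,806; Ex1+3:
55,123,254 ↔ 55,140,806), including the oddity that the 55,125,601
coordinate is described as exon-3 sequence for an isoform named Ex1+2;
we did not reinterpret the naming. Percentages are rounded to one
decimal; the combined defined-isoform and sloppy percentages are exact
complements before rounding.

## 5. Local alignment and conserved stretches

`local_align()` is a Smith–Waterman implementation with affine gaps in
C++, using the Water DNA defaults (match +5, mismatch −4, gap open 10,
extend 0.5) and the Water convention that a gap of length L costs
`open + (L-1)·ext`. Scores are doubled to integers internally so the
half-unit extension penalty never meets floating-point comparison.
Matching is case-insensitive and `N` scores as a mismatch against
everything, including `N`. Ties are broken deterministically: traceback
prefers diagonal, then a gap in the second sequence, then a gap in the
first, starting from the highest-scoring cell with the smallest (i, j)
lexicographically. The single best alignment is reported, as Water does;
sub-region analyses (individual exons, an enhancer) are separate calls
on extracted subsequences.

Two independent oracles guard the DP: a brute-force enumerator (also
shipped, `enumerate_local_score()`) that walks every increasing chain of
matched column pairs with the same gap convention — exact and feasible
to ~12 nt — and, in the test suite only, the local alignment scorer from
Biostrings with the gap convention mapped accordingly.

`conserved_stretches()` splits the alignment into maximal gap-free runs
and keeps runs of ≥ 20 columns, reporting per-stretch identity but not
thresholding on it: the rule is length-and-gaplessness, substitutions
allowed. No headline "percent conservation" statistic is invented; the
summary exposes coverage fractions and the paired-coordinate stretch
table from which connecting-line plots are drawn.

## 6. ORF enumeration and score distributions

`enumerate_orfs()` reports every ATG-initiated ORF in the three forward
frames of the stranded transcript, including nested internal starts,
each extended to the first in-frame stop. Starts with no downstream stop
are flagged `open_ended` and excluded by default; `min_aa` defaults to 0
(no length filter). These defaults are stated rather than asserted
against any particular published ORF count, since minimum-length and
open-ended conventions vary.

The scorer is a contract: any deterministic function from an ORF
sequence to a real number. The packaged `codon_logodds_scorer()` is a
deliberately simple codon-frequency log-odds against a uniform
background — enough to exercise sampling, windowing and density
comparison end to end. It is not a phylogenetic codon-substitution
model, and scores are not comparable to one.

`percentile_window()` uses linear interpolation between order statistics
(`quantile` type 7) and keeps the closed interval [P2.5, P97.5]. The
definition matters at finite n: for 10,000 distinct scores exactly 9,500
survive; for the grid 1…100 the bounds are 3.475 and 97.525 so 4…97
survive. `compare_distributions()` evaluates both kernel densities on a
shared grid and rescales each so its trapezoid integral is exactly 1 —
the two curves enclose equal areas regardless of sample size imbalance.

## 7. Pulldown ranking and fractionation

`rank_pulldown()` scores each protein as
log₂(((Even + Odd)/2 + pc) / (LacZ + pc)). The pseudocount defaults to
0 and a zero LacZ intensity is then an error naming the offending
proteins: silently imputing a denominator would fabricate enrichment,
so the choice to add a pseudocount is always explicit. Ties are broken
by protein id to keep the ranking a deterministic permutation. The
Even/Odd split-probe design is metadata only.

`fractionation_percent()` divides each fraction's band intensity by the
cytoplasmic intensity (so Cyt's relative value is 1 by construction) and
scales each replicate's relative values to sum to 100%. Both operations
are invariant to rescaling all intensities of a replicate, which the
tests assert.

`simulate_lfq()` plants `n_enriched = 20` of 1,000 proteins at fold 8
over a log-normal abundance background with multiplicative noise of
CV 0.1 in each channel; under these conditions ≥ 18 planted proteins
occupy the top 20 ranks in ≈ 100% of seeds, and a fold-1 null recovers
planted proteins only at chance.

## 8. Reproducibility and problem sizes

Every generator is a pure function of its `sim_config()`: one master
seed, fixed offsets per generator, and byte-identical outputs per seed
(RNG state is saved and restored, so library calls never perturb a
caller's stream). The analysis drivers under `analysis/` write a JSON
manifest (inputs, parameters, package version, seed, stage tallies)
next to every output.

Problem sizes used throughout — 50 kb genomes, ~100 fragments, 10,000
reads, 100-seed recovery suites, 200 alignment oracle pairs, 500 ORF
oracle transcripts — were chosen so the full workflow and its test
suite run comfortably on a laptop while leaving the statistical
assertions (binomial bounds on recovery rates) well-powered. Scaling
the generators up is a matter of configuration, not code.

## Known limitations

* The built-in aligner is exact-match; real 4C data needs an external
  aligner behind the same mapping contract, and mappability artefacts
  are not modelled.
* Statistical interaction calling, replicate variance models, capture
  Hi-C, and de novo isoform discovery are out of scope.
* The coding-potential scorer is a toy; plug in a real scorer for
  biological conclusions.
* Simulated nanopore reads have exact block structures and constant
  quality; basecalling and alignment error models are not emulated.
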