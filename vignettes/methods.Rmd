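---
title: "Calling A-to-I editing hotspots in miRNA seed regions: models and methods"
author: "mirED authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling A-to-I editing hotspots in miRNA seed regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA. Because
the sequencing and translation machineries read inosine as guanosine, A-to-I
editing appears in small-RNA sequencing data as an A→G mismatch against the
genomic reference. When such an edit falls inside a mature miRNA's *seed*
(positions 2–8), the region whose perfect Watson–Crick pairing dominates
target recognition, a single edited base can simultaneously release the
canonical target set and create a new one. `mirED` implements the
computational chain needed to find such events in a multistage disease
cohort and to predict the resulting target switching: read preprocessing and
alignment, strand-aware pileup, statistical editing-site calling, annotation
and variant filtering, cohort-level hotspot selection, edited-miRNA seed
matching over 3'UTRs, and fuzzy c-means expression-pattern shortlisting. A
first-class synthetic-data module generates every input the pipeline
consumes, so the whole chain is testable offline.

## The editing-level model and the binomial test

At a reference-adenosine site with miRNA-strand base counts $(A, C, G, T)$,
the editing level is

$$\hat f = \frac{G}{A + G},$$

treating C and T reads as sequencing errors rather than editing evidence.
Under the null hypothesis of no editing, each of the $n = A + G$ informative
reads shows G only through miscalls. With a per-base error rate $e$ and a
uniform substitution spectrum, the per-base A→G error probability is $e/3$,
and the raw p-value is the exact binomial upper tail

$$p = \sum_{k \ge G} \binom{n}{k} (e/3)^k (1 - e/3)^{n-k}.$$

Sites are tested per sample; the Bonferroni family is the number of
A-reference sites reaching the coverage floor in that sample, and a site is
significant when $\min(1, p \cdot n_\text{tests}) \le 0.1$. The referenced
profiling scripts' exact null is not restated in their methods text, so two
choices here are package decisions: the $e/3$ uniform-spectrum null, and the
per-sample test family. Both are configurable (`call_config()`). The error
rate can be supplied or pooled from the data (`estimate_error_rate()`): all
mismatches at C/G/T reference sites plus A→C/T at A sites, over the
corresponding coverage, excluding the A→G signature from both sides and
floored at $10^{-6}$.

A site enters the cohort matrix if it is significant and unflagged in at
least one sample. Two cohort retention rules mirror the two study designs:
the multistage rule keeps sites with mean editing ≥ 5% across covered
samples *and* host-miRNA mean TPM ≥ 1; the tumor/normal rule keeps sites
with editing ≥ 5% in at least 10 samples. "Average editing rate" is averaged
over samples where the site is testable (coverage at the floor), never
imputed — the methods text does not say which convention the study used.

## Alignment contract

Reads are adapter-trimmed (exact leftmost-longest 3' match, minimum 3-nt
overlap), 3'-quality-trimmed at Q20 with the standard partial-sum algorithm,
and gated to 15–28 nt. The mapper is ungapped, ignores the final two bases
of each read (`trim3 = 2`), and reports a read only when its best mismatch
stratum (0, then 1) contains exactly one location across both strands of the
whole reference — the "no cross mapping" contract. Three deliberate
deviations from the emulated tools, recorded here because they matter to
reviewers:

* the emulated aligner's quality-sum ceiling (`-e 50`) is not reproduced;
  with Q30 data it never binds;
* adapter matching is exact, whereas the emulated trimmer tolerates ~10%
  errors; consequently a read whose *insert* happens to end with ≥ 3 nt of
  the adapter's prefix is shortened again on a second pass — exact 3'
  adapter trimming is idempotent only away from that ambiguity, and the test
  suite asserts exactly that;
* whether the study applied `trim3` before or after length gating is not
  stated; `mirED` gates on post-adapter length and clips only at alignment.

For minus-strand pre-miRNAs all evidence is complemented into miRNA-strand
space before pileup, so the editing signature is always A→G regardless of
genomic strand.

### A known limitation: reference bias of the 1-mismatch mapper

An edited read carries one mismatch by construction. If it also carries one
sequencing error it exceeds the mismatch budget and is dropped, while an
unedited read with one error is kept. At 1% error over a ~20-nt core this
depletes edited reads by ≈ 18% relative to unedited ones, biasing $\hat f$
downward by roughly $0.1 \hat f$ (e.g. ≈ 0.27 observed for a true fraction
of 0.30). Any pipeline built on a best-stratum 1-mismatch aligner — including
the emulated one — shares this bias. The editing-level recovery criterion
(± 0.05 in ≥ 95% of replicates at coverage 500) is therefore verified on the
estimator itself, with reads simulated at the site; the end-to-end tests run
the full chain, where the bias is visible but does not impede hotspot
detection or trend calling.

## Candidate selection

Hotspots are restricted to seed positions 2–8. The study describes its
multistage rule only as "editing frequency increased as liver cancer
progressed"; `mirED` operationalizes this as three auditable conditions:
nondecreasing per-stage mean editing along the user-declared stage order, a
total first-to-last rise of at least `delta` (default 0.01), and a Spearman
rank correlation (midranks) of editing against ordinal stage reported
alongside. The tumor/normal rule uses a two-sided Wilcoxon rank-sum test
(normal approximation with tie correction) and requires a higher tumor mean
at `alpha` (default 0.05). Candidates are intersected across cohorts keyed by
(miRNA, seed position). Stage order is always declared in the sample sheet,
never inferred from labels.

## Target switching

`apply_edit()` derives the edited miRNA (A→G at the called position) and
both seeds. `scan_utr()` re-implements the canonical TargetScan site
classes: anchored on a perfect match to the reverse complement of miRNA
positions 2–7, extended by pairing of position 8 (m8) and/or an adenosine
opposite position 1 (A1):

| type    | definition                       |
|---------|----------------------------------|
| 8mer    | m8 match + A1                    |
| 7mer-m8 | m8 match, no A1                  |
| 7mer-A1 | A1, no m8 match                  |
| 6mer    | core match only                  |

Each core occurrence (overlaps included) is reported once with its single
highest-priority type. Context++ scoring, conservation filtering and
3'-supplementary pairing are intentionally out of scope: the study used
TargetScan as a black box, and site typing is the reproducible core.
`target_delta()` partitions genes into *lost* (canonical-only), *gained*
(edited-only) and *shared*, ranked by best site type then site count.

Expression shortlisting follows the study's log2(FPKM + 1) convention,
collapses samples to per-stage means, standardizes each gene to mean 0,
sd 1, and clusters with fuzzy c-means (`fuzzy_cmeans()`): memberships
$u_{ij} = 1/\sum_k (d_{ij}/d_{ik})^{2/(m-1)}$, centers as $u^m$-weighted
means, objective $\sum u_{ij}^m d_{ij}^2$ nonincreasing by construction.
The fuzzifier defaults to $m = 2$ and the cluster count is user-chosen; the
study reports neither. A lost target is shortlisted when its dominant
cluster (membership ≥ 0.5) has a stage-monotone *increasing* center (the
gene is de-repressed as editing rises), a gained target when the center is
monotone *decreasing*; the minimum center change defaults to 0.25
standardized units.

## The synthetic world

`make_reference()` builds a genome with an autosomal and a mitochondrial
contig, 60–110-nt pre-miRNA hairpins each carrying one 20–24-nt mature arm
(at least one on the minus strand, the last on the mitochondrial contig), a
GFF3 annotation, and a known-variant VCF anchored at mature position 3 of a
declared subset of miRNAs. Every mature arm is forced to hold adenosines at
positions 3 and 12 so seed and non-seed edits can always be planted — the
study's central event is a position-3 edit, so the generator states that
world directly.

`simulate_reads()` draws Poisson read counts per miRNA (default 5000×),
edits each read at planted sites with the sample's stage fraction, appends
the 3' adapter, truncates to the 36-nt machine read length, and applies
uniform substitution errors (default 1%, the common Illumina magnitude; no
indels, matching the ungapped alignment contract). Base qualities are Q30
with an optional Q10 3' tail to exercise quality trimming. Because the
simulated reference covers only a tiny miRNome slice, TPM is computed
against a declared per-sample library size (default 5 × 10⁶ reads), giving
an ordinarily expressed miRNA ≈ 10³ TPM, a realistic scale.

Six decoys each violate exactly one documented filter, making every filter's
test attributable: a known-variant overlap, a mitochondrial site, an
intergenic mismatch site, an under-expressed host (burst expression in a few
samples so that mean TPM < 1 while per-sample coverage still supports a
call), a non-seed (position 12) edit, and a stage-flat editing fraction.
The default stage profile for trend plants rises 0.02 → 0.25, the fractions
the study's progression figures motivate.

The expression simulator uses three cluster shapes — monotone up, monotone
down, transient peak — on the log2 scale with log-normal noise (sd 0.5).
A *flat* third shape was considered and rejected: per-gene standardization
(which the clustering contract, like Mfuzz, requires) maps a flat profile to
pure noise, so its labels are unrecoverable in principle and a recovery test
against it would measure nothing. `simulate_utrs()` plants seed-match sites
of exact requested types with rejection-sampled backgrounds guaranteed free
of accidental sites for either seed.

What a green test does *not* establish: the simulator has no isomiR length
heterogeneity, PCR duplicates, adapter chimeras, position-dependent error
profiles, or expression-editing coupling; real cohorts add all of these.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based closed in
  GFF3/VCF/SAM, converted only at the I/O boundary.
* `pbinom(G − 1, A + G, e/3, lower.tail = FALSE)` supplies the exact tail;
  it matches an independent arbitrary-precision summation oracle to
  < 10⁻⁹ relative error for coverage ≤ 2000 (asserted in the tests).
* Sites with zero coverage or with $A + G = 0$ are excluded, never NaN.
* Constant vectors make Spearman's rho undefined: the functions warn and
  return NA rather than a number.
* In fuzzy c-means, a point coinciding with a center receives crisp
  membership there; centers are initialized from distinct data rows chosen
  by the seeded RNG, so runs are reproducible by construction.
* A 2×2 table with a zero cell gets the Haldane (+0.5) odds-ratio
  correction; a degenerate margin yields `p = NA` with a warning.
* The AUC uses midranks, so tied scores contribute half-concordance,
  matching the Mann–Whitney U identity exactly.

## Known limitations

* The mapper's reference bias against edited reads (above) shrinks editing
  levels by ≈ 10% relative at 1% error; trend and threshold rules operate on
  the biased scale, as they do in the emulated pipeline.
* Exact adapter matching slightly lowers yield relative to an
  error-tolerant trimmer (reads with an error in the adapter segment fail
  the length gate); at the default depths this costs ~13% of reads and no
  statistical power that matters to the tests.
* The Bonferroni family is per-sample; a cohort-wide family would be more
  conservative. Both interpretations are defensible; the choice is exposed
  through the per-sample call interface.
* Candidate selection statistics (trend delta, rank correlation, Wilcoxon
  alpha) are explicit stand-ins for a procedure the study does not specify;
  they are reported with each candidate so downstream users can re-filter.
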