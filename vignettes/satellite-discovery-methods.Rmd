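---
title: "Discovering candidate centromere tandem repeats from shotgun reads"
author: "satmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering candidate centromere tandem repeats from shotgun reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the premise

Centromeres of most animal and plant species are built on satellite DNA:
megabase-scale arrays of a tandemly repeated monomer (171 bp in human,
178 bp in *Arabidopsis*, 1,419 bp in cattle, 728 bp in monkeyflower).
Because the arrays are collapsed or absent in genome assemblies, the most
reliable evidence for them is in *unassembled* shotgun reads.  satmine
implements a discovery pipeline built on one premise: **the most abundant
tandem repeat in a random read sample is the prime candidate for the
centromere repeat**.  The pipeline has three read regimes:

* **Sanger / long reads** (hundreds of bp to tens of kb) are scanned
  directly — a read long enough to hold two or more copies of the monomer
  carries the repeat structure itself.
* **Short reads** (50–300 bp) cannot hold two copies of most monomers, so
  monomers are reconstructed first as high-coverage cycles in a k-mer
  (de Bruijn) graph, which plays the role of an iterative assembler: a
  tandem array, read at depth $d$ with copy number $c$, appears as a cycle
  of the monomer length whose node coverage is roughly $c \times d$ against
  a background at $d$.

Downstream, per-read hits are canonicalized (a monomer is only defined up
to rotation and strand), clustered into repeat families, ranked by the
fraction of reads supporting each family, and the rank-1 family is
nominated as the candidate.  Further analyses detect higher-order repeat
(HOR) structure, profile coexisting repeat variants, and compare monomers
across species on a timed phylogeny.

## The tandem detector

For each read the detector

1. collects candidate periods from the distance histogram of exact k-mer
   re-occurrences (k = 12 for reads ≥ 500 bp, 8 below; a candidate needs
   ≥ 3 supporting re-occurrences and must be a ±2 bp local maximum);
2. seeds a consensus with the single unit anchored at the start of the
   supporting region — a global window stack would desynchronize when the
   array carries indels or truncated units;
3. refines the consensus by wraparound dynamic programming of the read
   against the circular consensus (match +2, mismatch −7, indel −7, linear
   gaps, minimum reported score 50 — the classic parameterization of this
   detector family), re-deriving the consensus as the column majority of
   the alignment's base counts until it is stable (at most 4 rounds);
4. reports span, period, copy number (aligned span / period), percent
   identity of the array against its consensus, and the alignment score.
   Hits with fewer than two copies are suppressed; the period search is
   capped at min(2,000 bp, read length / 2).

Two artifact guards matter in practice.  Consensus ties are broken toward
the repeated consensus of a detected sub-period, so a multimer consensus
never drifts away from the monomer consensus without evidence.  And a hit
whose span is occupied by another hit with ≥ 5 points higher identity at a
period that is *not* a multiple or divisor is dropped: gapped wraparound
alignment can stretch an array onto a compressed, unrelated period seeded
by internal monomer structure, and such alignments always have materially
lower identity than the true period's.

Candidate filtering then applies the pipeline's rules: hits must span
≥ 80% of their read, periods < 50 bp are discarded, and among hits
occupying approximately the same span (reciprocal overlap ≥ 0.9, the
quantification we chose for "approximately") only the shortest period is
retained — a pure tandem array of period $p$ is equally well described by
$2p, 3p, \dots$.

DUST-style low-complexity masking precedes detection (window 64, step 32,
threshold 2.0 on the triplet score $S=\sum_t c_t(c_t-1)/2 / n_{\rm
triplets}$).  Masking is soft (lowercase) and a hit more than half
soft-masked is dropped; this preserves the ability to detect AT-rich
satellites that merely flirt with the threshold.

## Short-read reconstruction

Canonical k-mers (k = 31, counts pruned below 2 to drop sequencing-error
singletons) form an implicit graph whose edges are (k−1)-overlaps.  Cycle
search walks greedily from the highest-coverage node, always taking the
highest-coverage successor among nodes above `covFactor` (default 5) times
the graph's median coverage; a revisit closes a cycle.  The greedy rule is
also the bubble resolution: a SNP branch carries a fraction of the
consensus coverage and loses.  Every cycle in the length window is
re-verified by running the tandem detector on the doubled cycle, which
must recover a two-copy hit of the cycle length; cycles whose re-detection
reveals a shorter sub-period are flagged as HOR multimer cycles but not
suppressed — the shortest-period logic downstream decides.  Reconstructed
monomers are consensus sequences; within-family variant structure is not
preserved by this route.

The 2-bit k-mer packing caps k at 31, which is also the default; the
200,000-read sampling default for this stage follows the original
assembler protocol, and the 85% similarity figure of that protocol maps
onto the bubble-merge behaviour of majority-branch resolution.

## Abundance, profiles and the low-repeat call

A repeat family's abundance is the fraction of sampled reads matching its
consensus: a read counts when its best local alignment against the doubled
consensus (either strand) reaches 70% identity over at least half of
min(read, monomer).  Read-count abundance is what the pipeline defines —
it is subject to library and sampling biases, which we document rather
than correct.  With genome size $G$ and chromosome number $n$, the mean
array size per chromosome is $f \times G / n$.  A species whose candidate
fraction is strictly below a designated control (the holocentric nematode
*C. elegans* in the original analysis) is classified as lacking a
high-copy centromere tandem repeat.

Clustering operates on canonical monomers with the within-species aligner
settings (match +1, mismatch −1, gap open 3, gap extend 3, word 10).
Identity edges at ≥ 80% define "local" clusters (connected components);
inside them, requiring near-identical lengths (pairwise ratio ≥ 0.95)
defines "global" clusters.  The 0.80/0.95 values quantify the qualitative
"very similar" / "near-identical" wording of the method we re-implement;
both are exposed in the configuration.  Ranking is total and stable:
supporting-read fraction, then longer consensus, then lexicographic order.

## Higher-order repeats

HOR detection consumes the *unfiltered* hits: it needs exactly the
multimer hits the shortest-period rule discards.  A multimer hit over the
same span as a monomer hit (reciprocal overlap ≥ 0.9) is called an HOR
when its period is close to an integer multiple of the monomer's (±3%) —
or fits a truncated-unit model, $P = m p + \tau$ with
$\tau \in [0.2p, 0.8p]$ — *and* both its identity and score exceed the
monomer hit's.  Because the multimer consensus is fit on fewer units per
column it gains a fraction of a point on homogeneous arrays by pure
overfitting; the call therefore requires an identity gain ≥ 0.5 points,
well below the gain a genuine dimer produces (half its diagnostic columns
mismatch the monomer consensus, i.e. roughly `100 * d / 2` points at
inter-variant divergence `d`).  A pair whose two periods are both multiples of a shorter
spanning hit (e.g. 342 and 513 over a 171 array) is skipped as already
explained.  These two guards, not a statistical test, are what hold the
false-positive rate below 1% while keeping essentially full power at ≥ 3%
inter-variant divergence with ≥ 6 units in the read.

Monomer instances cut at consensus-aligned unit boundaries are clustered
by neighbor joining on 1 − identity; the two-class cut at the deepest
internal edge, with bootstrap over alignment columns (default 100
replicates), verifies the alternation of variant classes along the read.
The half-alignment test asks whether a long monomer is a doubled version
of a short one (length ratio restricted to [1.8, 2.2]): each half is
compared by the rotation-tolerant global identity, and half-specific
difference columns are reported when lengths permit a positional
comparison.

## Cross-species identity and its decay

Monomer boundaries are arbitrary, so identity must tolerate circular
permutation: the best local alignment of one monomer (either strand) is
computed against the *doubled* partner, making rotation transparent.  The
cross-species parameterization is match +1, mismatch −1, gap open 2, gap
extend 2, word size 8.  A global identity is then assembled by crediting
unaligned columns at the 25% background match rate of uniform DNA: with
$L = \max(|a|,|b|)$,

$$\mathrm{id} = 100\,\frac{\mathrm{matches} + 0.25\,(L - \mathrm{cols}_a)}{L}.$$

Using the longer monomer as denominator makes a monomer's identity against
its own multimer < 100, which is desirable — multimers are distinct units.
An alignment is only accepted if it scores ≥ 16 and contains an exact
match run of the word size; this mirrors the seeded, significance-gated
behaviour of the aligner whose role this function re-implements.  Without
the gate, an unconstrained Smith–Waterman optimum exists for *every*
random pair and systematically inflates background identity well above
25%; with it, unrelated monomers sit at the background almost surely, and
the mean over random pairs is 25% to within a fraction of a point.  Only
the single best local alignment contributes matches; the handling of
multiple high-scoring segments is deliberately left out.

Node-averaged contrasts control for shared history: every tip pair
contributes to exactly the node that is its most recent common ancestor,
giving one identity value $H$ per node at the node's age $t$ (in MY).
Polytomies are resolved randomly (ten resolutions by default) with
zero-length inserted branches, so path lengths are unchanged.  The decay
model is fit as printed, $H \sim \alpha t^{\lambda}$ — a power law, though
it is conventionally called an exponential decay — by nonlinear least
squares under Gaussian residuals started from the log–log linear fit,
with no additive background floor inside the fit; the background enters
only through $t_{\rm background}$, the earliest age at which the fitted
curve reaches 25%.  $\lambda$ is unconstrained: a flat or rising curve is
reported as such.

Phylogenetic signal uses Blomberg's $K$: the observed MSE$_0$/MSE ratio
(variance of tip values around the phylogenetically corrected mean over
the GLS mean squared error under the tree's Brownian covariance $C$),
scaled by its analytic Brownian expectation
$(\mathrm{tr}\,C - n/\mathbf{1}'C^{-1}\mathbf{1})/(n-1)$.  $K \approx 1$
under Brownian evolution — our calibration tests require the mean over
500 Brownian replicates on a 20-tip tree to land in [0.9, 1.1].
Significance comes from permuting trait values across tips (999 by
default, one-tailed greater).  Note the permutation test's null is random
assignment of values to tips: its p-values are uniform for i.i.d. traits,
and concentrate low for Brownian traits, which carry signal relative to
that null.

## The synthetic-data generator

The generator is first-class, tested code; everything the test-suite and
the acceptance analyses consume is produced by it.  It emulates:

* genomes as i.i.d. uniform ACGT background (hence the 25% identity
  convention) with planted arrays — mutated monomer copies, optional HOR
  patterns (an ordered cycle of variant labels with per-variant edit
  lists), per-copy substitution rates;
* reads of the three regimes as uniform substrings, reverse complemented
  with probability 0.5, with substitution errors applied globally at the
  specified rate and 1-bp indels split 60% insertions / 40% deletions (a
  crude emulation of long-read chemistry; the exact mix is not
  performance-critical);
* traits under Brownian motion and monomer families diverging by
  Jukes–Cantor substitutions along a timed tree (both delegated to the
  standard phylogenetics packages, wrapped for seed determinism).

What it does **not** emulate: transposon and rDNA repeat families,
chromatin context, quality-score structure beyond flat Phred, diploid
heterozygosity, GC bias and the many library biases of real archives.
Passing planted-truth tests therefore shows the machinery is correct and
calibrated, not that real archives are free of confounders — on real
data, ribosomal and knob repeats can outrank the centromere repeat and
must be recognized downstream.

All generators are pure functions of their inputs and a seed; the
conditions used by the validation analyses are: a 171-bp monomer at
~2.5% of a 20-Mb genome with 1% per-copy divergence read at 800 bp / 0.5%
error (the Sanger regime); a 1,419-bp monomer in 5–10-kb error-free reads
(the long regime); a 728-bp monomer at 2% divergence under 30× of 100-bp
reads (the short regime).  The test suite runs the same configurations
scaled to ~2-Mb genomes and a few thousand reads, sizes chosen so the
whole suite completes in minutes on one core.

## Technology routing

Reads tagged "short", or with mean length below `routeMinLength`
(default 300 bp ≈ twice the typical monomer scale), are routed through
reconstruction; longer reads are scanned directly.  We deliberately did
not tie the routing threshold to the 2,000-bp period cap: that would send
800-bp Sanger reads to the assembler, whereas the platform routing this
pipeline emulates scans them directly and simply cannot see monomers
longer than half a read — a documented blind spot, visible in our tests
only through the short-read route's ability to find them.

## Numerical choices and degenerate inputs

* Coordinates in hit tables and mask annotations are 0-based half-open;
  planted-truth intervals are also returned as `GRanges` (1-based, the
  container's convention) for interoperation and BED export.
* Consensus ties break toward a reference (sub-period consensus) when one
  exists, else alphabetically — deterministic everywhere.
* Reads shorter than twice the minimum period return an empty hit set,
  not an error; empty read sets are errors in the pipeline entry point.
* `fitDecay` falls back to the log–log estimates when the nonlinear
  optimizer cannot improve them (an exactly flat curve makes the gradient
  singular); degenerate inputs (constant age, < 3 usable contrasts) are
  errors.
* All randomness is funneled through explicit seeds; stage sub-seeds are
  derived from one master seed, and two runs with the same configuration
  produce byte-identical outputs.

## Known limitations

Interrupted and nested repeats are not decomposed; the detector reports
the dominant periodicity of a span.  Probabilistic (HMM) repeat models
are out of scope.  Chromosome assignment of repeat families needs
assemblies or cytology.  Read-count abundance underestimates families
with strong HOR structure, since multimer-spanning reads may be split
between the monomer and multimer families.  The exact parameter set of
the original external tools is not published; equivalence is therefore
defined — and tested — at the level of planted-truth recovery, not
byte-level concordance.
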