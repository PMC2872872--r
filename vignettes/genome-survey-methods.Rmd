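---
title: "Low-coverage genome surveys: repeat discovery, quantification and rDNA parentage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-coverage genome surveys: repeat discovery, quantification and rDNA parentage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatsurveyr)
```

# The problem

A shotgun survey covering ~1% of a large plant genome cannot be assembled,
but it is a statistically well-behaved sample of the genome's composition.
Three things can be read off such a sample. First, at sub-1x coverage the
only reads that overlap each other come from high-copy repeat families, so
assembling the overlapping reads ("non-cognate assembly") yields repeat
family consensus sequences de novo. Second, the number of reads matching
any given sequence estimates that sequence's genomic copy number. Third,
tandem gene families sampled deeply enough — ribosomal DNA above all —
expose allelic variation: in an interspecific hybrid the rDNA arrays still
carry both parents' ITS haplotypes, and individual survey reads can be
assigned to a parent.

`repeatsurveyr` implements this whole analysis chain over a synthetic-data
generator that emulates the study design: a multi-megabase genome with
planted repeat families spanning the detection limit, 454-style reads at
~1.2% coverage, small-RNA signatures produced per repeat copy, and
two-haplotype rDNA arrays. Because every planted feature is recorded in a
truth table, each analysis step is testable as a parameter-recovery
problem.

# The synthetic survey

`simulate_genome()` plants repeat families (a master sequence replicated
with independent per-copy substitutions), exon/intron gene mosaics, and
rDNA arrays into i.i.d. background sequence at 44% GC (the survey's
measured base composition). Key generator choices:

* **Copy divergence is substitution-only** (rate `intra_family_divergence`,
  0-10%), so planted feature lengths are exact and the per-copy Hamming
  distance to the master is binomial — the oracle used in tests.
* **Tandem classes** (centromeric, telomeric) are planted as one contiguous
  array; all other classes are dispersed uniformly.
* **rDNA units carry one of two ITS haplotypes verbatim**; family
  divergence applies to the flanking unit sequence only. This keeps the
  diagnostic region haplotype-faithful, mirroring concerted evolution
  within arrays, while the rest of the unit accumulates noise. Both
  haplotypes are guaranteed to appear.
* **Reads** (`simulate_survey_reads()`): lengths normal around 229 bp,
  uniform starts on both strands, per-base substitutions, and
  homopolymer-scaled indels (indel probability = rate x run length,
  capped at 0.5) emulating pyrosequencing flow miscalls. Read names encode
  the true origin (`family|copy|start|strand`), so recovery tests are
  label-based rather than alignment-based.
* **Small RNA** (`simulate_srna()`): each planted copy produces a Poisson
  number of signatures with expectation `class rate x copy kilobases`;
  signatures are genomic substrings (either strand), 24 nt with
  probability `fraction_24nt` (default 0.65, inside the observed 59-70%
  range) and otherwise uniform over 18-32 nt. The per-class rates order
  rDNA > MITE > DNA transposon > retrotransposon per kb; they are free
  parameters of the simulator, not estimates from any dataset.

What the generator does *not* emulate: nested insertions and LTR
structure, isochore-scale composition, quality-score realism, paired ends.
Tests passing on this generator therefore demonstrate the statistical
machinery — estimator calibration, clustering sensitivity, classification
logic — not robustness to every artefact of real 454 data.

# The aligner

All similarity searches go through one internal seed-and-extend local
aligner: exact 11-mer words locate candidate regions, each resolved by an
affine-gap Smith-Waterman (match +1, mismatch -1, on an internal x100
integer scale where gap open costs 400 and extension 30). `N` never seeds
and never matches. E-values use the ungapped nucleotide Karlin-Altschul
constants (K = 0.711, lambda = 1.37); the e-value gates in the pipeline
(1e-6 for contamination and classification calls) follow the survey's
conventions. Tests hold the top local score equal to an independent
full Smith-Waterman oracle on planted-core pairs.

The minimum reported score (default 30, in match units) is the one free
calibration: the original two-stage search it replaces reports scores on a
different internal scale, so no direct translation exists.

# Repeat discovery

`overlap_graph()` joins two reads when some dovetail or containment layout
gives an overlap that (a) contains an exact shared 14-mer — the classic
assembler minimum-match rule, a 14-base anchor at 100% identity — and
(b) reaches 90% identity over the full overlap region. The region
filter matters: without it, a repeated word inside a family can propose a
wrong offset whose long, low-identity "overlap" out-competes the true one;
90% is the same similarity threshold used throughout the pipeline. A
strictly literal rule requiring the *entire* overlap at 100% identity
would disconnect reads from family copies diverged by 1-2% (a clean 100-bp
overlap then has probability ~e^-3) and could not reproduce the
sensitivity this method demonstrably has; the word-anchor reading is the
one consistent with both the assembler actually used and the detection
claims.

Clusters are connected components with at least 3 reads. The 3-read
threshold is justified by Lander-Waterman island statistics
(`cluster_significance()`): dropping the survey's reads on a single-copy
locus, the probability that any three chain by 14-bp overlaps is small, so
3-read clusters reject the single-copy null. The closed form treats
islands' read counts as geometric with Poisson-distributed island starts;
it is validated against Monte-Carlo simulation (agreement within two
Monte-Carlo standard errors at the tested parameters), not asserted
against any published constant, because the published derivation is not
reproducible from the text.

Consensus calling is deliberately two-phase. Fixed layout offsets drift by
single bases across indel-bearing reads, and a majority vote over drifted
placements degrades sharply (two mutually frameshifted reads vote noise).
So a draft template is first tiled from oriented reads in layout order with
every junction re-anchored by local alignment, and all member reads are
then realigned to the draft and vote a per-column majority; columns
supported by fewer than two reads are trimmed from the ends. One family
may legitimately yield several clusters (different regions of one
element); no merging is attempted, matching the original analysis.
Inconsistent layouts are handled by using the strongest overlaps first and
ignoring edges that contradict an existing placement.

# Copy number and genome fraction

With uniform sampling at coverage `c`, a single-copy window of `w` bp
collects on average `c (w + L) / L` reads of mean length `L` (any read
whose span touches the window). The copy number of a target is therefore

```
CN = N L / (c (w + L))
```

for `N` observed matching reads. The formula is pinned by two anchors: it
is exactly 1 at the single-copy expectation, and it reproduces the printed
genome fractions of the most abundant repeat (0.45% of a 7.5-Gbp genome;
1.02% of the 818-Mbp relative) from its printed copy numbers and length.
Reads are counted per 1,000-bp sliding window at >= 90% identity, a read
counting once per window it overlaps by at least one base (the containment
alternative is not stated in the source and partial-overlap counting is
what the calibration above assumes). Genome fraction is
`CN x length / G`, with `G` the total (3C) genome size — copy numbers are
per total nuclear genome throughout.

The repeat-read fraction (the "68%" style statistic) counts each read once
if it matches any cluster at >= 90% identity over >= 90% of its own
length; the 90% length tolerance absorbs simulated read-end errors where
the source demands full-length matches.

# Small-RNA quantification

Signatures (18-32 nt) map ungapped, full-length, with at most one
substitution — for this length range the one-mismatch rule subsumes a 94%
identity threshold, and an indel breaks full coverage and is a non-hit.
Mapping is exhaustive (every position, both strands) and is tested for
exact set equality against an independent scan. Abundances normalise to
TPQ (transcripts per quarter-million sequenced signatures) and to per-kb
rates, `count / (CN x length / 1000)`.

For the copy-number relationship, clusters are binned by copy number
(width 25-200); per bin the summed matched count is regressed on the bin's
*minimum* copy number (the source's stated regressor, not the midpoint)
for R^2, and the per-bin totals are tested against a uniform expectation
by chi-square. A signature's abundance is credited to every cluster it
hits for cluster-level counts, but apportioned equally among classes for
class shares so that shares sum to 100% — the source does not state its
apportioning rule, and this is the only choice that keeps both "report all
hits" and a closed composition.

In the recovery test the copy-number grid is chosen to tile every tested
bin width evenly (copies on an even grid over [11, 799]); a partial final
bin would break linearity for reasons of binning arithmetic, not biology.

# Gene space and survey arithmetic

Reads matching a related species' coding sequences at 94-99% identity
(inclusive; 100% is outside the window) are "gene-space" reads, after
first removing coding entries that match a repeat library at e <= 1e-6.
The exon-space fraction `E / (E + L - 2m)` (= 66% at E = 250, L = 229,
m = 50) converts the gene-space read fraction into a genomic coding
fraction; the chain `coding % -> coding bp -> loci -> loci per subgenome`
uses the *rounded* coding percentage downstream, which is what makes the
printed figures (2.2%, 165 Mbp, 110,000, 37,000) internally consistent.
A placement simulation over an exon/intron mosaic reproduces the formula
within two percentage points for short-intron (~150 bp, grass-like)
geometries; for long introns the closed form overstates the exonic
fraction by ~3 points — a known limitation of the formula, not of the
implementation.

Rounding conventions are pinned per quantity because the printed values
are only reproducible under one rule each: contamination percentages
truncate at two decimals (901/366,448 -> 0.24%), the flow-cytometry total
rounds to the nearest 0.5 Gbp (7.62 -> 7.5), the per-haploid size to two
significant figures (2.54 -> 2.5), the coding percentage to one decimal,
and loci per subgenome to the nearest thousand.

# rDNA parentage

Reads matching the rDNA unit at >= 90% identity are mined, anchored on the
unit by local alignment (>= 50 bp overlap at >= 80% identity to stay),
and trimmed to the diagnostic 150-bp ITS2 block: columns gapped in
strictly more than 95% of rows are removed (a column at exactly 95% is
kept), rows not fully spanning the region are dropped, and rows with `N`
in the block are dropped as the quality filter (the source's filter has no
stated threshold; an ambiguous base inside the diagnostic block is the
unambiguous analogue). Each read is then assigned to the parental
haplotype at the strictly smaller substitution distance over shared
ungapped columns; ties are `ambiguous`. Bayesian tree inference is
deliberately exported (NEXUS) rather than re-implemented: the biological
conclusion — a bipartition of reads between two parents — is exactly what
the distance classification tests, and an MCMC engine would add no
testable surface here.

# Problem sizes and numerical choices

The test and analysis runs use 10-24 Mbp genomes, ~500-1,300 reads at
1.2% coverage, a few hundred repeat families, and ~8,000 small-RNA
signatures: the sizes at which every recovery statistic already has
adequate power (>= 3 expected reads per family at the detection limit,
Poisson noise a few percent of bin totals) while each analysis completes
in seconds to a few minutes. Family units of 3.5-4 kb match the observed
lengths of the most abundant repeat clusters (1.4-3.9 kb). Degenerate
inputs fail loudly: infeasible packing names the overflowing family, an
empty read set or zero-coverage request is an error, all-zero small-RNA
rates warn and return an empty set, identical haplotypes in a block are an
error rather than an all-ambiguous call. Ties in best-hit selection break
by bit score, then identity, then subject id, so results are independent
of input order.

# Known limitations

* The generator's uniform-start model has no sampling bias; real 454 runs
  under-sample extreme GC.
* Consensus accuracy is bounded by coverage: 3-4-read clusters carry a
  ~1-2% noise floor from copy divergence at two-fold column depth.
* The overlap graph seeds only exact 14-mers; overlaps in which every
  14-mer window is interrupted (by error or divergence) are invisible, a
  sensitivity loss shared with the word-anchored assembler it models.
* Copy-number estimates assume the consensus represents all copies at
  >= 90% identity; families more internally diverged than that fragment
  into clusters and are under-counted individually (their union is not).
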