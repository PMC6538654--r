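---
title: "Methods: centromere sequence landscapes with censcape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centromere sequence landscapes with censcape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

censcape re-implements, as a tested and reusable pipeline, the
sequence-feature computations used to compare fission-yeast
centromeres: GC-normalized 5-mer enrichment z-scores of sliding genome
windows with PCA-based chromatin-group separation, greedy tRNA-gene
cluster detection with a genome-shuffle permutation test, and
minichromosome establishment/loss statistics. This vignette is the
package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## The enrichment model

Fission-yeast centromeric DNA is AT-rich relative to the genome, so
raw k-mer frequencies of centromeric windows mostly reflect base
composition. The pipeline therefore scores each window against a
composition-preserving null: all base pairs of the window are
randomized — each artificial sequence is a uniformly random
*permutation* of the window's letters — 1000 times, k-mer counts are
recomputed on every artificial sequence, and the observed count of
each k-mer *m* is expressed as

z(m) = (observed(m) − null mean(m)) / null sd(m),

with the sample standard deviation (denominator n − 1) across
shuffles. Because a permutation preserves the mononucleotide multiset
exactly, GC content is matched by construction and z captures
higher-order (dinucleotide and above) sequence structure. Permutation
is the only reading of "randomized with the same GC content" that
preserves GC *exactly*; sampling with replacement would only preserve
it in expectation.

Numerical conventions:

* when the null sd is 0 the composition pins the count (for example a
  homopolymer window), the observed count necessarily equals the null
  mean, and z is defined as 0;
* k-mers are counted strand-specifically, as written, with no
  canonical collapsing — the null shuffles the same strand, so the
  statistic is self-consistent; whether the original analysis
  collapsed strands is not documented, and a strand-collapsing mode
  was deliberately not added;
* k-mers containing a non-ACGT letter are skipped in both observed
  and shuffled counting; ambiguity codes are permuted with the rest
  of the letters;
* every window draws its shuffles from an RNG stream derived from the
  master seed and the window's chromosome and index, so the profile
  matrix does not depend on evaluation order.

Windows are 12 kb with a 4.5 kb overlap (step 7.5 kb), anchored at
position 0 of each chromosome; partial terminal windows are dropped so
every profile shares the 12 kb denominator that the group definitions
assume. The anchor is a declared convention: nothing in the method
fixes the phase of the tiling. Coordinates are 0-based half-open
throughout; GFF3 input is converted on read.

The closed-form expectation used as the test oracle follows from
exchangeability: any k consecutive positions of a uniformly random
permutation are an ordered sample without replacement from the letter
multiset, so the expected count of a k-mer is (L − k + 1) times a
product of sequential draw probabilities. The Monte-Carlo null is
checked against this expectation over every letter composition of
lengths 2–8 (the null law depends only on the composition, so this
covers all short strings); with thousands of simultaneous
standardized comparisons a few 3-SE excursions are expected by
chance, and the suite bounds their frequency (≤ 1%) and magnitude
(< 5 SE) rather than asserting each one individually.

## Chromatin groups

Windows are assigned to exactly one of six groups, by the first
matching rule in priority order:

1. **CENPA** — CENP-A peak coverage > 6 kb (strict);
2. **NEOCEN** — overlaps a neocentromere region (regions are supplied
   as intervals, not derived from reads);
3. **MAT** — more than half the window in the mating-type region;
4. **CEN_HET** — more than half covered by H3K9me2 peaks and within
   1 bp (abutting or overlapping) of a CENP-A peak or CENPA window;
5. **SUBTEL** — more than half covered by H3K9me2 peaks and within
   100 kb of a chromosome end;
6. **OTHER** — everything else.

The priority order, the 100 kb telomere-proximity distance and the
1 bp adjacency gap are declared package conventions (all three are
configurable): the group definitions say "adjacent to CENP-A domains"
and "close to the end of a chromosome" without quantifying either,
and do not say how overlapping evidence is resolved. CENP-A is given
priority because its rule is the most specific.

For genomes whose centromeres are not fully assembled, the limited-PCA
mode substitutes the top 11 most enriched windows of a score track
(`top_enriched_windows()`, ties broken by genomic order) and ten
randomly selected control windows (`random_control_windows()`,
uniform without replacement, seed-reproducible).

## PCA and group statistics

The windows × 1024 z-score matrix is centred by column but not
rescaled — the entries are already z-scores on a common scale, and
per-k-mer re-standardization would up-weight k-mers whose null sd is
poorly estimated. Components come from the SVD; each component's sign
is fixed so its largest-magnitude loading is positive, making scores
reproducible across platforms.

Group ellipses are normal-theory data ellipses: centre at the group
mean, axes from the eigendecomposition of the sample covariance
scaled by sqrt(χ²₂(0.95)) ≈ 2.448, so the ellipse encloses 95% of the
data under a bivariate normal model. A convex-hull-peeling ellipse
was considered and rejected: the normal-theory ellipse is the
standard reading of "encloses 95% of the data points" in the plotting
conventions this field uses, and is stable for small groups.

"Mean comparison" between groups is the two-sided Wilcoxon rank-sum
test on PC1 scores — exact when both groups have ≤ 25 observations
and no ties, otherwise the normal approximation with continuity
correction. The plotting convention the figures follow defaults to
Wilcoxon for two-group comparisons, and a rank test is robust to the
heavy-tailed score distributions that arise here; the exact identity
of the original test is not documented. Stars map as: p > 0.05 ns;
(0.01, 0.05] `*`; (0.001, 0.01] `**`; (0.0001, 0.001] `***`;
≤ 0.0001 `****`.

Group membership is also modelled by logistic regression of the
indicator on the PC scores, with a likelihood-ratio test against the
intercept-only model. When groups separate perfectly — common here,
since the planted signal is strong — the ML coefficients diverge; the
fit flags separation instead of reporting the coefficients as
meaningful, while the LRT statistic (a difference of deviances)
remains well defined.

## tRNA gene clusters

Genes < 1000 bp apart (end-to-start gap in half-open coordinates,
strict) are chained greedily into clusters; singletons are kept as
1-gene clusters but only clusters of ≥ 2 genes enter the permutation
test. A cluster's signature is its sequence of (amino acid, strand)
pairs in genomic order, canonicalized as the lexicographic minimum of
the string and its orientation flip (order reversed, strands
inverted), so a cluster and its reverse-orientation mirror match.
Matching is at amino-acid level, not anticodon level — the original
matching rule is not documented, and amino-acid level is what the
published cluster diagrams display.

Significance: gene locations are shuffled across the genome 1000
times — each gene is re-placed uniformly (chromosome chosen
proportional to length, placement non-overlapping by rejection
sampling, lengths/strands/identities preserved) — and for each tested
signature the p-value is the raw proportion of permutations in which
the signature occurred at least as many times as observed. A p of 0
is flagged `below_resolution`: the observed count exceeded every
permutation, and the raw proportion cannot resolve below 1/n_perm.
(This is why a published "p < 0.00001" cannot be reproduced with 1000
shuffles; `n_perm` is exposed for users who need finer resolution.)
Benjamini–Hochberg q-values account for testing many signatures.

One statistical point deserves emphasis. If only the signatures that
happen to occur in the observed genome are tested, the procedure
re-tests rare events by construction: a chance cluster in a sparse
gene set is precisely an event that few permutations reproduce, so
nearly every post-hoc signature looks significant regardless of any
real centromere association. The test therefore accepts a
predeclared signature panel (`signatures =`); a predeclared signature
absent from the real genome simply gets observed count 0 and p = 1.
The package's calibration study uses a fixed panel of all canonical
2-gene signatures over the decoy amino alphabet, for which the
permutation p-value is superuniform in the usual way; the power study
uses the planted cluster signature, which is known a priori. Users
analysing real genomes should treat p-values of post-hoc signatures
observed exactly once with caution and rely on recurrent (observed
count ≥ 2) clusters, as the original analysis did.

## Minichromosome statistics

Establishment frequency is 100 × (adjusted white colonies) /
transformants, where white/pale-pink replica-plated colonies indicate
minichromosome retention. When a sample of whites was re-streaked to
detect integration events (false positives), the white count is
scaled by (1 − integrants/checked). Loss rate per division is 100 ×
half-sectored colonies / all non-pure-red colonies: a colony ≥ 50%
red lost the minichromosome at the first division after plating, and
pure reds are excluded because they lost it before plating. The
printed denominator is taken to be the count *after* pure-red
exclusion. Both statistics are reported half-up to one decimal,
matching the published table formatting, and the mean loss rate
across transformants of one construct is the count-weighted pooled
rate (the pooling rule used originally is not stated).

One published row (establishment 28.1% of 208) cannot be reproduced
by any integer white count (58/208 = 27.9, 59/208 = 28.4); it is
presumably the result of a fractional integrant adjustment whose
inputs are not printed. The reconstruction tests pin this row at 27.9
and round-trip the other seventeen printed values exactly.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be
exercised, end to end, without downloading the deposited assemblies.
Its default configuration is fixed and is what the acceptance studies
run:

| parameter | default | why |
|---|---|---|
| chromosomes | 3 × 4 Mb | fission-yeast genome scale (~12 Mb) |
| base composition | A/T 0.32, C/G 0.18 | ~36% GC |
| bias epsilon | 0.15 | planted compositional effect size |
| CENP-A core | 30 kb mid-chromosome | several windows clear the >6 kb rule |
| H3K9 flanks | 40 kb each side | centromeric heterochromatin domain |
| subtelomeric blocks | 50 kb per end | exercises the SUBTEL rule |
| mat-like region | 20 kb on chr2 | exercises the MAT rule |
| neocentromere-like | 2 × 15 kb, biased | regions that share centromere composition |
| planted cluster | D+V+A+, one per centromere | centromere-exclusive recurrent cluster |
| decoys | 100 singleton genes, ≥ 1 kb apart | scattered background genes |
| colony model | Binomial, p = 0.94 / 0.058 | a high-establishment construct |

The planted compositional signal is deliberately the *minimal* effect
the method can detect: centromere-like intervals are drawn from a
first-order Markov chain P[i, j] = π[j] + ε·a[i]·b[j], where a is the
π-centred AT/GC contrast and b[j] = π[j]·(s[j] − Σπs). Rows sum to 1,
π is exactly stationary (so GC matches the background by
construction, verified to 1e-9), and the entries stay non-negative
for every ε < 1 because P[i, j] = π[j](1 + ε·a[i]·(s[j] − Σπs)) with
|a[i]·(s[j] − Σπs)| < 1. ε = 0 gives the i.i.d. background kernel
exactly. Because the shuffle null preserves mononucleotide
composition and nothing else, a dinucleotide-level bias is exactly
what the z-scores are designed to see — at ε = 0.15 the AT→AT
transition probability rises by ~8% relative, which compounds across
a 5-mer and separates centromeric windows decisively on PC1.

What the generator does **not** emulate: repeat families and their
homogenization, retrotransposon remnants and LTRs, real tRNA gene
density and amino-acid usage, ChIP-seq read-level noise (peaks are
emitted as clean intervals consistent with the truth labels), and
centromere-size variation. Passing the recovery tests therefore shows
the pipeline's logic and statistics are correct under the stated
model, not that real centromeres would be detected with these exact
thresholds.

## Problem sizes and runtime choices

The acceptance studies use problem sizes chosen to exercise each
statistic at meaningful power on a single CPU: 200 i.i.d. 2-kb
windows × 1000 shuffles for null calibration; every letter
composition of lengths 2–8 at 50,000 shuffles for the oracle check;
the full default genome (~1600 windows × 1000 shuffles each) for the
pipeline-recovery study; 200 null genomes × 200 permutations for
cluster-test calibration and 1000 permutations for power. The
windowed shuffle-null inner loop is implemented in C++ (driven by R's
RNG, so results are reproducible from `set.seed`) with a pure-R
replay of the identical RNG stream serving as the oracle in the unit
tests.

## Known limitations

* The anchor phase of the window tiling and the exact
  telomere/adjacency distances of the original analysis are unknown;
  all are configurable and the defaults are documented conventions.
* Raw-proportion permutation p-values saturate at 1/n_perm; q-values
  below that resolution reflect the `below_resolution` flag, not a
  measured tail.
* Post-hoc signature p-values are anti-conservative (see above);
  predeclare signatures, or interpret only recurrent clusters.
* Strand-collapsed k-mer counting is not offered.
* The generator's peak tracks are noiseless by design; classification
  robustness to peak-calling noise is untested.
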