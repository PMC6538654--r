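# censcape

Comparative analysis of centromere sequence landscapes in fission
yeast genomes.

Centromere identity is specified epigenetically by the histone-H3
variant CENP-A, yet in *Schizosaccharomyces* species CENP-A chromatin
assembles on particular sequences — central cores flanked by
H3K9me2-heterochromatic outer repeats — whose DNA shows no detectable
homology between species. censcape implements the computations used
to ask what those nonhomologous centromeric sequences nonetheless
have in common: compositional sequence features detectable after
controlling for GC content, centromere-exclusive clusters of tRNA
genes, and the ability of centromeric DNA to establish and maintain
minichromosome segregation function. It is written for genome
researchers who want to run these analyses on their own assemblies
and peak calls, or to validate them end to end on synthetic data.

## The statistics at the core

**GC-normalized k-mer enrichment.** Each genome is tiled into 12 kb
windows with a 4.5 kb overlap. For a window with observed 5-mer count
obs(m), 1000 artificial sequences are generated by randomly permuting
the window's base pairs — preserving mononucleotide composition, and
hence GC, exactly — and

&nbsp;&nbsp;&nbsp;&nbsp;z(m) = (obs(m) − μ̂₀(m)) / σ̂₀(m),

where μ̂₀ and σ̂₀ are the mean and sample standard deviation of the
count across shuffles (z ≡ 0 where σ̂₀ = 0). The windows × 1024
z-score matrix is analysed by PCA (column-centred, SVD); windows are
classified into six chromatin groups (CENP-A core, centromeric
heterochromatin, mating type, subtelomere, neocentromere, other) from
peak intervals, groups are drawn with 95% normal-theory data
ellipses, and group differences on PC1 are tested by two-sided
Wilcoxon rank-sum with the star convention (ns, \*, \*\*, \*\*\*,
\*\*\*\*) plus logistic regression of membership on the PC scores.

**tRNA cluster permutation test.** tRNA genes < 1000 bp apart are
chained into clusters; a cluster's canonical signature is its
(amino acid, strand) sequence, orientation-normalized. Gene locations
are shuffled across the genome 1000 times and each signature's
p-value is the proportion of permutations containing it at least as
often as observed (flagged `below_resolution` when no permutation
does), with Benjamini–Hochberg q-values across signatures.

**Minichromosome statistics.** Establishment frequency =
100 × white transformant colonies (adjusted for detected integrants)
/ transformants; loss rate per division = 100 × half-sectored
colonies / all non-pure-red colonies.

A synthetic-data module generates multi-chromosome genomes whose
centromere-like domains are drawn from a Markov kernel with the
background composition as exact stationary distribution — GC-matched
but dinucleotide-biased, the minimal signal the shuffle null is built
to detect — together with consistent peak tracks, planted tRNA
clusters with scattered decoys, and binomial colony counts.

## Worked example

```r
library(censcape)

# a 3 x 1 Mb synthetic genome with planted centromeres
cfg <- synth_config(chromosome_length = 1e6)
d   <- synth_dataset(cfg, seed = 42)

w  <- make_windows(d$genome)            # 12 kb / 4.5 kb overlap
cl <- classify_windows(w, d$genome,
                       cenpa_peaks    = d$annotations$cenpa_peaks,
                       h3k9_peaks     = d$annotations$h3k9_peaks,
                       mat_regions    = d$annotations$mat,
                       neocen_regions = d$annotations$neocen)
dplyr::count(cl, group)
#> # A tibble: 6 × 2
#>   group       n
#>   <fct>   <int>
#> 1 CENPA      12
#> 2 NEOCEN      7
#> 3 MAT         3
#> 4 CEN_HET     6
#> 5 SUBTEL     36
#> 6 OTHER     332
```

Twelve windows clear the ">6 kb CENP-A coverage" rule (four per
planted 30 kb core). The enrichment PCA separates them from the rest
of the genome:

```r
m   <- profile_matrix(d$genome, w, k = 5, n_shuffles = 1000, seed = 1)
pca <- fit_pca(m, n_components = 2)
compare_group_means(pca$scores[cl$group == "CENPA", 1],
                    pca$scores[cl$group == "OTHER", 1],
                    "CENPA", "OTHER")
autoplot(pca, groups = cl$group)   # score plot with 95% ellipses
```

The planted tRNA cluster (D–V–A, one copy inside each centromere) is
recovered and is never reproduced by location shuffles:

```r
res <- cluster_permutation_test(d$genome, d$annotations$genes,
                                n_perm = 1000, seed = 11)
dplyr::select(res, -null_counts)
#> # A tibble: 1 × 6
#>   signature observed_count     p below_resolution     q n_perm
#>   <chr>              <int> <dbl> <lgl>            <dbl>  <int>
#> 1 A-V-D-                 3     0 TRUE                 0   1000
```

(`A-V-D-` is the canonical, orientation-normalized form of the
planted `D+V+A+` signature; p = 0 with `below_resolution = TRUE`
means the observed count of 3 exceeded all 1000 permutations, i.e.
p < 1/1000.)

Minichromosome assay arithmetic, e.g. 204 white colonies of 217
transformants and 190 half-sectored of 3284 colonies:

```r
establishment_frequency(217, 204)
#> [1] 94
loss_rate_per_division(3284, 190)
#> [1] 5.8
```

Fitted objects have broom-style `tidy()`/`glance()` methods and
ggplot2 `autoplot()`/`plot_*()` helpers throughout.

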