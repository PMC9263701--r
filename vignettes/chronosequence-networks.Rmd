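---
title: "Methods: chronosequence community analysis and co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronosequence community analysis and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronet)
```

`chronet` implements the statistical workflow used to study how soil
bacterial communities reorganise along a land-use chronosequence — for
example, forest soils converted to tea monoculture and sampled across
stands of increasing age. This vignette documents the models, the
numerical conventions, and the design decisions behind each stage, so a
reader can judge exactly what the package computes and what its tests
do and do not demonstrate.

## The data model

The pipeline starts from four tables: an OTU count matrix (samples x
taxa, integer reads), a ranked taxonomy (kingdom through genus, any rank
possibly `"unclassified"`), per-sample design metadata (site, stand age
in years, land use, plot), and a soil-chemistry table (pH; TOC and TON
in g kg^-1^; C/N; MBC, MBN, AP and exchangeable K/Ca/Mg/Na in mg
kg^-1^). Counts are always stored as integers; relative abundances are
derived views. Stand ages are binned into four network groups — adjacent
forest `F`, young `Y3_20`, middle-aged `Y40_50` and old `Y90` stands.
The default bin edges (`<= 21`, `22-69`, `>= 70` years) are
configurable because the group membership of intermediate ages (a
21-year stand, say) is a genuine design choice rather than something
the binning can decide on its own.

## Rarefaction and diversity

Sequencing depth varies between samples, so count tables are rarefied:
each sample's reads are subsampled *without replacement* to a common
depth (default 7,000 reads) before any comparison. Rarefaction is a
single seeded draw, not an average over draws — a deliberate choice that
keeps every downstream statistic (distances, ordinations, networks)
exactly reproducible from the seed, at the cost of a small amount of
extra Monte-Carlo noise that is shared by all downstream stages.
Samples below the target depth are dropped with a warning. Alpha
diversity is reported as observed richness (OTUs with count > 0);
no Chao1/Shannon estimators are included because richness is the
quantity the downstream correlation analyses consume.

## Dissimilarity and unconstrained ordination

Between-sample structure uses Bray–Curtis dissimilarity,
$d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, computed by default
on rarefied counts (at equal depth these are proportional to relative
abundances; a relative-abundance input is equally valid and supported).

**PCoA** double-centres $-d^2/2$ (Gower), eigendecomposes, and scales
eigenvectors by $\sqrt{\lambda}$. Bray–Curtis matrices are semi-metric,
so negative eigenvalues can occur: they are reported but excluded from
the coordinates and from the proportion-explained denominator, and no
Lingoes/Cailliez correction is applied — the same convention the
distance-based RDA below relies on, which keeps "proportion explained"
interpretable as a share of the representable (positive) inertia.

**NMDS** minimises Kruskal stress-1 by iterative majorisation (the
Guttman transform) alternated with monotone regression
(pool-adjacent-violators). Ties in the input dissimilarities get the
primary ("weak") treatment: tied dissimilarities are sub-ordered by the
current configuration distances, so their fitted disparities need not
be equal. The best of `n_starts` configurations is returned; the first
start is the PCoA solution (a strong, deterministic initialisation) and
the remainder are seeded Gaussian starts. Convergence is declared when
the relative stress change drops below `tol` (default 1e-7) within
`max_iter` (300) iterations; otherwise the best configuration found is
returned with `converged = FALSE`.

**PCA** of soil profiles standardises columns (zero-variance columns
are an error when scaling) and is used for the environmental side of
the analysis only.

## PERMANOVA

For one factor with $a$ groups over $N$ samples,

$$SS_{total} = \tfrac{1}{N}\sum_{i<j} d_{ij}^2, \qquad
  SS_{within} = \sum_g \tfrac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,$$

and pseudo-$F = \frac{SS_{between}/(a-1)}{SS_{within}/(N-a)}$ with
$R^2 = SS_{between}/SS_{total}$. Labels are permuted freely (no
strata): the sampling design has independent plots within stands and
no stated blocking structure. The p-value convention is
$(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + B)$, which cannot return zero;
with `n_permutations = "exact"` all label assignments are enumerated
and the p-value is the exact tail proportion. Factors are tested in
separate one-factor runs (stand-age group and site each on their own),
mirroring how such designs are usually reported; a sequential
multi-factor decomposition is deliberately out of scope.

## Distance-based RDA and forward selection

db-RDA regresses the positive-eigenvalue principal coordinates $Y$ on
the centred, standardised explanatory matrix $X$ and reports the
constrained proportion $\mathrm{tr}(\hat Y^\top \hat Y) /
\mathrm{tr}(Y^\top Y)$, with a permutation test of the pseudo-F
statistic obtained by shuffling the rows of $X$. Soil variables are
z-standardised except pH, which is already on its own fixed scale and
is only centred (`no_scale = "pH"`).

Forward selection adds, at each step, the candidate with the smallest
permutation p-value for its marginal (partial) addition, breaking ties
by the larger partial pseudo-F, and stops when no candidate reaches
`alpha`. Because running $k$ marginal tests per step inflates the
selection-wide false-positive rate (with six noise candidates at
$\alpha = 0.05$ roughly a quarter of null datasets would admit at
least one variable), the selection is guarded by the double-stopping
rule that has become standard practice for this procedure: a global
permutation test of the full candidate set runs first, and selection
proceeds only if the global model is significant at `alpha`. This
keeps the null behaviour of the whole selection near the nominal
level, which the package's tests verify empirically.

## ANOVA with Tukey letters

Group comparisons of soil properties use one-way ANOVA followed by
Tukey's HSD at `alpha = 0.05`, summarised as a compact letter display
(insert-and-absorb algorithm; groups sharing a letter do not differ).
The function accepts either raw values or published summary statistics
(mean, sd, n per group), reconstructing the pooled mean square from
the latter — convenient for re-analysing printed tables. The
"repeated measures" label sometimes attached to chronosequence designs
does not apply here: plots are independent between stands, so a
one-way layout is the faithful model.

## Co-occurrence networks

The core of the package. For each age group:

1. **Correlation.** All-pairs Spearman correlations between
   family-level relative abundances (from rarefied counts) across the
   group's samples. Families with zero variance are excluded up front.
   P-values use the t approximation with $n-2$ df, the convention of
   the correlation-matrix tooling this analysis descends from. (The
   scalar `correlate()` helper additionally offers exact permutation
   p-values for $n \le 9$.)
2. **Thresholding.** Benjamini–Hochberg adjustment across the upper
   triangle, then an edge iff $|\rho| > 0.8$ and adjusted $p < 0.01$.
   The magnitude threshold is two-sided — negative associations are
   real edges with `sign = "negative"`. A `use_fdr = FALSE` flag
   restores literal raw-p thresholding.
3. **Subnetworks.** Each sample's subnetwork is the induced subgraph
   on the families present (abundance > 0) in that sample.
4. **Topology.** Average path length and diameter over connected pairs
   only (so the statistics stay defined on sparse subnetworks);
   density $2m/n(n-1)$; mean local clustering with 0 for degree < 2;
   modularity and cluster count from deterministic greedy
   agglomeration (no random initialisation, hence seed-free); Freeman
   betweenness centralization $\sum_i (b_{max} - b_i)/(n-1)$ with node
   betweenness pre-normalised to $[0,1]$, so a star graph scores
   exactly 1. The modularity reported is always the Q of the returned
   partition itself, computed directly from
   $Q = \sum_c \left[ e_c/m - (d_c/2m)^2 \right]$.
5. **Null models.** 10,000 Erdős–Rényi $G(n,m)$ graphs matched on node
   and edge count ("identically sized"), each passed through the same
   topology suite. Small-world assessment reports, for path length,
   clustering, cluster count and modularity, the real/null-mean ratio,
   the empirical percentile, and a flag when the real value exceeds
   the 95th null percentile. Clustering and modularity above the null
   at comparable path length is the classic small-world signature.
6. **Trends.** Per-sample subnetwork parameters are ln-transformed and
   Pearson-correlated with stand age. Samples with non-positive
   parameter values are dropped for that parameter (the logarithm is
   undefined there) rather than offset by a pseudo-count, which would
   make the correlation depend on an arbitrary constant; constant
   parameters are skipped with a warning. Topology–soil associations
   use all-pairs Spearman correlations with significance stars, soil
   variables z-normalised except pH (a monotone transform that leaves
   Spearman untouched, retained for consistency of reporting). A
   Mantel-style distance-based variant of the topology–soil analysis
   was considered and not implemented: the direct correlation reading
   is the one the per-parameter star matrix supports.

## The synthetic community generator

Because the original sequencing data live in an external archive, the
package ships a generator that reproduces the *statistical shape* of
the study so that every stage has a ground-truth test bed:

- **Design.** Three sites, ten (site, stand) groups — stands of 10 and
  90 years; 13, 50, 90 years plus a forest; 3, 21, 43 years plus a
  forest — three plots each: 30 samples. Depths uniform on
  7,265–9,204 reads. 60 families in 12 phyla with Proteobacteria,
  Actinobacteria and Acidobacteria dominant.
- **Abundances.** A Gaussian copula: per sample, a latent normal
  vector with the age group's block-correlation matrix is mapped
  through per-family log-normal marginals, normalised to proportions,
  and counts drawn Multinomial(depth, proportions). The copula is the
  one construction that guarantees a valid joint distribution with
  arbitrary block structure and the heavy-tailed marginals typical of
  relative-abundance data.
- **Planted structure.** Two guilds ("blocks") of 12 families whose
  latent correlation tightens with stand age — 0.60 (F), 0.75
  (Y3_20), 0.85 (Y40_50), 0.92 (Y90) — mimicking the qualitative
  finding that associations strengthen along the chronosequence
  without asserting any published effect size. Guild families get a
  moderately higher log-normal location (meanlog 0.7 ± 0.5 versus
  0 ± 1.2 for the background, sdlog 1.2 for all): correlation
  networks can only resolve associations among taxa whose counts rise
  above multinomial sampling noise at realistic depths, and a
  generator whose planted structure lived among unmeasurably rare
  families would test nothing. The within-family log-scale dispersion
  (sdlog 1.2, roughly an order of magnitude of abundance variation
  across samples) matches the span expected between forest soils and
  90-year monocultures.
- **Soil.** TOC = 1.0 + 0.018·age + N(0, 0.12) g kg^-1^ (about 1.0 at
  the forest end and 2.6 at 90 years) and MBN = 10 + 0.35·age +
  N(0, 3) mg kg^-1^, pH ~ N(4.1, 0.2), remaining properties
  age-independent noise around field-realistic magnitudes. These are
  generator defaults spanning the right orders of magnitude, not
  claims about any particular dataset.
- **Reproducibility.** One master seed; each sample draws from a
  substream derived by a counter, so the same configuration and seed
  give byte-identical output regardless of generation order.

What passing tests on this generator show: that the pipeline recovers
planted correlation structure, planted soil trends, and calibrated
error rates under a model whose assumptions (log-normal-ish marginals,
block-structured dependence, multinomial counting) are a reasonable
cartoon of amplicon data. What they do not show: robustness to
compositional artefacts beyond those the closure itself induces, to
spatial autocorrelation between plots, or to taxonomic
misclassification — none of which the generator emulates.

### A note on detection limits

The planted-edge recovery experiments use the raw-p thresholding mode
(the literal "|rho| > 0.8 and p < 0.01" rule). This is deliberate. At
12 samples per group, the sampling distribution of Spearman's rho
around a true copula value of ≈ 0.95 has a long left tail: even with
noiseless data, only about 72% of true pairs exceed the effective
cutoff that a Benjamini–Hochberg-adjusted p < 0.01 over all 1,770
family pairs implies (roughly rho ≥ 0.89). High recall under the
FDR-adjusted rule is therefore statistically unattainable at this
sample size regardless of implementation, and the recovery experiment
would measure the multiplicity correction, not the network
construction. The FDR-adjusted rule remains the default for real
analyses, where controlling false discoveries matters more than
recall against a known truth.

## Problem sizes and numerical conventions

The shipped tests run the full suite at deliberately modest sizes —
500-replicate null calibrations with 199 permutations, 20-replicate
recovery experiments, 1,000–10,000-graph null ensembles, 200-graph
brute-force topology comparisons on up to 7 nodes — sizes chosen so
the whole suite documents the package's statistical behaviour in a
few minutes on one core. Tolerances follow the quantity: exact
combinatorial results are asserted to machine precision (1e-10 to
1e-12), eigen-decompositions to 1e-9, Monte-Carlo quantities to their
own standard errors or to the interval the experiment defines.

## Known limitations

- Spearman co-occurrence on relative abundances is blind to
  compositional coupling; closure can induce spurious (mostly
  negative, cross-guild) correlations. Compositionality-aware
  estimators are intentionally out of scope.
- The greedy modularity partition is deterministic but not optimal;
  Q values are lower bounds on the maximum modularity.
- Subnetwork extraction uses family-level presence; OTU-level
  presence within families is not tracked.
- PERMANOVA and db-RDA p-values use free permutation; designs with
  true blocking need strata the package does not provide.
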