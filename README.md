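# chronet

Chronosequence analysis of soil bacterial communities and their
co-occurrence networks.

`chronet` is an R package for microbial ecologists studying how soil
communities reorganise after land-use conversion — the motivating case
is forest soil converted to long-term tea monoculture, sampled across
stands of increasing age ("a chronosequence"). Starting from an OTU
count table, taxonomy, sample metadata and soil chemistry, it runs the
full comparative workflow:

- **Normalisation and diversity** — seeded rarefaction to an even
  depth, observed richness, taxonomic aggregation with a top-*k*
  "others" bucket;
- **Community structure** — Bray–Curtis dissimilarity
  (`d = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`), PCoA (Gower double-centring,
  negative eigenvalues reported and excluded), NMDS (Kruskal stress-1
  by majorisation with monotone regression), PCA of soil profiles;
- **Hypothesis tests** — one-factor PERMANOVA
  (pseudo-F = (SS_B/(a−1))/(SS_W/(N−a)) under free label permutation,
  with exact enumeration for small designs), distance-based RDA with
  permutation forward selection of soil drivers (double-stopping
  rule), one-way ANOVA + Tukey HSD compact letter displays,
  Benjamini–Hochberg FDR adjustment;
- **Co-occurrence networks** — per age group, all-pairs Spearman
  correlations between family abundances; an edge where |ρ| > 0.8 and
  (BH-adjusted) p < 0.01, signed by the correlation; per-sample
  induced subnetworks; a topology suite (average path length,
  diameter, degree, density, clustering, greedy modularity, Freeman
  betweenness centralization); 10,000-graph Erdős–Rényi G(n, m) null
  ensembles with small-world assessment; and correlations of
  ln-transformed subnetwork topology with stand age and soil
  chemistry;
- **A synthetic community generator** — a Gaussian-copula simulator
  that reproduces the study design (30 samples, 10 site×stand groups,
  7,265–9,204 reads, 60 families in 12 phyla) with planted,
  age-tightening correlation blocks and planted soil trends, so every
  stage can be validated against known truth.

## Worked example

Simulate the default chronosequence design, rarefy, ordinate, test,
and build the old-stand network:

```r
library(chronet)

sim  <- simulate_dataset(simulation_config(seed = 1))
rare <- rarefy(sim$otu, depth = 7000, seed = 1)
rare
#> otu_table: 30 samples x 60 taxa (rarefied to 7000)

d   <- bray_curtis(rare)
ord <- pcoa(d)
ord
#> PCoA ordination: 30 samples, 24 axes
#> proportion explained: 26.0%, 12.2%, 8.9%, 8.8%

samp <- sim$samples[match(rownames(rare), sim$samples$sample_id), ]
permanova(d, samp$age_group, n_permutations = 999, seed = 1)
#> PERMANOVA: pseudo-F = 1.014, R2 = 0.1048, p = 0.41 (999 permutations)

fam <- aggregate_by_rank(rare, sim$taxonomy, rank = "family", top_k = Inf)
idx <- samp$age_group == "Y90"
fc  <- family_correlations(fam[idx, , drop = FALSE])
net <- build_network(fc$rho, fc$p, taxonomy = sim$taxonomy, group = "Y90")

tp  <- topology(net)
ens <- er_null_ensemble(tp$n_nodes, tp$n_edges, n_graphs = 1000, seed = 1)
small_world_assessment(tp, ens)
#>                   metric      real  null_mean     ratio percentile higher_than_null
#> 1    average_path_length 1.0000000 2.66720417 0.3749244      0.000            FALSE
#> 2 clustering_coefficient 0.2500000 0.04351548 5.7450825      0.989             TRUE
#> 3             n_clusters 7.0000000 6.68700000 1.0468072      0.809            FALSE
#> 4             modularity 0.7083333 0.49601389 1.4280514      0.996             TRUE
```

Reading the output: the PERMANOVA R² is the share of Bray–Curtis
variance between age groups (here small — the default generator plants
*correlation* structure, not compositional shifts, so this is the
expected null-ish answer). In the small-world table, the 90-year
network's clustering coefficient and modularity sit above the 95th
percentile of 1,000 size-matched random graphs (`ratio` ≈ 5.7 and 1.4,
`higher_than_null = TRUE`) — the modular, "small-world" signature that
distinguishes structured microbial networks from random ones.

The whole workflow, including per-sample subnetworks, null ensembles,
and topology-vs-age/soil correlations, can be run as one orchestrated
pipeline that writes TSV/JSON/GraphML artifacts plus a manifest of
parameters and checksums:

```r
run_pipeline(list(simulate = TRUE, seed = 1, output_dir = "run1"))
```

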