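# symbiopan

Phylosymbiosis assessment from bacterial pangenomes.

`symbiopan` is an R package for researchers asking whether a bacterial
lineage's evolution tracks the phylogeny of its animal hosts — the pattern
known as **phylosymbiosis** — using genome-scale data rather than marker-gene
surveys. It was built around the analysis of a marine bacterial genus with
free-living and invertebrate-associated lifestyles, and covers the whole
chain from pangenome structure to cophylogeny statistics:

* **Pangenome structure** — core / accessory / unique partitioning (core =
  prevalence strictly > 95%), gene accumulation curves with a Heaps'-law
  openness verdict, and a chi-squared test of gene class against lifestyle.
* **Phylogroups** — hierarchical clustering of an ANI similarity matrix cut
  at 95%, with lifestyle composition summaries.
* **Accessory-genome networks** — prevalence-filtered (> 5%) accessory
  families, Jaccard genome–genome similarity, GraphML/TSV export, and
  weighted categorical assortativity to ask whether the network organizes by
  phylogroup or by lifestyle.
* **Cophylogeny testing** — PACo: principal-coordinates embeddings of the
  two trees' patristic distances (Cailliez-corrected), symmetric Procrustes
  superimposition over the association links, residual

  m² ∈ [0, 1],  R² = 1 − m²,

  and an association-permutation p-value (1000 permutations by default);
  plus an information-based **generalized Robinson–Foulds** distance
  (mutual-information split matching, normalized to [0, 1]); and the
  published classification rule: *signal* when p < 0.05 (high if R² ≥ 0.20),
  *congruence* when additionally R² > 0.25 (weak ≤ 0.60 < strong).
* **panGWAS** — per-family two-sided Fisher's exact tests of gene presence
  against lifestyle with Haldane-corrected odds ratios, Bonferroni control
  (FWER cutoff 0.99), and clade filtering.
* **Read-recruitment profiles** — RPKM normalization with a 0.1 detection
  threshold, Bray-Curtis dissimilarity, UPGMA dendrograms, and a PACo test
  of concordance between host phylogeny and profile clustering.
* **Seeded simulators** for every input: host–symbiont cophylogenies with
  tunable host switching and loss, structured pangenome matrices with
  planted trait genes at a target odds ratio, block ANI matrices, and
  Poisson read counts — so the full pipeline runs and is testable with no
  external data.

## Worked example

Simulate a 16-host cophylogeny with moderate host switching, test it, and
classify the outcome:

```r
library(symbiopan)

co <- simulate_cophylogeny(n_hosts = 16, switch_prob = 0.3, loss_prob = 0.05,
                           multi_assoc_rate = 0.5, seed = 42)

pr <- paco(patristic_distances(co$host), patristic_distances(co$symbiont),
           co$assoc, n_permutations = 999, seed = 42)
pr
#> PACo: m2 = 0.7232, R2 = 0.2768, p = 0.015 (999 permutations, scheme r0, 18 links)

rf <- congruence_rf(co$host, co$symbiont, co$assoc, n_subsamples = 100, seed = 42)
classify_phylosymbiosis(pr$p_value, pr$r2, rf = rf$distance)
#> Cophylogenetic signal: high | Phylogenetic congruence: weak (p = 0.015, R2 = 0.277, RF = 0.852)
```

Read: the permutation test finds a non-random host–symbiont association
(p = 0.015); the Procrustes fit explains R² ≈ 0.28 of the superimposed
configuration, above both the high-signal (0.20) and congruence (0.25)
cuts, so the call is *high signal, weak congruence* — codiversification
signal eroded, but not erased, by the 30% host-switch rate we simulated.
The mean generalized RF of 0.852 over 100 one-to-one tip subsamples says
most split information is not shared, which is why congruence is weak
rather than strong.

Pangenome structure from the simulator's defaults:

```r
pg <- simulate_pangenome(seed = 42)
partition_gene_families(pg$matrix)
#> Pangenome [all]: 3313 families | core 157 (4.74%), accessory 1842 (55.60%),
#>   unique 1314 (39.66%); core prevalence > 0.95
```

The whole chain can also be driven from one YAML file:

```r
run_pipeline("run.yaml", "out/")   # writes TSVs + manifest.json
```

with per-stage blocks for thresholds (all defaulting to the published
protocol values) and a `simulate:` block when inputs should be generated.
A thin wrapper for shell use is installed at
`system.file("scripts", "symbiopan.R", package = "symbiopan")`.

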