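---
title: "Assessing phylosymbiosis from bacterial pangenomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing phylosymbiosis from bacterial pangenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiopan)
sp_log_enable(FALSE)
```

## The scientific question

Phylosymbiosis is the pattern in which microbial community relationships
recapitulate the phylogeny of their hosts. For a bacterial genus that spans
free-living and host-associated lifestyles — the motivating system is a
ubiquitous marine genus associated with invertebrates across several phyla —
the question splits into graded claims:

* **Cophylogenetic signal**: related hosts carry related bacteria more often
  than chance predicts. Signal can arise from codiversification, but also from
  trait matching or shared biogeography.
* **Phylogenetic congruence**: the stricter claim that host and symbiont
  trees share codiversification topology.

`symbiopan` implements the full analysis chain around these claims: pangenome
structure, ANI phylogroups, accessory-genome networks, Procrustes-based
cophylogeny testing with an explicit classification rule, gene–lifestyle
association, and read-recruitment profile concordance. Because the original
genome collections and metagenomes are large external resources, the package
also ships seeded simulators that generate inputs with the statistical
structure each stage assumes, making every claim testable at desk scale.

## The statistical core

### PACo: Procrustes superimposition of tree spaces

Both trees are turned into patristic distance matrices, embedded by principal
coordinates (Cailliez correction by default — patristic distances are
frequently non-Euclidean, and the correction adds the smallest constant that
makes all eigenvalues non-negative), and the two embeddings are superimposed
over the association links: each host–symbiont link contributes one row
pairing the host's coordinates with the symbiont's. After column-centring and
scaling both configurations to unit trace (symmetric scaling), the optimal
rotation is obtained from the SVD of the cross-product, and the residual sum
of squares is

$$m^2 = 1 - \left(\textstyle\sum_i \sigma_i\right)^2 \in [0, 1],
\qquad R^2 = 1 - m^2 .$$

The symmetric scaling matters: it makes $m^2$ scale-free (invariant to
uniform rescaling of either distance matrix) and guarantees $R^2 = 1 - m^2$
is a well-defined goodness of fit. An asymmetric variant would leave $m^2$
unbounded and $R^2$ meaningless, so it is not offered.

Significance comes from permuting the association matrix. Two schemes are
provided:

* `r0` (default, following the upstream convention): each host row's links
  are re-placed uniformly among the symbionts, preserving that row's link
  count. For one-to-one associations this breaks the one-to-one structure —
  permuted configurations contain duplicated symbiont rows — and we measured
  the resulting test to be anticonservative in exactly that setting (type-I
  ≈ 0.13 at nominal 0.05 on independent 16-tip trees).
* `full_shuffle`: all links are shuffled preserving the total link count and
  the at-least-one-link constraints. For a one-to-one association the
  constrained set is precisely the set of permutation matrices, which the
  implementation samples directly (uniformly); this is the exact null for
  randomly matched tips, and the measured type-I error is ≈ 0.045. Naive
  rejection sampling would practically never produce a permutation matrix
  (acceptance probability ~1e-12 at 16 links), hence the direct route.

Calibration checks therefore use `full_shuffle`; `r0` remains the default
for general many-to-many associations, where it is the field's convention.
The p-value uses the add-one estimator $(1 + \#\{m^2_{perm} \le
m^2_{obs}\})/(B + 1)$, so it can never be below $1/(B+1)$; ties count toward
rejection of neither side.

### Generalized Robinson–Foulds distance

Classic RF only credits identical splits, saturating quickly. The
information-based variant implemented here scores every pair of non-trivial
splits (one per tree) by the mutual information, in bits, between the
two-block partitions they induce on the shared tips; a maximum-weight
bipartite matching (solved exactly) pairs the splits, and the distance is
normalized as

$$d = 1 - \frac{2\,\mathrm{MSI}}{H_1 + H_2},$$

where MSI is the total matched information and $H_t$ the sum of split
entropies of tree $t$. Identical split sets give 0 (each split matches
itself with MI equal to its entropy); trees sharing no split information
give 1. The exact variant and normalization used by any particular published
analysis are rarely stated; this one is documented, bounded in [0, 1], and
verified against exhaustive enumeration over all split matchings for every
binary tree pair on 5 and 6 leaves. Star trees have no non-trivial splits;
two stars are treated as identical (distance 0).

When several symbiont tips link to one host, tree distances need a
tip-matching rule, which published analyses typically leave unstated. Here
`map_symbiont_tips()` draws seeded one-to-one subsamples (one linked tip per
host, collisions resolved by rejection), and `congruence_rf()` reports the
mean distance over subsamples (default 100) — well-defined, reproducible,
and convergent in the number of subsamples.

### The classification rule

`classify_phylosymbiosis()` encodes the decision framework: signal exists
when the PACo permutation test is significant ($p < \alpha$, default 0.05,
with 1000 permutations by default); it is graded *high* when $R^2 \ge 0.20$
and *low* otherwise; congruence additionally requires $R^2 > 0.25$ and is
graded *weak* up to $R^2 \le 0.60$, *strong* above. The 0.20 signal cut is
inferred from the published grading of $R^2 = 0.11$ as low against 0.20 as
high, and is configurable because no source prints it. An optional
generalized-RF gate can additionally be required for congruence; it is off
by default since the published framework treats RF as corroborating, not
gating. $R^2$ is rounded at the ninth decimal before threshold comparison so
that values like $1 - 0.80$ classify by their intended magnitude rather than
floating-point residue.

## Pangenome, phylogroups, network, panGWAS, profiles

**Partitioning.** A family present in exactly one genome is *unique*; one
with prevalence strictly above 0.95 is *core* (strict because the
definition is "present in more than 95% of genomes"); the rest are
*accessory*. Families absent from a genome subset are dropped before
classifying that subset, so lifestyle-restricted pangenomes have independent
totals. Percentages are rounded to two decimals.

**Accumulation and openness.** Gene accumulation curves average the
cumulative distinct-family count over seeded random genome orderings.
Openness is decided numerically — visual asymptote judgments do not
reproduce — via a Heaps'-law fit $\log(\bar F_N) = \log\kappa + \gamma \log
N$ over $N \ge 3$: open when $\gamma > 0.02$ and families are still being
gained at the final genome. Both thresholds are exposed.

**Phylogroups.** Agglomerative clustering on $1 - \mathrm{ANI}$, cut at
$1 - 0.95$. Average linkage is the default (matching the secondary
clustering of standard dereplication workflows); single linkage, equivalent
to connected components of the threshold graph, is the documented
alternative. Labels `PG1..PGk` order clusters by descending size with ties
broken by the lexicographically smallest member, so they are a function of
the clustering alone.

**Accessory network.** Families classified accessory and above 5%
prevalence feed pairwise Jaccard similarity (simple matching optional; the
upstream toolkit's exact formula is unpublished), an edge threshold
(default 0.5, configurable — display thresholds are never printed), and a
weighted categorical assortativity coefficient. Assortativity is the
quantitative stand-in for the visual claim that networks organize by
phylogroup rather than lifestyle: near 1 means edges stay within label
classes, near 0 means mixing.

**panGWAS.** Per family, a two-sided Fisher's exact test of presence
against lifestyle; the odds ratio is the sample $(ad)/(bc)$ with a Haldane
+0.5 correction when a cell is zero (whether published workflows apply one
is unstated; this one is documented). Families constant across the analyzed
genomes are skipped and excluded from the Bonferroni denominator. A hit
requires $p < 0.05$ and Bonferroni $p \le 0.99$ — the permissive published
screen; both values are reported so stricter control can be imposed
downstream. The phylogeny-aware pairwise-comparison refinement of some
pan-GWAS tools is deliberately out of scope. Exact conditional tests are
conservative at small sample sizes: the computed attained size at
$\alpha = 0.05$ under this generator's margins is ≈ 0.031 at 100 genomes and
≈ 0.039 at 400, so the null-calibration experiment is run at 400 genomes,
where the attained level approximates the nominal one; the planted-gene
recovery experiment stays at 100 genomes.

**Profiles.** RPKM = reads / ((genome length / 10³) × (library size /
10⁶)); values below the detection threshold (default 0.1) are zeroed —
zeroing rather than dropping genomes, so downstream dissimilarities keep a
common genome set. Bray-Curtis dissimilarities among samples are clustered
by UPGMA (the standard linkage for community profiles; the published
hierarchical clustering leaves its linkage unstated), and the dendrogram's
cophenetic distances face the host tree's patristic distances in PACo, with
each sample linked to its host taxon.

## What the simulators emulate — and what they do not

**Cophylogenies.** Hosts follow a Yule (pure birth) process — the simplest
model consistent with consuming host topology from a time-calibrated
database. Symbiont lineages ride the host tree: at each host bifurcation a
resident lineage codiverges, switches to a uniformly random co-existing host
branch, or is lost. Losses are re-drawn when they would leave both daughter
lineages empty; if every resident switches away a daughter starts empty and
may be re-colonized by later switches; any host tip still empty at the
present is colonized by a terminal host switch. This keeps "every host has a
symbiont" true while letting high switch rates genuinely scramble topology:
mean generalized RF rises 0 → ≈0.83 → ≈0.96 as the switch probability goes
0 → 0.4 → 0.8. Under pure codivergence the symbiont tree is an exact
relabeled copy of the host tree, branch lengths included.

**Pangenomes.** Core families at prevalence 1; accessory prevalences from a
Beta(0.5, 1.5) truncated to (1/n, 0.95) — right-skewed, mimicking the
preponderance of rare accessory genes; Poisson singleton families per
genome; planted trait families whose presence odds differ between lifestyles
by a target odds ratio around a baseline presence probability of 0.3.
Defaults (60 genomes, 150 core, 2000 accessory, 20 singletons/genome, 60%
host-associated) scale the published structure — a few percent core, a
large accessory fraction, and enough singletons to keep the pangenome open —
down to desk size.

**ANI and read counts.** Block-diagonal similarity with optional Gaussian
noise, clipped and symmetrized; and Poisson recruitment with fold
enrichment on host-linked genomes, genome lengths uniform on 3–6 Mbp,
library sizes ten times the mapped total (floored at one read so a zero-depth
sample still forms a valid, all-zero profile).

Deliberately **not** emulated: sequence evolution, orthology-inference
error, ANI estimator asymmetry beyond averaging, cross-mapping between
related genomes, compositional read noise, and biogeography. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
under its stated assumptions — not that any real dataset satisfies those
assumptions.

One consequence worth spelling out: with a strictly one-genome-per-host
association, binarized recruitment profiles make all between-sample
dissimilarities equal, and no method can (or should) find host-tree signal
in them — the concordance test's permutation distribution collapses and the
p-value is 1 by construction. Host-tree structure in profiles exists exactly
when related hosts share symbiont genomes; `clade_association()` builds that
structure (one genome per host clade), and the power analyses use it.

## Numerical choices and degenerate inputs

* PCoA axes with eigenvalue ≤ 1e-9 are dropped; without correction,
  negative eigenvalues trigger a warning and are dropped.
* Procrustes on a configuration with zero spread (all coordinates
  identical) is an error, not a silent zero.
* `paco()` requires at least 3 links; permutation p-values are reported on
  the add-one grid.
* ANI matrices are symmetrized by averaging reciprocal values within 1e-6;
  larger asymmetry is an error. Similarities above 1 are read as
  percentages.
* UPGMA sorts labels before clustering, so merge order (including exact
  ties) is a deterministic function of the distances, independent of input
  order.
* Bray-Curtis between two all-zero samples is 0 by convention, logged.
* Every randomized operation takes an explicit seed and restores the
  caller's RNG state; the pipeline derives per-stage seeds from one
  top-level seed and refuses to run randomized stages without it.

## Problem sizes used in the shipped checks

The package's own validation runs at sizes a laptop handles in about two
minutes: 16-tip trees with 199 permutations and 200 null replicates for
PACo calibration; 100 replicates for power; all 5- and 6-leaf binary tree
pairs for the generalized RF oracle; 400 neutral families on 400 genomes
(calibration) and 20 planted families on 100 genomes over 20 seeds
(recovery) for panGWAS; 50 replicates each for profile-concordance power
and calibration. The full-scale quantities of the motivating study — its
seven-clade statistics table, 57 phylogroups from 236 genomes, ≈45,600 gene
families, specific odds ratios and per-family mean RPKMs — require the
original RefSeq genomes and metagenomes and are not reproducible from
simulations; what the package reproduces exactly is the framework
arithmetic connecting the printed statistics (class percentages,
composition percentages, $R^2 = 1 - m^2$, and the signal/congruence
labels), which the acceptance script recomputes.

## Known limitations

* `r0` permutation is anticonservative for one-to-one associations (see
  above); use `full_shuffle` there.
* The generalized RF is one member of a family of information-based tree
  distances; values are comparable within this package, not across
  differently normalized implementations.
* Fisher-based panGWAS ignores phylogenetic non-independence of genomes;
  hits on strongly clonal clades should be read as co-occurrence, not
  causation. Clade filtering (e.g. analyzing pigmentation clades
  separately) mitigates but does not remove this.
* The openness verdict is a numeric convention on a fitted exponent;
  near-threshold values deserve a look at the curve itself.
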