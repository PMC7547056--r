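---
title: "Methods: from unmapped host reads to microbial hubs and their host genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from unmapped host reads to microbial hubs and their host genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phyllonet turns host whole-genome sequencing by-products into a
characterization of the leaf microbial community and of the host genetics
that may shape it. This vignette explains each stage's model, its
assumptions, the tunable parameters that matter, and the design decisions
taken where the methodology was genuinely open. Nothing here states an
empirical result that the package's tests and acceptance script do not
themselves compute.

## 1. From alignments to a genus profile

Reads that fail to align to the host reference are candidate microbial
reads. `extract_unmapped()` filters a SAM stream on the flag field alone:
a record is kept iff its unmapped bit (0x4) is set and — in the default
`paired_mode = "both"` — its mate-unmapped bit (0x8) as well. A read
whose mate maps to the host genome is more likely a host-derived chimera
than a microbial fragment, which is why both-mates-unmapped is the
default; `paired_mode = "read"` relaxes this. Secondary (0x100) and
supplementary (0x800) records are always dropped so a template is never
counted twice.

Taxonomic classification itself is out of scope: the pipeline ingests
classifier reports (the six-column Kraken-report dialect, using genus-rank
clade totals, or a plain two-column genus/count table) and assembles a
`taxonomic_profile`: a samples x genera count matrix plus lineage and
sample metadata. Genera are restricted to Bacteria and Archaea; genera
with unknown lineage are dropped, never guessed, and the dropped fraction
is reported per sample because downstream interpretation depends on that
accounting.

Two filters recur downstream and are deliberately minimal:

* `prevalence_filter(p)` keeps a genus present (nonzero) in at least
  `ceiling(p * n_samples)` samples — the network stage uses `p = 0.5`;
* `abundance_filter(t)` keeps taxa whose *mean* relative abundance is
  strictly greater than `t` (default 1%).

## 2. Diversity and the location contrast

Richness is the count of nonzero genera on unrarefied counts (no
rarefaction depth is imposed; richness at these depths is driven by the
tail of the abundance distribution, and an optional rarefaction would sit
orthogonally to everything else). Shannon H is reported in nats; the base
is switchable, and with hundreds of genera natural-log values near 3-4
are the familiar scale. Group contrasts use the Kruskal-Wallis rank test
(`stats::kruskal.test`, with the all-tied degenerate case mapped to
H = 0, p = 1).

Genus accumulation uses random sample orderings
(`vegan::specaccum(method = "random")`); the confidence band is the
percentile interval of the per-permutation cumulative richness curves at
the requested level (default 95%), which is well-defined, seedable and
has a pinned, zero-width final point.

The between-location dissimilarity is decomposed SIMPER-style on relative
abundances: the contribution of genus *i* is the mean over all
between-group sample pairs of `|x_i - y_i| / sum_j (x_j + y_j)`, so the
contributions sum *exactly* to the mean between-group Bray-Curtis
dissimilarity (this identity is enforced in the tests at 1e-12). The
report lists the minimal prefix of genera reaching a target cumulative
fraction (default 70%).

## 3. The co-occurrence network and hub calling

Counts of the prevalent genera are centered-log-ratio transformed
(`log(x + pc) - mean(log(x + pc))` per sample, pseudocount 0.5 by
default); CLR is the standard guard against compositional artifacts:
its rows sum to zero and, at zero pseudocount, the transform is invariant
to per-sample depth rescaling.

Edges are Pearson correlations between CLR columns (Spearman available).
An edge must pass two gates: `|r| >= 0.3`, and a permutation-null BH-FDR
q < 0.05, where the null pools |r| from `n_permutations` (default 50)
column-wise sample-order shuffles. The |r| threshold controls the
sparsity regime; the permutation FDR keeps weakly-sampled panels honest.
Both are exposed because the appropriate sparsity is a property of the
data, not of the method.

Per node we report weighted degree (sum of |w| over incident edges),
betweenness centrality and local clustering on the *unweighted* skeleton
(correlation weights are similarities, not distances; any
similarity-to-distance transform would be arbitrary, so path-based
metrics use topology only), and eigenvector centrality of the |w|
adjacency. Eigencentrality is computed by a dense symmetric
eigendecomposition *per connected component*, max-normalized within each
component; an ARPACK/power-iteration route was rejected because its
random start vector is not reproducible run-to-run, and per-component
normalization prevents the largest component from zeroing out every
other component's structure.

Modules are Louvain communities on the |w| graph, seeded and
deterministic; the partition's modularity Q is reported.

Hubs are called by a composite score: the equal-weighted mean of the
within-network z-scores of weighted degree, betweenness and
eigencentrality, with ties broken by node name. Local clustering and
module membership are *reported* for each hub but not scored: module
membership is categorical, and genuine hubs that bridge neighbourhoods
tend to have *low* local clustering, so scoring either would work against
the quantity of interest. The weights and k (default 12) are arguments,
because "how many hubs" is a question the data cannot answer by itself.

## 4. Community function profiles

The genus-to-pathway weight table is an input (rows normalized to 1 on
load), not a bundled database: pathway databases are version-unstable and
their reconstruction is a project of its own. `project_functions()` is
the abundance-weighted sum `rel %*% W` restricted to the annotated genus
universe and row-renormalized; before renormalization the projected mass
equals the annotated fraction of the community, which is returned so that
coverage problems are visible rather than silently absorbed. Profiles of
two groups are compared by a two-sided Wilcoxon rank-sum test on
per-pathway mean abundances.

## 5. Kinship-corrected association

The trait table is the CLR abundance of each hub genus. Relatedness is
the centered cross-product kinship `K = W W' / m` over mean-imputed,
polymorphic dosage columns — symmetric and PSD by construction.

Each trait is scanned with an exact single-random-effect linear mixed
model `y = b0 + g b + u + e`, `u ~ N(0, sg2 K)`. The variance ratio
`delta = se2/sg2` is profiled out by REML using one spectral
decomposition of K shared across all SNPs: the REML criterion is
evaluated on an 80-point log-spaced delta grid for *all* SNPs
simultaneously (three matrix products per grid sweep), and each SNP's
optimum is then Brent-refined inside its bracketing grid interval. The
Wald test uses the t distribution with n - 2 degrees of freedom, so with
K = I the scan reproduces OLS F-test p-values exactly — the calibration
anchor in the acceptance suite.

Two deliberate substitutions relative to a full multivariate LMM:

* **Univariate scans + Sidak omnibus.** The omnibus p for a SNP is
  `1 - (1 - min_t p_t)^T` over the T traits. This preserves the
  "associated with at least one hub" semantics at a fraction of the
  cost and complexity of a multivariate fit, and is exact under
  independence while conservative under the positive dependence typical
  of co-abundant hubs.
* **Per-SNP mean imputation** of missing dosages (the convention of
  standard mixed-model GWAS tools).

SNPs below 5% MAF are excluded by default (flag-exposed). Significance
defaults to BH-FDR q < 0.05 on the omnibus p; a raw p threshold is also
available for settings where a fixed genome-wide cutoff is preferred.

Calibration is checked on a null in which the trait is a hub CLR
abundance and the genotypes carry no causal effect, with one SNP per LD
block. Two properties of the alternative designs made them unusable as
acceptance gates, and are worth recording: (i) with LD blocks, the
genomic-inflation factor is a median over effectively `n_blocks`
independent statistics, so lambda fluctuates far outside [0.9, 1.1] even
for a perfectly calibrated test; (ii) with a polygenic trait drawn from
K, every tested SNP contributes to the background (proximal
contamination), so the per-SNP null is not exactly true and type-I runs
slightly above nominal. The LD-free null isolates the property actually
being asserted. The complementary property — that the mixed model absorbs
polygenic confounding that inflates OLS — is tested separately.

Pairwise haplotype-abundance contrasts at called SNPs use two-sided
Wilcoxon rank-sum tests between genotype groups (minimum group size 3,
smaller contrasts skipped and flagged), BH-adjusted across all contrasts
in the batch.

Coding effects are annotated by rebuilding the codon containing the SNP
from the CDS parts of the containing gene in transcript orientation
(reverse-complement on the minus strand), substituting the alternate
allele, and translating under the standard code; a CDS whose length is
not a multiple of 3 is flagged and skipped rather than guessed at. A
mismatch between the claimed reference allele and the reference sequence
is an error, not a silent call.

## 6. Haplotype blocks and follow-up

Because the panel is inbred, homozygous dosage pairs *are* two-locus
haplotypes: `ld_stats()` reads haplotype frequencies directly off {0,2}
dosage columns, excluding heterozygous or missing entries pairwise. This
is the largest simplification in the package — it removes EM phasing
entirely — and it is exactly right for selfing material with residual
heterozygosity at or below 1%.

D' confidence intervals come from a multinomial likelihood evaluated on a
|D'| grid in steps of 0.001 with allele frequencies at their MLEs; the CI
bounds are grid quantiles of the normalized likelihood. Blocks follow the
confidence-interval rule with the published defaults: a pair is in strong
LD iff the 90% CI satisfies lower >= 0.70 and upper >= 0.98, and a block
is a maximal run of consecutive SNPs in which >= 95% of informative pairs
are strong. Candidate intervals are accepted longest-first without
overlap, making detection deterministic; each significant SNP is anchored
to its containing block or reported as a singleton. The window searched
around each anchor defaults to +-100 kb (flag-exposed), and overlapping
anchor windows are merged so each region is scanned once.

Candidate genes overlap a block by >= 1 bp (touching intervals do not
count). A QTL is counted once per category no matter how many candidate
genes hit it. GO enrichment is the upper-tail hypergeometric probability
per term, BH-adjusted.

## 7. The synthetic study: what it emulates, and what it does not

The generator is first-class, tested code: every stage of the pipeline is
exercised against data whose truth is known.

* **Counts.** Genus base log-abundances are normal with SD 1.5
  (heavy-tailed abundances); each of `n_hubs` latent factors is a
  standard-normal per-sample score loading with weight `hub_loading`
  (default 1.0) on its hub genus and with uniform weights in
  `hub_loading * [0.3, 0.6]` on 15 partner genera; per-genus noise SD is
  0.7; counts are a multinomial draw at a depth uniform on
  [20k, 100k], so rows sum to their depth exactly. The loading asymmetry
  is the point: hub-partner correlations exceed partner-partner
  correlations, so correlation-based inference sees a hub-centred star
  over a weak clique and the hub is the most connected member of its own
  neighbourhood. Partner sets smaller than 3 are rejected as
  unrecoverable.
* **Locations.** Two locations by default; 10% of genera are private per
  location and *sporadic* within it (present in any home sample with
  probability 0.6). Sporadic occupancy is what real location-specific
  taxa look like, and it places private genera below the 50% overall
  prevalence filter, so the location signal lives in the diversity and
  SIMPER stages rather than leaking block-artifacts into the network.
* **Genotypes.** Inbred {0,2} dosages (optional heterozygosity <= 1%),
  2000 SNPs in 100 blocks over 2 chromosomes; within a block each sample
  copies its allele from the adjacent SNP with probability 0.95 and
  otherwise redraws from the SNP's frequency (uniform in `maf_range`).
  Causal SNPs (default 3, MAF >= 0.2, one block each where possible) add
  `causal_effect * dosage/2` CLR units to their hub's trait — effects act
  on the trait table, which is returned shifted, mirroring a real study
  where the microbiome is measured once and the genetics act on it.
* **Annotations.** Non-overlapping single-exon genes (ATG start, length
  divisible by 3, no internal stop) tile each chromosome, with a gene
  laid over every causal SNP so coding-effect annotation has something to
  find; the reference sequence agrees with every CDS and every SNP ref
  allele; QTLs span 1-20 genes across the three trait categories; each
  gene carries 1-5 of 50 GO terms; genus-to-pathway weights are sparse
  exponential draws, row-normalized.

All randomness flows from one master seed through per-table sub-streams,
so changing one table's parameters does not perturb another table's
draws, and identical seeds give byte-identical outputs after
serialization.

What the generator does **not** emulate — and therefore what passing
tests do *not* establish about real data: classifier misassignment and
contamination structure; zero-inflation beyond what the multinomial tail
produces; phylogenetic correlation between related genera;
population structure correlated with location (kinship in the generator
is exchangeable within the panel); linkage between causal SNPs and the
microbiome acting through the counts rather than the trait table; and
any read-level artifacts (the generator works at the count level by
design).

## 8. Numerical choices and degenerate inputs

* CLR requires a positive pseudocount when zeros are present; rows of
  the result sum to zero within 1e-9.
* Constant CLR columns (undefined correlations) are excluded from edge
  inference with a warning; an edgeless graph has Q = NA; an
  all-monomorphic panel yields a zero kinship matrix with a warning.
* The REML grid spans delta in [1e-5, 1e5]; RSS is floored at 1e-12
  before logging; kinship eigenvalues are clipped at zero (PSD up to
  1e-8 tolerance is accepted).
* Hub composite ties break lexicographically by node name; block
  candidates are accepted longest-first, then by left endpoint.
* Empty significant-SNP sets short-circuit the follow-up stages with
  empty, well-formed tables.

## 9. Problem sizes

The reference configurations used by the test-suite and the acceptance
script are chosen as the smallest sizes at which the planted structure is
comfortably identifiable rather than borderline: 300 samples x 200 genera
with 5 hubs for network recovery (20 seeds), 500 samples x 2000 SNPs with
3 causal effects of 1.0 CLR unit at MAF >= 0.2 for association recovery
(20 seeds), 5000 independent SNPs at n = 300 for null calibration, and a
200-sample end-to-end run. These are desk-scale stand-ins for a panel
two orders of magnitude larger; the statistical machinery is identical,
only the multiple-testing burden and the LD landscape differ.

## 10. Known limitations

* The hub composite is one defensible formalization of "a combination of
  centrality properties"; other weightings are reasonable, which is why
  the weights are arguments.
* The Sidak omnibus is conservative under strong positive trait
  correlation; a multivariate LMM would gain power there.
* The block rule classifies pairs independently before run-finding; very
  sparse regions can fragment blocks that denser genotyping would join.
* Direct haplotype reading is wrong for outbred material; the functions
  refuse heterozygote-rich input rather than phasing it.
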