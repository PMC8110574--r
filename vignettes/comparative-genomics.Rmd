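---
title: "Synteny-constrained comparative genomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-constrained comparative genomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(syntevol)
```

This vignette is the package's account of the science it implements: the
models, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the choices made where the design was
genuinely open.

## The problem

Comparing two related plant genomes — say, two eucalypt lineages that
split roughly 60 million years ago — raises four linked questions:

1. Which genes are orthologous, and is their chromosomal order
   preserved (synteny)? Raw similarity searches alone conflate
   orthologs, ancient paralogs and tandem copies; collinearity is the
   extra constraint that separates them.
2. When did the lineages split, and is there a shared whole-genome
   duplication (WGD)? The synonymous substitution rate Ks acts as an
   approximate molecular clock: ortholog Ks dates the divergence,
   intra-genome paralog Ks reveals duplication waves.
3. How fast do these genomes mutate at the population scale? Read
   profiles from resequenced individuals carry a signal of the
   population mutation rate θ = 4·Ne·μ.
4. Which gene families expanded in one lineage, by what mechanism
   (tandem duplication being the prime suspect), and before or after
   the split?

Every stage here operates in **gene-rank space**: a gene's rank is its
ordinal position along its chromosome, ordered by start coordinate
(ties by end, then identifier), ignoring strand. Rank space makes gap
and radius rules independent of gene density and intergenic distance.
Internally all coordinates are 0-based half-open; GFF3 I/O converts to
and from the format's 1-based inclusive convention.

## The synteny pipeline

The pipeline is a five-stage procedure; every stage is an exported
function, and `synteny_run()` chains them.

**Culling** (`cull_hits`). Self-hits are removed, hits with bit score
below 50 are dropped (strictly-less dropped, so a hit at exactly 50
survives), and for each query gene and target genome only the top
`2 × ploidy(target)` hits by bit score are kept — top two per target
haplotype, so a diploid target retains at most four hits per query.
For haploid-represented assemblies (`ploidy = 1`) this degenerates to
top-two-per-genome. Culling is idempotent and purely subtractive.

**Pairwise orthogroups** (`infer_pairwise_orthogroups`). Edges below
half of either endpoint's best inter-genome score are removed, then
connected components of the remaining hit graph become orthogroups.
This is a deterministic reimplementation of the orthogroup-clustering
step usually delegated to a dedicated tool; components err on the side
of lumping (WGD paralogs join their orthologs' group), which is
exactly what the downstream per-pair classification expects.

**Chaining** (`chain_collinear_blocks`). Anchors (orthogroup-consistent
hit pairs with rank coordinates) are chained by dynamic programming
into runs strictly monotone in both rank coordinates — increasing /
increasing for collinear blocks, increasing / decreasing for inverted
ones. Consecutive anchors may be separated by at most
`gap_allowance_factor × 0.5 × mbs` intervening ranks (5 × 5 = 25 at the
default minimum block size `mbs = 10`), applied independently on both
chromosomes. Chain score is the anchor count (unit weights, so "genes
per block" is the literal chain score); among equal-score chains the
one with smaller total rank gap wins, then the smaller starting rank.
Chains are extracted greedily best-first and chains shorter than `mbs`
are discarded. The gap rule could also be read as a per-block total
gap budget; both readings are implemented (`gap_rule` in
`synteny_params()`), with the per-step reading as the default since it
is the one a seed-and-extend collinearity scanner enforces.

**Density pruning** (`prune_blocks_density`). Within each block,
anchors are clustered by DBSCAN in 2-D rank space with radius
`5 × mbs` and core threshold `min_pts = mbs` (counting the point
itself — the "at least mbs hits within the radius" reading); noise
points and sub-`mbs` clusters are removed. The metric is Chebyshev
(maximum of the two rank distances) because the gap rule is also
per-axis; Euclidean is available via `synteny_params()`. DBSCAN is
implemented directly (quadratic neighborhoods — block anchor sets are
small) and is checked in the test suite against an independently coded
brute-force oracle.

**Completion and extension** (`complete_orthogroups`,
`extend_blocks`). Orthogroups from different pairwise runs sharing any
gene are merged by transitive closure (a true closure: applying it
twice changes nothing). Blocks are then re-formed after pulling back
*all* score-passing hits — agnostic to orthogroup identity — whose both
endpoints lie within 100 gene ranks of an existing block, which fills
gaps left by the stochastic connectivity of orthogroup inference.

**Classification** (`classify_syntenic_homologs`). Hits culled to
within 50 gene ranks of a block are labeled `ortholog` (different
genomes, same orthogroup), `paralog` (same genome, same orthogroup),
`unclustered_homolog` (no shared group, but bit score ≥ 50 *and* ≥ 50%
of the best score for that gene-by-genome combination), else `dropped`.

Summaries (`summarize_synteny`) re-filter blocks to a reporting
threshold of ≥ 25 genes per block — block *construction* uses
`mbs = 10`, chromosome-level *reporting* uses the stricter figure, the
same split a published synteny table and its companion figure use.
Percentages are rounded to one decimal, matching table conventions.

For intra-genome duplication structure, `paralog_blocks()` runs the
same chaining on within-genome hits after excluding self-hits and
pairs closer than 5 ranks, so tandem arrays cannot masquerade as
duplicated segments.

## Ks estimation and dating

`estimate_pairwise_ks()` implements Nei–Gojobori (1986) counting with
the Jukes–Cantor correction. Per codon, the synonymous site count is
the fraction of the nine possible single-base changes that preserve
the amino acid, with changes to stop codons excluded from the
synonymous fraction (so S = Σ n_syn/3 and N = 3·codons − S: stop-bound
changes count as nonsynonymous capacity — the convention of the
classical implementations). Sites are averaged over the two sequences.
For codons differing at d positions, substitution counts are averaged
over all d! mutational pathways that avoid stop codons; if every
pathway is blocked, all pathways are used with stop steps scored as
nonsynonymous. Then pS = Sd/S and Ks = −¾·ln(1 − 4·pS/3), likewise for
Ka.

Numerical guards: the Jukes–Cantor formula diverges at p = 0.75, so
p > 0.74 in either class flags the estimate `saturated` and caps the
rate at 3.0; saturated pairs are excluded from peak detection. The
estimator is validated against a brute-force per-codon oracle across
all 61 × 61 sense-codon pairs to 10 decimal places.

This is a counting estimator, not the maximum-likelihood codon-model
estimator a dedicated phylogenetics suite provides. For *peak
location* — the quantity all the dating arithmetic consumes — the two
agree well at the divergences involved here (Ks ≲ 0.5); NG86 is known
to underestimate at high divergence, which is one reason the
paleohexaploidy-scale peak (Ks ~1.2) should be read qualitatively. A
different estimator can be substituted upstream of `ks_peak()` since
the interface is just a vector of Ks values.

`backtranslate_alignment()` maps a gapped protein alignment onto its
coding sequences (terminal stop codons stripped; the ungapped protein
must equal the standard-code translation, and mismatches are reported
by residue). Simulator output contains no indels, so `codon_alignment()`
pairs equal-length CDS directly.

`ks_peak()` uses a Gaussian kernel density on [0, 3] with Silverman's
bandwidth computed on the values ≤ 2 (the tail beyond 2 is
saturation-dominated and would inflate the bandwidth); peaks are local
maxima above 5% of the maximum density. Both the mode and the median
of values within one bandwidth of the mode are reported, because
"median Ks peak" is ambiguous between the two; at a symmetric peak
they coincide to well within the reporting precision.

Rates: `rate_per_site_year(ks, T) = ks / (2T)` — divergence
accumulates along both branches. The divergence age T is deliberately
a parameter (fossil brackets give multiple defensible ages, e.g.
57.2–64.6 MYA for a eucalypt split), so rate brackets rather than
single values are the natural output. `extract_wgd_paralogs()` takes
the closed window (endpoints inclusive), e.g. Ks ∈ [0.33, 0.45] for a
Myrtales-type paleotetraploidy peak.

## Population mutation rate from read profiles

A site profile is the quartet of read base counts (nA, nC, nG, nT) at
one position; `load_profiles()` applies the minimum-depth rule
(coverage ≥ 4 by default). `estimate_theta_ml()` maximizes the
composite likelihood

L(θ, ε) = Π_sites [ (1 − H)·P(counts | hom, ε) + H·P(counts | het, ε) ]

with H = θ/(1+θ) (diploid per-site heterozygosity under the
infinite-sites approximation). Homozygous sites produce the major base
with probability 1 − ε and each other base with ε/3; heterozygous
sites draw an allele uniformly before the same error process, so each
allele base appears with probability (1−ε)/2 + ε/6. The genotype bases
are identified with the observed top counts (plug-in), which makes
(coverage, top count, second count) a sufficient statistic — the
likelihood is evaluated over the aggregated table of unique triples,
so a million sites cost the same as a few thousand unique
configurations. Optimization is a coarse log-scale grid over (θ, ε)
followed by Nelder–Mead refinement; the 95% CI is the profile
likelihood in θ (ε re-maximized at each θ, Δlog-L = 1.92).

Assumptions worth stating: sites are treated as independent (linkage
is ignored — fine for point estimation, anticonservative for the CI on
strongly linked data); the error model is symmetric and uniform across
bases and sites; all-monomorphic input pins θ at the lower
optimization bound with a warning. The estimator is exactly matched to
the generative model of `simulate_profiles()`, so simulation tests
check implementation correctness, not robustness to model
misspecification.

Conversions are exact arithmetic: μ/generation = θ/(4·Ne),
μ/year = (μ/generation)/g. Ne and g are *assumptions*, never
estimated; with θ ≈ 8.3 × 10⁻³, Ne = 112,421 and g = 15 y these give
the familiar ≈ 1.9 × 10⁻⁸ /site/generation and ≈ 1.2 × 10⁻⁹
/site/year magnitudes. (One published bound, 7.12 × 10⁻³/(4 × 112,421),
equals 1.583 × 10⁻⁸ at full precision although 1.59 × 10⁻⁸ is commonly
printed — the package reports full precision and leaves rounding to
the caller.)

## Gene families

`classify_expansion()` implements two rules with deliberately
different strictness, mirroring how such rules are phrased:
lineage-shared expansions need *more than* 5 genes and *more than* 70%
from the two focal genomes combined — plus at least one gene from each,
an added guard, since a group drawn purely from one genome would
otherwise satisfy a "derived from both" rule — while species-specific
expansions need *at least* 5 genes and *at least* 50% from the single
focal genome.

`detect_tandem_arrays()` emits maximal runs of same-family genes whose
consecutive members differ by at most `max_rank_gap` ranks; the
default 1 (strictly adjacent) is the conservative reading, and the
parameter admits the laxer ≤ N-intervening-genes conventions.
`expansion_tandem_overlap()` counts overlap at the *gene* level
(fraction of focal expansion genes that are array members), the
reading consistent with published counts of form "81% (n = 408)" over
~500 expansion genes; orthogroup-level counting is a trivial variation
on the returned tables.

`hypergeometric_enrichment()` is the standard upper-tail test
(`phyper`), flagging pathways at raw p < 0.05 as is conventional for
KEGG-style screens; Benjamini–Hochberg values are reported alongside
but never silently substituted. Because the test is discrete, its
exact size at α = 0.05 is strictly below 0.05 by an amount set by the
tail probability mass; the calibration test compares the empirical
rejection rate to the exact attained size computed by enumeration,
not to the nominal level.

## The simulator: what it emulates, and what it does not

`simulate_genomes()` produces two genomes from a common ancestor:

* an ancestral gene order (default 11 chromosomes × 182 genes — about
  2,000 genes per genome, a deliberate ~15× linear downscale of a
  ~35,000-gene genome that keeps every rank-space rule exercised at
  desk scale), CDS lengths uniform on 300–1,500 codons;
* an optional shared WGD: every chromosome's gene set is duplicated
  (appended as a second arm, echoing post-WGD fusion), duplicates
  survive with probability 0.7 (`loss_fraction = 0.3`);
* codon-level divergence to target dS values, then speciation;
* per-genome inversions (3, of 40–120 genes, with strand flip) and one
  reciprocal terminal translocation (20–60 genes) — the "few large
  intra-chromosomal rearrangements" regime;
* tandem arrays (40 per genome, sizes 2–4, copy dS 0.05) and
  species-specific expansions in genome A (10 families of 5, planted
  as tandem duplications, half recent at dS 0.08 and half
  pre-divergence at dS 0.21, echoing a bimodal expansion-age pattern).

Two non-obvious semantics:

* **`wgd_ks` is the target *contemporary* paralog divergence.**
  Post-WGD copies diverge to `wgd_ks − speciation_ks` before the
  split; both paralogs then keep evolving in each descendant, adding
  `speciation_ks` between them, so extant within-genome paralog pairs
  sit at ≈ `wgd_ks` (0.4) and ortholog pairs at ≈ `speciation_ks`
  (0.1585) — the two-peak structure the dating stage must resolve.
* **Inversions are planted on disjoint gene sets across the two
  genomes.** Overlapping inversions in both lineages would cancel
  (a double inversion is collinear), leaving the planted "inverted
  block" truth undefined.

`evolve_codons()` applies Poisson numbers of synonymous
(mean `dS_target × S`) and nonsynonymous (mean `ω × dS_target × N`,
ω = 0.2) single-base events, drawn proportionally to each codon's
change counts, never creating stops — a substitution process whose
expected NG86 divergence is the target, rather than a full codon
model. `simulate_hit_table()` synthesizes bit scores as a
deterministic monotone map from planted divergence
(`2·len·e^(−1.1·dS)`), so no aligner binary is needed and
score-ordering properties are exact; 10% random noise pairs score
uniformly on 40–80, straddling the bit-score floor. Read profiles
(`simulate_profiles`) follow exactly the θ-mixture model above.

Not emulated: indels (so codon alignments are trivial), repeats and
transposons, intron structure, assembly artifacts, GC/codon-usage
bias, rate variation among genes and sites, linkage between profile
sites, and genuinely independent error processes. Passing tests
therefore demonstrate that the pipeline recovers planted structure
under its own model assumptions — estimator and procedure correctness
— not robustness to the full messiness of real genome data.

## Problem sizes and budgets

The simulation scales used throughout (chosen once, as the package's
study conditions): two ~2,000-gene genomes for synteny recovery; all
planted ortholog and paralog pairs (~3,400 + ~2,800) for Ks peak
recovery; 10⁶ profile sites for the headline θ fit, with 20 replicate
CI-coverage runs at 10⁵ sites; 1,000 null draws × 20 pathways for
enrichment calibration. The full test suite and the acceptance script
each run in a few minutes on a single core.

## Known limitations

* NG86 underestimates Ks beyond ~1, so paleohexaploidy-scale peaks are
  qualitative; a plug-in ML estimator would refine them.
* Orthogroup inference by connected components can chain distinct
  families through promiscuous hits on dense hit graphs; the
  best-score-fraction edge filter and the downstream synteny
  constraint are the mitigations, and both matter.
* The θ CI ignores linkage and is calibrated only under the profile
  model's assumptions.
* Tandem detection depends on the family map it is given; with
  orthogroup-derived families, a WGD paralog adjacent to its partner
  by rearrangement would be (correctly, by the definition) called
  tandem.
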