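---
title: "Detecting A-to-I recoding sites from mismatch evidence: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I recoding sites from mismatch evidence: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recodeseek)
```

## The problem

Adenosine-to-inosine (A-to-I) RNA editing by ADAR enzymes is read by
sequencers as guanosine, so editing appears as A-to-G mismatches between
RNA-seq reads and the reference genome. Within protein-coding sequence,
genuine recoding sites are vastly outnumbered by three confounders that
produce the same signal: rare genomic SNPs (a typical genome carries tens of
thousands of rare variants absent from any database), systematic
misalignment of reads from paralogous loci and processed pseudogenes, and
plain base-calling error. `recodeseek` implements a detection pipeline that
attacks each confounder with a dedicated filter, plus the downstream
statistics used to characterize the resulting site set: the pooled editing
index, cross-species conservation and emergence placement,
synonymous/nonsynonymous incidence, ADAR isoform specificity, a
variance-decomposition estimator of biological variability, differential
editing tests, and edited-peptide databases for proteomic support.

## The statistical model

For each donor and site, with coverage $C$ and $E$ mismatch-supporting
reads, three binomial hypotheses explain the data without editing:

* **Sequencing error** — upper tail $P(X \ge E)$, $X \sim \mathrm{Bin}(C,
  E_{error})$ with $E_{error} = 10^{-3}$, the error probability implied by
  the Phred $q \ge 30$ base filter. (The printed form of this test arranges
  the exponents so that the summand counts $C-j$ errors; the upper tail on
  mismatch-supporting reads is the sensible reading and is what
  `pError()` computes.)
* **Rare heterozygous SNP** — $p_{het} \cdot P(X \le E)$, $X \sim
  \mathrm{Bin}(C, 0.5)$, with prior $p_{het} = 10^{-4}$. The prior is a
  conservative round-up of the rare-SNP density in coding sequence:
  $2.6\times 10^4$ CDS SNPs per individual over $3.4\times 10^7$ bp of CDS,
  of which ~4% are rare, gives $3.06\times 10^{-5}$ (`snpPriorEstimate()`).
* **Rare homozygous SNP** — $p_{hom} \cdot P(X \le E)$ with expected
  alternative fraction 1 and $p_{hom} = p_{het}^2 = 10^{-8}$; analytically
  this is $p_{hom}$ when $E = C$ and zero otherwise.

Per donor one p-value is chosen and combined over the $N$ contributing
donors with Fisher's method (natural log), $S = -2\sum_i \ln p_i$. The
chosen values are not uniformly distributed under the null, so $S$ is used
only as a filter at its reference mean: sites with $S < 2N$ are discarded,
and no per-site p-value is ever reported. The definition of the score takes
the *minimum* of the three p-values; because the homozygous term is exactly
zero whenever $E < C$, a literal minimum degenerates, so the default
combiner takes the *maximum* — a site survives only if even its most
plausible non-editing explanation is rejected — and a `literal_min` mode is
retained for auditability (it errors on zero).

Donors enter the score only when they carry at least one mismatch-supporting
read: the evidence representation is a mismatch list, so a donor with
coverage but no mismatch does not appear at a site; zero-coverage donors
carry no evidence either way.

### Strand consistency

Editing is present on both strands of the amplified cDNA, while several
technical error modes are strand-specific. Counts are pooled over all
samples and the error test is applied separately to reads aligned to each
genomic strand; both tails must fall below $\exp(-N/4)$. Here $N$ counts the
donors contributing *coverage* at the site: the pooled test uses all the
data, not only mismatch-carrying donors, and the threshold tightens with
cohort size accordingly. A strand with zero coverage fails (the conservative
reading of an unstated case). Pooled per-strand coverage is reconstructed
from the depth tables with an even split, which is immaterial at pooled
depths of thousands.

### Region- and context-level filters

* **Annotation mask** (`buildMask()`): common SNPs, 50 bp around common
  indels, positions where the reference genome carries a rare allele
  (reference allele frequency < 1%), rDNA and Alu repeats, and regions where
  both strands are annotated coding exons.
* **Sequence context** (`positionFilters()`, `filterMismatches()`):
  mismatches within 5 bp of read or alignment ends, within 4 bp of a splice
  site (exonic side), inside or immediately flanking (1 bp — the minimal
  reading of "adjacent") a homopolymer run of 5 bp or more, or below base
  quality 30; reads failing vendor checks, improperly paired, duplicated,
  with ≥ 25% of bases under q20, or carrying ≥ 3 mismatches of more than two
  distinct types (both conditions jointly).
* **Self-homology blacklist** (`homologyBlacklist()`): an exact-k-mer
  (k = 12) seeded, ungapped extension scan over 76 bp CDS windows at a 19 bp
  step, keeping local hits of length ≥ 61 bp and identity ≥ 94% ("no indels
  in query" motivates the ungapped form); within-hit mismatched positions
  and their implied substitution types are blacklisted, in both directions.
  By default only the implied type is suppressed; `strictBlacklist = TRUE`
  suppresses every type at the position.
* **Cluster filter** (`clusterFilter()`): mismatch positions are mapped to
  mature-mRNA coordinates (longest coding transcript per gene), joined
  iteratively at ≤ 100 bp (single-linkage transitive closure, which is what
  iterative pair joining computes), and clusters containing more than one
  substitution type are discarded entirely.
* **WES filter** (`wesFilter()`): pooled whole-exome evidence discards sites
  with under 100 DNA reads or a DNA mismatch level strictly above 0.1%.
* **Level filter** (`recomputeLevels()`): levels are recomputed per tissue
  from pooled unfiltered counts; sites must reach 1% in at least one tissue.
  The representative per-site value is the maximum level over tissues with
  coverage ≥ 100 (`maximalLevel()`).

The pipeline applies these in the order: position context → mask →
homology → score → strand → cluster → WES → level (`runPipeline()`, order
configurable through `stages`). Every candidate is either a survivor or
removed at exactly one stage, and the per-stage substitution spectrum lets
one watch the A-to-G (plus antisense T-to-C) fraction rise stage by stage.

### Strandedness and the T-to-C signal

Non-stranded libraries cannot tell which strand was transcribed, so the
expressed strand is assumed to be the annotated coding strand. A-to-I
editing of antisense transcripts overlapping a coding exon then surfaces as
T-to-C mismatches. In stranded mode the evidence carries the origin strand,
each strand is processed independently, and the same events are called as
A-to-G sites on the antisense strand. The per-strand editing index
(`editingIndex()` on one strand's counts) quantifies this: the index is the
pooled percentage of G among A+G reads — a coverage-weighted aggregate, not
a mean of per-site levels.

## Downstream statistics

**Conservation and emergence.** Ortholog counts pooled per species group and
category (brain / non-brain) are tested against the $10^{-3}$ error rate
with BH correction per list at FDR 0.001; absence calls additionally require
adjusted p > 0.05 and coverage ≥ 500. The emergence node of a site is the
LCA of human and the most distant conserved group whose most recent outgroup
is non-conserved; an indeterminate outgroup leaves the site unresolved, and
a site conserved nowhere with a non-conserved nearest group is a
human-specific candidate.

**Recoding incidence.** Every sense-strand CDS adenosine is classified by
its A→G consequence under the standard genetic code (stop treated as a 21st
amino acid, so stop-retaining edits are synonymous and stop-loss edits
nonsynonymous — a convention, the source being silent). $f_N/f_S$ compares
called to potential sites, with a randomization p-value from sets matched on
chromosome and ±1 bp coding-strand context. The default 10⁴ replicates
(10⁶ in the original analysis) keep the estimator identical at desk scale;
sampling is with replacement within context strata.

**ADAR specificity.** Eq-style influence $I = L_1/(L_1+L_2)$ with
pseudo-count 0.001 (exact as printed, not configurable), negatives clamped
to zero; classification by two-sided exact count tests against matched WT
with BH ≤ 0.05 and direction consistency (OE up, KO down).

**Biological variability.** With $g_i \sim \mathrm{Bin}(c_i, p_i)$,
$\mathrm{Var}(e_i) = v(1 - c^{-1}) + c^{-1}(p - p^2)$, so
$v = (\mathrm{Var}(e_i) - c^{-1}(p-p^2))/(1 - c^{-1})$. `biologicalVariability()`
uses the unbiased $(n-1)$ sample variance (the estimator targets a
population quantity from a finite sample) and clamps negative estimates to
zero. It is an over-estimate of truly biological variability, since
technical sample-to-sample effects also contribute.

**Differential editing.** Paired t-tests on per-donor levels (combined
coverage ≥ 40 per donor, pooled level ≥ 0.5% in some group, BH 0.05, and an
absolute mean difference > 10 percentage points — "10% difference" is read
as absolute); Mann–Whitney group tests (donor coverage ≥ 20, both groups
≥ 10 subjects); single-cell population pairs with a pooled exact count test
and a per-cell rank test, both BY-adjusted, for sites reaching 10% at
coverage ≥ 5 in some population.

**Proteomic support.** Proteins are digested in silico by trypsin (cleave
after K/R, suppressed before P — the standard rule, configurable), up to two
missed cleavages. For each protein all $2^s$ edited/unedited state
combinations are enumerated (capped at the 12 strongest sites per protein —
$4096$ variants — because pathological mega-clusters are combinatorially
intractable and their handling is unstated), translation stops at internal
stops, stop-gaining and stop-losing edits are dropped (both exclusions
implemented, flag-controlled), and peptides are marked `edited_only`,
`genomic_only` or `shared` by exact sequence comparison. The enrichment test
compares supported/covered site counts between a test and a control stratum
with a two-tailed exact test. The reported construction places the covered
totals, not their complements, in the second column — reproducing the
printed p-values (0.00032 for 11/17 vs 18/158) — and
`margins = "complement"` gives the textbook table, which differs only for
extreme proportions.

## The synthetic cohort generator

Every stage is exercised against `generateReference()` +
`simulateCohort()`, which plant known signals in a fully specified genome:

```{r, eval = FALSE}
cfg <- simConfig(seed = 1)       # the packaged study conditions
ref <- generateReference(cfg)
cohort <- simulateCohort(ref)
res <- runPipeline(cohort)
```

The default configuration is the packaged study condition set: 50 donors ×
5 tissues at mean depth 50 and base-calling error $10^{-3}$; 60 editing
sites with mean levels 1–30% (ten per tier); 30 rare heterozygous and 10
rare homozygous SNPs (each guaranteed a carrier); two paralog duplications
(96% identity, 10% of source-locus reads misaligned — simulated directly at
count level, since the aligner is out of scope and the downstream signature,
dense mixed-type clusters, is what matters); two antisense transcription
intervals (expression ratio 0.5, editing level 30%); common SNPs, indels,
Alu/rDNA repeats, a dual-strand CDS overlap and homopolymer runs as mask
fodder. The genome is two 80 kb chromosomes with 30 two-exon genes — sized
so that the evidence volume (~200k rows) keeps a full run in tens of
seconds on one core.

Model choices worth knowing:

* Per-donor editing levels are Beta-distributed around the site mean with
  variance $\rho\, m(1-m)$ ($\rho = 0$ means a fixed level). The Beta form
  is this package's choice — the source reports no distributional form — and
  exists chiefly so the variability estimator can be tested against known
  truth.
* Coverage is constant along a gene per (sample, gene), Poisson around the
  mean; evidence rows are materialized only where at least one mismatch read
  was drawn, with depth tables providing coverage elsewhere. Alignment
  strand is Bernoulli(1/2) per read, so per-strand counts conserve coverage
  by construction.
* Planted events of different classes are kept ≥ 110 bp apart in mRNA
  coordinates. This emulates genomic sparsity: real events are spread over
  34 Mbp of CDS, where different-type events within the 100 bp cluster
  distance are vanishingly rare, but a desk-scale genome would otherwise
  chain them into mixed clusters by construction.
* The WES companion uses a residual DNA mismatch rate of $10^{-4}$ — below
  the $10^{-3}$ RNA ceiling, because $10^{-3}$ is the *maximal* error at the
  q30 cutoff while post-filter DNA mismatch rates sit well under it; a WES
  error rate equal to the ceiling would make the strict ">0.1%" rule discard
  about half of all true sites at any depth, which is plainly not the
  behavior of the real filter.
* Reads exist in two granularities: count tables (the default; all
  statistics) and minimal SAM records (`writeCohortSam()`) that reproduce
  the count tables exactly for read-level testing. SAM emission covers
  configurations without antisense intervals.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: indels inside reads, quality-score
distributions beyond a single threshold, fragment-length and positional
coverage structure, mapping ambiguity produced by a real aligner (paralog
misalignment is planted at count level), population structure in SNP
genotypes, and correlated editing across neighboring sites.

## Numerical and degenerate-input choices

* Binomial tails come from `pbinom`; the homozygous case uses its analytic
  collapse. `pHomo(0, 0)` returns the prior (vacuous sum convention).
* The score errors on a zero chosen p-value only in `literal_min` mode; the
  default `max` combiner is bounded below by `pError` > 0.
* `maximalLevel()` is `NA` (flagged undefined) when no tissue reaches 100
  reads; `editingIndex()` is `NA` on zero A+G coverage; `adarInfluence()`
  is `NA` when both log-ratios vanish.
* Cluster joining breaks ties stably by position order; BH/BY use the
  standard step-up as implemented in `p.adjust`.
* The homology scan's seed size (k = 12) bounds its sensitivity: a
  qualifying hit is missed only if no clean 12-mer survives between
  mismatches, which at ≥ 94% identity is rare but possible in mutation
  clusters; the ECS search uses k = 8 against its 70% identity floor for the
  same reason.
* `ecsSearch()` truncates and flags queries near contig ends; free energies
  come from an injected `foldFn` (positive or missing values map to 0), so
  no thermodynamic engine is bundled.

## Problem sizes used by the checks

The packaged test suite runs the full pipeline on the default 50-donor
cohort (unstranded and stranded), verifies the three hypothesis p-values
against direct pmf summation for all $E \le C \le 200$, the cluster filter
against an $O(n^2)$ closure oracle on 1000 random instances, the codon
consequence table against the exhaustive 64 × 3 oracle, and the variability
estimator on 500 replicates of $n = 200$ samples at coverage 500. These
sizes were chosen so a complete run stays within a few minutes on a single
core while every check retains its discriminating power.

## Known limitations

* The score filter has little discriminating power per donor at moderate
  depths (a single mismatch read at $C \lesssim 700$ already passes $2N$);
  specificity is carried by the strand, cluster, WES and level filters, as
  in the source design.
* SNP rejection relies on the WES companion and the common-variant mask;
  rare SNPs without WES coverage are indistinguishable from editing by
  counts alone (prior-weighted tests only reweight them).
* The homology blacklist intentionally misses homologies below 94% window
  identity — including locally clustered mutations in an otherwise similar
  paralog — mirroring the thresholds it reimplements; the cluster and WES
  filters back it up.
* Coordinates: site tables are 1-based (VCF-like), BED exports 0-based
  half-open; mixing conventions is confined to the IO layer.
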