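---
title: "Methods: staged chromatin accessibility and the TF regulatory network"
author: "fibergrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged chromatin accessibility and the TF regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`fibergrn` implements a complete cis–trans regulatory analysis for a
six-stage developmental design: two "ovule" stages (0 and 3 days post
anthesis, DPA) and four "fiber elongation" stages (8, 12, 15, 18 DPA), with
two accessibility (DNase-seq-style) replicates and six expression (RNA-seq)
replicates per stage. The data model is deliberately minimal: DHS peak
intervals, gene models, TE intervals (`GRanges`), and non-negative integer
count matrices with stage/replicate metadata (`StageCounts`, a
`SummarizedExperiment`). Everything downstream — differential calling,
peak-to-gene linking, motif enrichment, co-expression, network
construction, clustering, QC — consumes only these objects, so real data in
the supported formats and simulated data are interchangeable.

This vignette explains each method, its assumptions and tunables, the
design decisions taken where the procedure was genuinely underdetermined,
and what the synthetic-data generator does and does not emulate.

# Interval rules

All overlap rules are fractions of the *query's* length (the `-f`
convention of interval toolkits):

- **Location categories.** A peak is promoter / genic / downstream only if
  at least 50 % of its bases fall in that class: the 1.5-kb strand-aware
  window upstream of the TSS, the gene body, or the 1.5-kb window
  downstream of the TTS. When several classes qualify, precedence is
  promoter > genic > downstream; these categories are reported as exclusive
  fractions, and the promoter-first precedence matches the regulatory focus
  of the analysis. Everything else is intergenic.
- **teDHS flag.** TE-derived status is an *independent* boolean (a peak can
  be both promoter and teDHS): total bases covered by the merged TE track
  must reach 30 % of the peak's length, boundary inclusive. The two
  thresholds (50 % and 30 %) are both exposed as arguments.
- **Nearest gene.** Distance 0 on any gene-body overlap, otherwise the gap
  in bases between interval ends; ties break toward the smaller gene start.
  A peak on a chromosome with no gene gets an `NA` sentinel and a logged
  message rather than an error.
- **Genome partition.** Per non-overlapping 1-Mb window, gene-covered
  fraction $g$ and TE-covered fraction $t$ are computed from the merged
  tracks; the window is gene-rich if $g \ge 2t$, TE-rich if $t \ge 2g$,
  else balanced. The 2× ratio is a package choice — no numeric rule exists
  for this partition — picked because it is symmetric and directly
  testable; a window empty of both tracks is balanced by convention.
- **Windowed signal.** Interval scores are attributed to windows pro rata
  by overlapping bases, so window totals conserve the input sum exactly;
  the final window on a chromosome may be short.

Every rule is validated against per-base brute-force oracles in the test
suite, exactly (not approximately), on random instances.

# Replicate QC

Window-level reproducibility is the Pearson correlation of 5-kb-window
signal between replicates, depth-normalized to counts per million by
default (raw counts via `normalize = FALSE`; whether zero–zero windows are
dropped is a flag, default retained). The rescue ratio is a *simplified*
reproducibility score, named `reciprocal_overlap_0.5` in every report so it
cannot be mistaken for IDR: a peak is reproducible when it overlaps a peak
of its sibling list by at least half of its own length; `Nt` and `Np` count
reproducible peaks over the two true-replicate lists and the two
pseudo-replicate lists, and the ratio is `min/max`.

Pseudo-replicates split the pooled peak list in half. The default split is
*identity-stratified*: the two measurement copies of the same underlying
peak always land in opposite halves. This is the peak-granularity analogue
of splitting merged reads in half — each half retains support for
essentially every peak — and it is what makes the ratio exactly 1 when the
replicate lists are identical. An independent fair-coin split
(`balanced = FALSE`) is also available; at peak granularity it strands both
copies of ~half the peaks in one half and therefore deflates `Np` for a
reason that has nothing to do with reproducibility.

# Differential calling

Normalization is median-of-ratios: per-sample factors are the median across
all-positive features of the ratio to the geometric-mean pseudo-reference.
The differential caller is a deliberately simple per-feature NB Wald test —
the decision thresholds, not the caller's internals, are the analysis
contract. Per feature, group means of normalized counts give
`log2FC = log2((mA + 1)/(mB + 1))` (pseudocount 1 guards zeros); a pooled
method-of-moments dispersion $\hat\alpha = \max((s^2 - \bar m)/\bar m^2,
10^{-8})$ feeds a delta-method standard error, and the Wald statistic is
referred to a t distribution on the pooled replicate degrees of freedom
(the small-sample choice that keeps the test near nominal size at six
replicates per group; the test suite checks type-I error 0.05 ± 0.02 on a
2,000-feature null simulation). There is no dispersion shrinkage, no
independent filtering, and no fold-change moderation.

Final calls use the two-stage consistency rule over the four
elongation-vs-0-DPA comparisons: DEGs require BH-adjusted p < 0.01 and
|log2FC| > 1 in at least two comparisons with a consistent sign; DOCRs use
raw p < 0.05 (an `adjusted` switch exists, since the raw-p convention for
accessibility is the weaker of the two standards and some users will want
symmetry). Mixed-direction significance yields `ns`: the rule speaks only
of consistent pairs. `down` means ovule-specific, `up` elongation-specific.
Note the rule is not perfectly monotone in its thresholds — loosening p can
newly make an opposite-direction comparison significant and demote a call
to `ns`; this is a property of any consistency rule, accepted as is.

# Peak-to-gene linking

Candidate pairs are DOCR–DEG pairs whose intervals lie within 50 kb
(gap-inclusive; overlap counts as 0). The correlation axis is the six
per-stage means of size-factor-normalized counts: accessibility has 2
replicates and expression 6, so sample-wise pairing is impossible and stage
means are the only common axis; n = 6 is recorded in all outputs.

The null is empirical and pooled: 10,000 random peaks (drawn from all peaks
within 50 kb of any gene body — all genes, not only DEGs; without
replacement, or with replacement when the eligible pool is smaller, as on
small synthetic genomes) are each correlated with *every* gene, and the
pool's mean and standard deviation standardize the observed correlation
into $z = (\mathrm{observed} - \mathrm{expected.mean}) /
\mathrm{expected.std}$, with a one-sided upper-tail p-value, significant at
p < 0.05.

The strict upper-tail test can only find positive (activating) links. To
admit repressive links, the default mode (`twoDirection = TRUE`) applies
the same one-sided test symmetrically to the mirrored deviation. The cost
is explicit and intrinsic: each direction contributes its own 5 % tail, so
the combined null rejection rate is ~10 %, not 5 %; calibration statements
in the tests therefore use the strict mode, and recovery statements the
two-direction mode. Users wanting the literal single-tail behaviour set
`twoDirection = FALSE`.

Significant links combine the DOCR and DEG directions into four groups:
down/down ovule-activating, down/up ovule-repressing, up/up
elongation-activating, up/down elongation-repressing; a link with an `ns`
direction on either side stays unclassified and is counted separately.

# Motif machinery

Log-odds scores are $\log_2((p + pc\,b)/((1+pc)\,b))$ in bits, with
pseudocount `pc` (default 0.01) and background `b` (default uniform;
supplying a sequence-derived background is supported through the
`MotifModel` object). Score p-values are *exact* under the background
model: scores are discretized to a stated grain (default $10^{-3}$ bits)
and the full score distribution is built by dynamic programming — a
convolution across motif columns — so the upper-tail p-value of any score
agrees with exhaustive enumeration over all $4^L$ words at the
discretization grain (checked to $10^{-12}$ for L = 6 in the tests).
Scanning reports a hit wherever the score p-value is at or below the
threshold (default $10^{-4}$, the customary scanner default), on both
strands, with reverse-strand scores computed on the reverse complement and
coordinates reported on the forward strand; windows containing non-ACGT
characters are skipped. One practical consequence of exact p-values worth
knowing: the smallest achievable p-value is $4^{-L}$, so motifs shorter
than 7 bp can never pass the $10^{-4}$ default.

Hits are assigned to DHSs by full containment (100 % of the hit inside the
peak). Enrichment is peak-level: with $N$ universe peaks of which $K$
carry a hit, and $k$ of $n$ foreground peaks carrying one, the upper-tail
hypergeometric p-value and fold $(k/n)/(K/N)$ are reported, significant at
p < 0.001. The peaks-with-hit formulation is the only one consistent with a
hypergeometric urn; hit *counts* are not urn draws. The teDHS summary
divides the mean fold-enrichment across stages in teDHSs by the mean across
stages in non-teDHSs — "mean over stages per compartment, then ratio" is
the interpretation adopted; the ratio is NA (logged) when the denominator
is empty or zero.

# Mutual-rank co-expression

Pearson correlations are computed between genes across all samples (36 in
the default design); constant genes are excluded with a message. For each
gene, partners are ranked by *decreasing absolute* correlation (self
excluded, ties broken by gene id), and `MR = sqrt(rankAB * rankBA)` is
exactly symmetric. Ranking by |PCC| rather than signed PCC is a deliberate
resolution of an internal tension: the retained network admits
negative-sign edges, which would be unreachable under rank < 3 if ranking
were signed-descending (strong negative correlations would sit at the
bottom of every list); `absolute = FALSE` restores signed ranking. An edge
survives iff `min(rankAB, rankBA) < 3` and `MR < 50`, with the sign of the
correlation attached; edges are deduplicated with gene_a < gene_b.

The rank < 3 threshold retains at most each gene's top two partners, so
only near-clique groups of at most three genes can be recovered completely
— the reason the generator's default co-expression modules have size 3.

# TF regulatory network

The accessibility network is built per stage: TF → target at stage s iff
some DHS present at s (i) overlaps the target's 1,500-bp strand-aware
upstream window by at least 50 % of the DHS's length — the package's
annotation convention, since partial-overlap handling is otherwise
undefined — and (ii) fully contains a hit of a motif mapped to the TF.
Motif-to-TF maps may be many-to-many; every TF sharing a motif receives the
edge, and hits of unmapped motifs are ignored but counted. The final
network keeps exactly those TF → target pairs that also form a
co-expression edge (either sign by default; `requirePositive = TRUE`
restricts to positive support), with the sign copied over — an exact set
intersection, asserted as such in the tests.

Stage-presence sets are classified by ordered first-match rules: (1) only
ovule stages → `ovule`; (2) ≥ 1 ovule stage and ≥ 1 of {12, 15, 18} →
`fiber_and_ovule`; (3) 8 plus a late stage → `fiber`; (4) 8 with no late
stage → `early_elongation`; (5) only late stages → `late_elongation`; an
explicit `other` bucket makes the function total (for the six-stage design
every non-empty subset in fact lands in the five named categories, which
the tests verify by enumeration). The rules as listed are not mutually
exclusive — e.g. {0, 8} — and ordered evaluation is the documented
resolution, under which {0, 8} is `early_elongation`.

Hubs are ranked by out-degree (distinct targets), tie-broken by total
degree then id — a deliberately simple, reproducible substitute for
module-centrality tooling. The per-stage TF activity score is likewise a
*substitute definition*, since no standard computation exists for this
quantity: the mean size-factor-normalized accessibility over the TF's
motif-bearing DHSs at each stage, z-standardized across stages; a TF with
no motif-bearing DHS gets an NA vector and a message.

# Profile clustering

Each gene contributes a 12-dimensional profile: six expression stage means
followed by six promoter-accessibility stage means (mean DHS stage profile
over DHSs overlapping the 1.5-kb promoter window by ≥ 50 % of the DHS, 0
when none — the aggregation is a package choice). Columns are normalized by
their 95th percentile and clipped to 1; all-zero columns stay zero. The
normalization is order-preserving up to clipping and is idempotent exactly
when a column's 95th percentile is already 1 (interpolated quantiles make
"almost-normalized" inputs move slightly — the property holds at the fixed
point, not on arbitrary renormalized data).

Clustering is Euclidean k-means with k-means++ seeding, 10 restarts, 300
Lloyd iterations, best total within-cluster sum of squares kept,
deterministic given the seed. k defaults to 13 for fidelity to the
13-cluster convention of this analysis style but is a free parameter.
Cluster numbering is arbitrary: all comparisons use label-invariant scores
(adjusted Rand index), never cluster ids. Whether to cluster on the
concatenated expression+accessibility profile or expression only is
genuinely ambiguous; concatenated is the default and `stageMeanProfiles()`
makes the expression-only variant a one-liner. Centroid rangeability is
max − min per half; a cluster is a minor-magnitude cluster when either half
ranges below 0.05. Region enrichment of a cluster against the 1-Mb
partition is upper-tail hypergeometric against the genome-wide composition,
via the gene's TSS window.

# The synthetic-data generator

`simulateFiberDataset()` emulates the study's *statistical* structure, not
its biology:

- **Genome.** Uniform-random ACGT chromosomes; 1-Mb windows labelled
  TE-rich (default 30 %), gene-rich, or balanced, with gene and TE counts
  allocated so the labels are recoverable from coverage; genes placed on a
  5-kb slot grid (never overlapping, either strand), widths 2–4.5 kb.
- **Peaks.** A DHS catalog (default 600) with a configurable teDHS fraction
  placed to overlap TEs by ≥ 35 % of peak length, promoter peaks wholly
  inside 1.5-kb upstream windows, and all other peaks rejection-sampled to
  < 30 % TE overlap, so the emitted flag always equals the recomputed rule.
  A `docrFraction` of peaks is stage-specific (present only at ovule or
  only at ≥ 2 elongation stages; absence means a 0.15× latent mean, about a
  2.7-fold accessibility contrast). Replicate peak sets are jittered
  (N(0, 20 bp)) copies of the per-stage consensus with 3 % dropout.
- **Counts.** Latent stage means are `base * (1 + cv * w)` with `w` a
  standardized stage profile and `base` uniform on 50–500; samples add a
  per-sample depth factor (±30 %) and NB noise with dispersion α (default
  0.05; variance μ + αμ²; α = 0 gives the Poisson limit). The design
  decision to build linked peaks through a shared-factor exponential link
  was replaced by this truncated-linear construction: planted links use
  Gram–Schmidt mixing so the *sample* correlation between the peak's and
  the partner gene's latent stage profiles equals `sign * linkEffect`
  exactly, which an exp-link cannot deliver at linkEffect = 1 (the
  noiseless-limit contract).
- **Expression programs.** Archetype genes carry 4-fold ovule-high or
  elongation-high programs with per-stage multiplicative jitter (default
  0.25): real stage programs differ gene to gene, and perfectly collinear
  within-class profiles would both distort the empirical link null and
  manufacture spurious "null" correlations. Ovule-high genes concentrate in
  TE-rich windows (and elongation-high in gene-rich ones), reproducing the
  coupling between pericentromeric accessibility and ovule-stage
  expression that the region-enrichment analysis is meant to detect.
  Co-expression modules (size 3, see above) and TF regulons additionally
  share a per-sample biological factor (sd 0.3): co-expressed genes in real
  data covary at the replicate level, not only through six stage means, and
  without this the 36-sample correlation cannot separate true partners from
  chance 6-point profile collisions.
- **Motifs.** Each TF gets an information-rich PWM (dominant base 0.85) of
  length 8; for every planted TF → target edge the consensus is written
  into the target's promoter DHS, and the edge's planted stage set is the
  peak's presence pattern.
- **Determinism.** One global seed fans out to per-component child seeds;
  identical configurations give byte-identical written outputs.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: realistic genome composition or an allopolyploid
subgenome structure; dinucleotide or GC sequence bias (motif backgrounds
are uniform); read-level artefacts (no FASTQ simulation, alignment,
multi-mapping loss, or peak calling); overdispersion heterogeneity across
features (α is global); and chromatin-contact-based regulation (linking is
purely distance- and correlation-based).

# Numerical choices and degenerate inputs

Score discretization 1e-3 bits; NB dispersion floored at 1e-8; k-means
ties in k-means++ seeding resolved by an infinitesimal jitter of duplicate
centers; mutual-rank ties by lexicographic gene id; constant profiles are
excluded with messages (correlation) or errors (degenerate empirical null,
all-zero size-factor reference); empty stage sets, empty peak pools, and
empty foregrounds raise typed errors. BED output is 0-based half-open and
GFF3 1-based, via rtracklayer; in-memory coordinates follow the
Bioconductor 1-based closed convention.

# Validation problem sizes

The test-suite and acceptance-script measurements use: 1,000-peak random
instances for the interval oracles; ~1,700–2,700 candidate pairs for null
calibration (no planted structure) and link recovery (200 planted links at
linkEffect 0.95 on a sparse 150-gene / 2,600-peak genome, so non-planted
pairs are genuinely null); a 50-gene matrix for the mutual-rank oracle; the
default 300-gene / 600-peak genome for network-edge and module recovery and
QC; 2,000 features for NB-test calibration and 2,000 genes (500 planted,
direction-balanced — one-directional shifts would bias median-of-ratios
normalization itself) for DEG recovery; and 300 genes in three planted
programs (jitter 0.1, base means 180–220, i.e. well-separated groups) for
clustering. These sizes were chosen as the smallest instances at which the
measured quantities are stable across seeds.

# Known limitations

The NB Wald test is anti-conservative below ~3 replicates per group and
carries no dispersion shrinkage; with very asymmetric differential signal,
median-of-ratios normalization compresses fold changes (a property of the
estimator, visible in the generator's one-directional configurations). The
two-direction link test doubles the null rejection rate by construction;
at ~10 % of candidate pairs truly linked, its positive predictive value is
bounded near 50 % regardless of effect size, so link lists at p < 0.05
should be treated as enriched candidate sets, not high-purity calls. The
rescue ratio here is peak-granularity reciprocal overlap, systematically
more optimistic than read-level IDR because halving depth cannot lose weak
peaks. Exact motif p-values assume the background model; uniform
backgrounds overstate significance on skewed genomes.
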