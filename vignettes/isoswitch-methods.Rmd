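---
title: "Methods: junction-centric differential splicing and alternative TSS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-centric differential splicing and alternative TSS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoswitch)
```

# The problem

White and beige human adipocytes differentiated in parallel from the same
donors differ not only in which genes they express but in *which isoforms* of
those genes they express. Short-read RNA-seq cannot resolve full transcripts,
but reads spanning exon–exon junctions quantify individual intron-excision
events directly and without committing to a transcript catalogue. `isoswitch`
implements a junction-centric pipeline for paired two-condition designs:

1. parse and filter splice-junction counts,
2. cluster introns that share splice sites (competing excision choices),
3. test each cluster with a Dirichlet-multinomial GLM (condition effect,
   donor confounder), yielding a per-cluster p-value and per-intron
   &Delta;PSI,
4. annotate junctions against prioritized transcript catalogues
   (e.g. GENCODE &gt; RefSeq &gt; FANTOM), classifying unannotated junctions
   by their splice-site motifs,
5. score the functional potential of the competing isoforms with TRIFID
   scores,
6. ask *where* the differential junctions fall (first introns indicate
   alternative transcription start sites) and quantify promoter chromatin /
   transcription-factor signal at the corresponding TSS windows,
7. relate differentially spliced genes (DSGs) to differentially expressed
   genes (DEGs).

A fully self-contained synthetic-data generator emulates the study design the
package targets — 6 donors &times; {white, beige} &times; 3 replicates = 36
libraries — with known ground truth, so every stage is testable end to end
without external data.

# The model

For one intron cluster with $J$ junctions, let $n_i \in \mathbb{N}^J$ be the
counts in library $i$ with total $N_i$. We model

$$ n_i \sim \mathrm{DirMult}(N_i,\; p_i,\; \alpha_0), \qquad
   p_i = \mathrm{softmax}(\eta_i), \qquad
   \eta_{ij} = \mu_j + \beta_j x_i + \textstyle\sum_d \gamma_{jd} z_{id}, $$

where $x_i$ indicates the second condition (beige), $z_{id}$ are donor
indicators, and the last junction's parameters are fixed at zero for
identifiability. A single concentration $\alpha_0$ is shared across libraries
within a cluster: a per-condition concentration would change the degrees of
freedom of the test and is not needed to describe the generator or typical
data. The log pmf, including the multinomial coefficient, is

$$ \log P(n) = \log\frac{N!}{\prod_j n_j!}
 + \log\frac{\Gamma(\alpha_0)}{\Gamma(N+\alpha_0)}
 + \sum_j \log\frac{\Gamma(n_j + \alpha_0 p_j)}{\Gamma(\alpha_0 p_j)}. $$

`dm_logpmf()` evaluates the gamma-function ratios as rising-factorial sums
$\sum_{k=0}^{n-1}\log(x+k)$ whenever the base exceeds $10^7$. This matters:
the naive difference `lgamma(a0 + N) - lgamma(a0)` loses *all* precision once
`a0` is large (the two arguments round to the same double), which in an
optimizer manifests as an unbounded spurious likelihood gain along the
concentration direction. With the stable evaluation the likelihood is
accurate for arbitrarily large $\alpha_0$, where the model correctly
approaches the multinomial.

## Fitting

`fit_cluster_dm()` maximizes the cluster likelihood by BFGS with analytic
gradients over $(\mu, \beta, \gamma, \log \alpha_0)$. Initialization:
$\mu$ at pooled log-proportions with pseudocount 0.5, effects at zero,
$\alpha_0 = 10$; relative tolerance $10^{-8}$, at most 500 iterations, one
deterministically jittered restart on failure. A cluster that still fails is
reported with `p = NA` and excluded from the multiple-testing family — never
silently assigned a value. The fitted likelihood is floored at the
initialization value, so the likelihood-improvement invariant holds even in
pathological cases.

## Testing and effect sizes

The condition effect is tested per cluster by likelihood ratio with
$\mathrm{df} = J - 1$ (one free parameter per non-reference junction).
Because $\alpha_0$ and the donor effects are estimated from only $L = 36$
libraries, the raw statistic is anticonservative: in null simulations its
mean is $\approx L/(L-K)$ times the nominal $\mathrm{df}$, where $K$ is the
number of mean-model columns — exactly the chi-squared-versus-$t$ phenomenon
of a normal model with estimated variance. `lrt_cluster()` therefore applies
a first-order Bartlett-type correction, scaling the statistic by $(L-K)/L$
(default, disable with `small_sample_correction = FALSE`). Under null
simulations at the default study geometry (2000 clusters, depth 200,
$\alpha_0$ log-normal with median 30, donor s.d. 0.25) the empirical type-I
error at $\alpha = 0.05$ is within $[0.03, 0.07]$; without the correction it
is $0.06$–$0.10$ depending on the configuration.

Effect sizes are reported as &Delta;PSI: the difference of the two softmax
proportion vectors evaluated at the donor-averaged linear predictor (uniform
mean over donors, matching the paired design), second condition minus first.
Each cluster's &Delta;PSI therefore sums to zero by construction. Cluster
p-values are Benjamini–Hochberg adjusted; junctions are classified as
condition-enriched when $|\Delta\mathrm{PSI}|$ *strictly* exceeds 0.1 in a
cluster with $q < 0.05$, as `low_differential` when they sit at or below the
threshold inside a significant cluster, and `non_significant` otherwise.
Both thresholds are arguments.

# Filters and their defaults

All thresholds are exposed as arguments and in the pipeline config; the
defaults are the operating point of the study design this package emulates:

| parameter | default | meaning |
|---|---|---|
| `min_anchor` | 6 bp | shortest aligned overhang supporting a junction |
| `min_intron`, `max_intron` | 20 bp, 1 Mb | intron length bounds (inclusive) |
| `min_reads` | 30 | cluster support, required in **every** library by default |
| `min_libs_detected` | 14 / 36 | libraries with a non-zero junction count |
| `min_libs_per_condition` | 12 | libraries per condition with cluster total &ge; `min_cluster_reads` |
| `min_cluster_reads` | 20 | read total defining a supported library |
| `alpha` | 0.05 | FDR level on cluster q-values |
| `dpsi` | 0.1 | junction effect-size threshold (strict) |
| `subsample` | 280 | control group size in the TRIFID comparison |

Two readings of the 30-read support rule exist in the field: per library, or
pooled over libraries. The default (`support_mode = "per_library"`) follows
the stricter every-library reading; `"pooled"` is provided. The iterative
refinement that drops junctions below `min_fraction = 0.001` of their
cluster's pooled reads is a conventional clustering default, also exposed.

# Annotation cascade and cryptic junctions

Junctions are matched by exact coordinates against an arbitrary number of
prioritized GTF tiers: the first tier with a hit supplies the matched
transcript set and lower tiers are ignored, so adding catalogues can only
annotate junctions that were previously cryptic, never change an existing
call (a tested invariant). Exact matching is deliberate — near-misses are
the interesting cryptic events, classified by splice-site sharing:
`alt_5prime` when the acceptor is annotated but the donor is not,
`alt_3prime` for the converse, `novel_pair` otherwise (including the rare
case where both sites are known but never paired). Motifs are read from the
genome in transcription orientation; GT–AG, GC–AG and AT–AC count as
canonical. Unstranded junctions are matched on both strands, resolved toward
the strand with more matched transcripts, and flagged when tied — the
upstream aligner's convention is not knowable here, so ambiguity is surfaced
rather than hidden.

A junction is a *first-intron* junction if it is the first intron (in
transcription order) of at least one matched transcript; the per-tier
proportion of significant junctions with this flag is the package's readout
for alternative-TSS-driven splicing. For promoter analyses each junction
contributes the most upstream TSS among its matched transcripts (minimum
coordinate on `+`, maximum on `-`), avoiding oversampling of genes with many
redundant transcript models.

# Functionality scores

TRIFID scores (normalized to $[0,1]$ per transcript) are consumed from a
table, never recomputed. A junction's score is the mean over its matched
transcripts *that have a score*; matched-but-unscored transcripts are
excluded from the mean rather than counted as zero, and a junction with no
scored transcript — including every cryptic junction — receives the sentinel
$-0.1$, which deliberately sits below the valid range. Per significant
cluster, &Delta;TRIFID compares the *top two* intron-excision events; the
two dominant events are chosen by pooled read count by default
(`rank_by = "reads"`), because abundance identifies the two isoforms that
actually compete, with `"abs_dpsi"` as the alternative; the difference is
signed so that a positive value means the isoform favoured in the second
condition is predicted more functional. The four-group score comparison
(condition-enriched junctions vs low-differential and non-significant
controls subsampled to 280) uses Kruskal–Wallis followed by pairwise t-tests
with Holm adjustment.

# Expression module

Gene-level counts are TMM-normalized (via `edgeR::calcNormFactors`, checked
in the tests against a longhand implementation of the published formula) and
filtered by a CPM rule tied to the median library size. Differential
expression uses a deliberately simplified moderated-t: per-gene linear
models on log2-CPM (prior count 0.5, effective library sizes) with condition
and donor terms, empirical-Bayes variance shrinkage by moment matching on
$\log s^2_g$, and $d_0 + d_g$ degrees of freedom. Voom precision weights and
robust outlier downweighting are intentionally omitted — the module's job
here is a calibrated DEG call for the DSG/DEG overlap, not numerical
equivalence with any published package (an externally produced DE table can
be supplied for the overlap instead). The overlap itself is
$|DSG \cap DEG| / |DSG|$; overrepresentation analysis is a one-sided Fisher
exact test per gene set with BH adjustment, equal by construction to the
hypergeometric tail.

# TSS windows and chromatin signal

Promoter windows default to $-2$ kb/$+0.5$ kb around the TSS, strand-aware,
clipped at chromosome ends, and merged per class when overlapping. Window
quantification recipes mirror common practice for specific marks
(H3K4me3: $-1$ kb/$+2$ kb; PPAR&gamma;: $\pm 250$ bp; MED1: $\pm 500$ bp).
Signal tracks are bedGraph-semantics coverage (missing = 0); the log-ratio
track is $\log_2((\mathrm{chip}+c)/(\mathrm{input}+c))$ with pseudocount
$c = 1$ so empty bins stay bounded. Window means are base-weighted. The
"scaled within each condition" quantification is a z-score using the
population standard deviation (min–max scaling available as a flag) — the
underlying figure convention is not standardized, so the choice is
documented rather than claimed. Peak overlap is &ge; 1 bp; windows whose
intervals overlap between the two enriched classes are reported as their own
class, since promoters of alternative TSS pairs of one gene often overlap.
Profile matrices tile fixed-width bins across $\pm 2$ kb, flip minus-strand
rows so bin 1 is always 5′, and exclude edge-truncated TSSs from column
means.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the study
conditions the package emulates:

* **Genome**: 2 chromosomes &times; 500 kb of uniform random sequence;
  ~200 genes placed sequentially with 0.4–1.2 kb spacing; 2–10 exons of
  60–150 bp and introns of 150–500 bp. Every simulated intron's first and
  last two bases are written into the genome as GT/AG in transcription
  orientation.
* **Isoform structure**: an `alt_tss_fraction` (default 0.3) of genes carry
  a second transcript differing only in its first exon, placed 1.5–3.5 kb
  upstream so that the two promoters' windows sometimes but not always
  overlap. Its first intron shares the acceptor of the primary first intron,
  forming the gene's junction cluster. Genes without an alternative TSS (and
  with &ge; 3 exons) instead carry an alternative 5′ splice-site variant of
  their second intron, so their cluster junctions are *not* first introns —
  this is what gives the first-intron readout a contrast to detect. Each
  cluster also has a pre-designated cryptic GT–AG junction written into the
  genome but omitted from every GTF; the count simulator expresses
  `n_cryptic` of them (default 8). Two-exon single-isoform genes contribute
  singleton junctions that the clustering stage legitimately discards.
* **Annotation tiers**: primary transcripts are always in tier 1 and copied
  into tiers 2/3 with probability 0.5/0.3; variant transcripts are homed in
  one tier (60/25/15%), so some junctions are only annotatable in lower
  tiers.
* **Junction counts**: per-library cluster totals are Poisson with mean
  `depth` (default 300, a moderately expressed gene's junction coverage);
  counts are Dirichlet-multinomial with concentration log-normal (median 30,
  log-s.d. 0.5) and logit-scale donor effects (s.d. 0.25) centred per
  junction, so the truth equals the designed proportions at the donor
  average — the same quantity the estimator targets. A `dsg_fraction`
  (default 0.1) of clusters receive a condition effect with maximum
  |&Delta;PSI| uniform on $[0.1, 0.5]$; 70% of these are drawn from
  alternative-TSS genes (`alt_tss_dsg_weight`), where the effect is placed
  beige-upward on the alternative first-intron junction, emulating the
  observation that most differential junctions in this system are
  first-intron events. TRIFID scores skew higher for alternative-TSS
  isoforms (U(0.55, 0.95) vs U(0.10, 0.80); 85% of transcripts scored), so
  a positive mean &Delta;TRIFID over true switches is a recoverable signal.
* **Gene counts**: negative-binomial (dispersion 0.1) with log-normal
  baselines, donor effects (s.d. 0.1) and a DE fraction (default 0.2) whose
  overlap with the DSG gene set is constructed to match `overlap_target`
  (default 0.1).
* **ChIP**: a flat input track and a ChIP track with Gaussian enrichment
  (amplitude 5&times;, s.d. 300 bp) at the alternative TSS of each
  beige-switching gene, log-normal noise (s.d. 0.05), 25 bp bins; one
  &plusmn;400 bp peak per enriched TSS.

Every artifact draws from its own RNG stream derived from the master seed,
so regenerating one file never perturbs the others, and equal seeds give
byte-identical files.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: alignment artifacts and anchor-length biases,
non-canonical splice sites, intron retention (invisible to junction counts),
overlapping genes and read-through clusters linking neighbours, GC and
mappability structure in ChIP input, library-size heterogeneity beyond
Poisson totals, and annotation errors in real catalogues. The generator
validates the *inference machinery and plumbing*, not the biology of any
particular dataset.

# Numerical and design choices

* Introns are stored 1-based inclusive; BED I/O converts at the boundary
  (round-trip tested). Window/peak arithmetic is 0-based half-open.
* Softmax identifiability by last-category-zero (simpler gradients than
  sum-to-zero; identical fits).
* Clusters whose fits fail conservatively leave the BH family rather than
  entering with p = 1.
* The problem sizes used in the test suite — 200-gene genomes, depth
  200–300, 2000 null clusters for calibration — run the full suite in under
  two minutes while leaving Monte-Carlo margins well inside the asserted
  bands.
* `differential_splicing()` returns a classed object with `print`,
  `summary` and `plot` (volcano) methods; `fit_cluster_dm()` returns a
  `dm_fit` with `coef` and `logLik` methods.

# Known limitations

* The DM GLM shares one concentration across libraries; strongly
  condition-dependent overdispersion would be absorbed into the mean model.
* The Bartlett-type correction is first-order; designs much smaller than
  ~20 libraries would need an explicitly derived correction or permutation
  p-values.
* Cryptic-event classification is site-based; it cannot distinguish a novel
  pairing of two known sites from a fully novel junction class beyond the
  `novel_pair` label.
* The expression module's moderated-t is a simplification (no voom weights,
  no robust shrinkage); for publication-grade DE analyses use the dedicated
  packages and feed the resulting table into `dsg_deg_overlap()`.
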