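# isoswitch

Junction-centric differential splicing and alternative-TSS analysis for
paired bulk RNA-seq designs, motivated by the comparison of white and beige
human adipocytes differentiated in parallel from the same donors.

Short reads cannot resolve full transcripts, but reads spanning exon–exon
junctions quantify individual **intron-excision events** directly. Introns
that share a splice site compete for the same excision choice and form a
**cluster**; shifts in the within-cluster proportions between conditions
reveal isoform switches — including switches driven by alternative
transcription start sites (TSSs), which show up as differential usage of
*first* introns. `isoswitch` implements the full analysis path:

- **junctions** — regtools-style BED12 or TSV junction counts; anchor
  (≥ 6 bp) and intron-length (20 bp – 1 Mb) filters; splice-site graph
  clustering with per-library support (≥ 30 reads) and strict prefilters
  (detected in ≥ 14 of 36 libraries; ≥ 12 libraries per condition with
  ≥ 20 reads).
- **diffsplice** — per-cluster Dirichlet–multinomial GLM
  `n_i ~ DirMult(N_i, softmax(mu + beta*condition + gamma*donor), a0)`
  with a likelihood-ratio test (df = J − 1, small-sample corrected),
  Benjamini–Hochberg FDR, and per-junction ΔPSI (beige − white) that sums to
  zero within each cluster. Junctions with |ΔPSI| > 0.1 in a q < 0.05
  cluster are condition-enriched.
- **annotation** — exact-coordinate matching against prioritized GTF tiers
  (first hit wins, e.g. GENCODE > RefSeq > FANTOM); unmatched junctions are
  cryptic and classified by splice-site motif (GT–AG/GC–AG/AT–AC canonical)
  and event type (`alt_5prime` / `alt_3prime` / `novel_pair`); first-intron
  flags and most-upstream TSS per junction.
- **functionality** — TRIFID scores averaged over matched scored
  transcripts (sentinel −0.1 when none), ΔTRIFID between the top two
  intron-excision events of each significant cluster, and a four-group score
  comparison with controls subsampled to 280.
- **expression** — TMM/CPM/FPKM normalization, low-expression filtering, a
  simplified moderated-t differential expression test with donor pairing,
  DSG∩DEG overlap, and Fisher overrepresentation analysis.
- **tss_chip** — strand-aware promoter windows (−2 kb/+0.5 kb, merged per
  class), log2 ChIP/input tracks, base-weighted window means with named
  recipes (H3K4me3 −1 kb/+2 kb, PPARγ ±250 bp, MED1 ±500 bp),
  within-condition scaling, peak-overlap fractions and TSS-anchored
  profiles.
- **synthetic_data** — a self-contained generator (genome, three GTF tiers,
  TRIFID table, junction and gene counts, ChIP tracks, peaks, design file)
  emulating the 6-donor × 2-condition × 3-replicate design with known ground
  truth.

See the methods vignette (`vignettes/isoswitch-methods.Rmd`) for the model,
its assumptions, all tunable parameters, and known limitations.

## Worked example

Simulate a complete toy study and run every stage:

```r
library(isoswitch)
sim <- simulate_dataset("demo", seed = 42)   # writes all inputs + config
res <- run_pipeline(sim$config)              # cluster ... tss
print(res$splicing)
```

```
splicing_result: 185 clusters tested, 19 significant at q < 0.05
junction classes:
  beige_enriched       18
  low_differential     2
  non_significant      340
  white_enriched       18
```

The generator planted differential splicing in 10% of ~190 clusters, so ~19
significant clusters with matching beige/white junction pairs is the designed
signal being recovered. Where do the significant junctions fall, and what do
their promoters look like?

```r
first_intron_proportions(res$annotation, res$splicing)
#   source  n n_first proportion
# 1  tier1 28      21  0.7500000
# 2  tier2  3       1  0.3333333
# 3  tier3  5       4  0.8000000

res$window_signal$class_summary       # mean log2 ChIP/input per TSS class
#    class   n       mean       median
# 1  beige  18 0.37472211 0.5150183963
# 2 nonsig 119 0.02802978 0.0004344123
# 3  white  18 0.14436048 0.0998278557

res$overlap$fraction                  # DSG/DEG overlap
# [1] 0.1111111
```

Most differentially spliced junctions map to first introns (the generator
drives 70% of true switches through alternative TSSs), beige-class promoter
windows carry the planted ChIP enrichment (0.37 vs 0.03 for non-significant
TSSs), and only ~11% of differentially spliced genes are also differentially
expressed — the generator's configured overlap. `res$delta_trifid` lists the
per-cluster ΔTRIFID values with positive values meaning the beige-favoured
isoform is predicted more functional.

A thin CLI wraps the same functions
(`inst/scripts/isoswitch.R simulate|run|... --config demo/config.txt`), with
exit codes 0/2/3 for success / validation error / stage failure, and a JSON
manifest (input MD5s, parameters, row counts) per run.

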