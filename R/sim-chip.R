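#' Simulate ChIP and input signal tracks with promoter-localized enrichment
#'
#' Writes binned bedGraph tracks for a ChIP sample and its input control over
#' the simulated genome, plus a BED file of called peaks. The input track is
#' flat positive coverage with multiplicative log-normal noise; the ChIP
#' track multiplies the same baseline by a Gaussian-shaped enrichment
#' (default amplitude 5x, s.d. 300 bp) centred on the TSS of each gene in
#' `beige_tss_genes` (the alternative TSS when the gene has one). One peak
#' interval of +/- `peak_halfwidth` bp is written per enriched TSS.
#'
#' @param annotation A `sim_annotation`.
#' @param beige_tss_genes Character vector of enriched genes (may be empty).
#' @param outdir Output directory.
#' @param bin Bin width of the bedGraph tracks (bp).
#' @param amplitude Peak ChIP/input enrichment at the TSS.
#' @param enrich_sd Gaussian s.d. of the enrichment shape (bp).
#' @param input_level Baseline coverage value.
#' @param noise_sd Log-normal noise s.d. (log scale).
#' @param peak_halfwidth Half-width of written peak intervals (bp).
#' @param seed Master seed (dedicated RNG stream).
#' @return List with `paths` (chip/input bedGraph, peaks BED) and `tss`
#'   (data.frame of the enriched TSSs).
#' @export
simulate_chip <- function(annotation, beige_tss_genes,
                          outdir = tempfile("simchip"),
                          bin = 25, amplitude = 5, enrich_sd = 300,
                          input_level = 1, noise_sd = 0.05,
                          peak_halfwidth = 400, seed) {
  assert_seed(seed)
  set.seed(stream_seed(seed, "chip"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  missing_genes <- setdiff(beige_tss_genes, annotation$genes$gene_id)
  if (length(missing_genes) > 0)
    stop("genes without a TSS in the annotation: ",
         paste(missing_genes, collapse = ", "))

  tx <- annotation$transcripts
  tss <- do.call(rbind, lapply(beige_tss_genes, function(g) {
    gt <- tx[tx$gene_id == g, , drop = FALSE]
    pick <- if (any(gt$role == "alt_tss")) which(gt$role == "alt_tss")[1] else 1L
    data.frame(gene_id = g, chrom = gt$chrom[pick], tss = gt$tss[pick],
               strand = gt$strand[pick])
  }))

  chip_gr <- list(); input_gr <- list()
  for (ch in names(annotation$chrom_lengths)) {
    len <- annotation$chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = bin)            # 0-based half-open bins
    centers <- starts + bin / 2
    base <- input_level * exp(rnorm(length(starts), 0, noise_sd))
    enrich <- rep(1, length(starts))
    if (!is.null(tss)) for (i in which(tss$chrom == ch)) {
      enrich <- enrich + (amplitude - 1) *
        exp(-(centers - tss$tss[i])^2 / (2 * enrich_sd^2))
    }
    chip_val <- input_level * exp(rnorm(length(starts), 0, noise_sd)) * enrich
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts + 1L,
                                                      pmin(starts + bin, len)))
    gr_chip <- gr; gr_chip$score <- round(chip_val, 4)
    gr_input <- gr; gr_input$score <- round(base, 4)
    chip_gr[[ch]] <- gr_chip
    input_gr[[ch]] <- gr_input
  }
  chip <- suppressWarnings(do.call(c, unname(chip_gr)))
  input <- suppressWarnings(do.call(c, unname(input_gr)))
  GenomeInfoDb::seqlengths(chip) <- annotation$chrom_lengths
  GenomeInfoDb::seqlengths(input) <- annotation$chrom_lengths

  paths <- list(chip = file.path(outdir, "chip.bedgraph"),
                input = file.path(outdir, "input.bedgraph"),
                peaks = file.path(outdir, "peaks.bed"))
  rtracklayer::export(chip, paths$chip, format = "bedGraph")
  rtracklayer::export(input, paths$input, format = "bedGraph")

  if (is.null(tss) || nrow(tss) == 0) {
    writeLines(character(0), paths$peaks)
  } else {
    peaks <- GenomicRanges::GRanges(
      tss$chrom,
      IRanges::IRanges(pmax(tss$tss - peak_halfwidth, 1L),
                       tss$tss + peak_halfwidth))
    names(peaks) <- tss$gene_id
    rtracklayer::export(peaks, paths$peaks, format = "BED")
  }
  list(paths = paths, tss = tss)
}
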