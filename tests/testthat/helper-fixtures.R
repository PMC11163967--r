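# Shared fixtures: all built in code at test time.

tiny_design <- function(n_donors = 6, n_replicates = 3)
  make_study_design(n_donors = n_donors, n_replicates = n_replicates)

# Wrap a count matrix as an intron_cluster with dummy coordinates.
mk_cluster <- function(counts, id = "test_cluster", chrom = "chr1",
                       strand = "+") {
  J <- nrow(counts)
  junctions <- data.frame(chrom = chrom,
                          start = seq(100, by = 1000, length.out = J),
                          end = seq(500, by = 1000, length.out = J),
                          strand = strand, anchor = 25L)
  junctions$key <- paste(chrom, strand, junctions$start, junctions$end,
                         sep = ":")
  structure(list(cluster_id = id, junctions = junctions, counts = counts),
            class = "intron_cluster")
}

# Build a junction_table directly from coordinate/count specs.
mk_junction_table <- function(chrom, start, end, strand, anchor, counts) {
  junction_table(data.frame(chrom = chrom, start = start, end = end,
                            strand = strand, anchor = anchor), counts)
}

# Write a minimal GTF from a list of transcripts:
# list(tid = list(gene, chrom, strand, exons = matrix(start, end))).
write_toy_gtf <- function(transcripts, path = tempfile(fileext = ".gtf")) {
  lines <- character(0)
  for (tid in names(transcripts)) {
    tx <- transcripts[[tid]]
    attr <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene, tid)
    lines <- c(lines,
               sprintf("%s\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tx$chrom, min(tx$exons[, 1]), max(tx$exons[, 2]),
                       tx$strand, attr),
               sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s",
                       tx$chrom, tx$exons[, 1], tx$exons[, 2], tx$strand,
                       attr))
  }
  writeLines(lines, path)
  path
}

tempfile_gtf_empty <- function() {
  p <- tempfile(fileext = ".gtf")
  writeLines(character(0), p)
  p
}

# Small cached synthetic dataset shared by the heavier tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(file.path(tempdir(), "isoswitch_shared_sim"),
                                 seed = 101)
    cache
  }
})
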