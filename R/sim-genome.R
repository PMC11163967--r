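# Synthetic genome + tiered annotation generator.
#
# Genes are laid out sequentially along each chromosome. Every gene has a
# primary transcript; a configurable fraction carries an alternative-TSS
# transcript that differs only in its first exon (its first intron shares the
# acceptor of the primary first intron, so the two junctions form an intron
# cluster). Multi-exon genes without an alternative TSS instead carry an
# alternative 5' splice-site variant of their second intron, giving every
# gene with >= 3 exons exactly one junction cluster. Each cluster also has a
# pre-designated "cryptic candidate" junction: a GT-AG junction written into
# the genome sequence but absent from every GTF tier, which the count
# simulator may later populate with reads.

#' Generate a toy genome, tiered annotations and a TRIFID score table
#'
#' Writes a random genome FASTA (with `.fai` index), three prioritized GTF
#' annotation tiers with partially overlapping transcript content, and a
#' TRIFID score TSV covering a configurable fraction of transcripts. All
#' simulated introns start `GT` and end `AG` in transcription orientation;
#' this is enforced by writing the dinucleotides into the genome sequence.
#'
#' @param outdir Output directory (created if needed).
#' @param n_genes Number of genes to place.
#' @param alt_tss_fraction Fraction of genes that carry a second transcript
#'   differing only in its first exon/TSS.
#' @param trifid_fraction Fraction of transcripts that receive a TRIFID score;
#'   the remainder are absent from the table.
#' @param n_chrom,chrom_length Genome shape (default 2 x 500 kb).
#' @param seed Master seed; the generator draws from a dedicated RNG stream.
#' @return An object of class `sim_annotation`: gene/transcript/junction truth
#'   tables plus the written file paths (`$paths`).
#' @export
make_genome_and_annotation <- function(outdir = tempfile("simgenome"),
                                       n_genes = 200,
                                       alt_tss_fraction = 0.3,
                                       trifid_fraction = 0.85,
                                       n_chrom = 2,
                                       chrom_length = 500000L,
                                       seed) {
  assert_seed(seed)
  assert_proportion(alt_tss_fraction, "alt_tss_fraction")
  assert_proportion(trifid_fraction, "trifid_fraction")
  if (n_genes < 1) stop("n_genes must be >= 1")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  set.seed(stream_seed(seed, "genome"))
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom_lengths <- setNames(rep(as.integer(chrom_length), n_chrom), chroms)

  is_alt <- rep(FALSE, n_genes)
  if (n_genes == 1) {
    is_alt[1] <- alt_tss_fraction >= 1
    if (alt_tss_fraction > 0 && alt_tss_fraction < 1)
      is_alt[1] <- runif(1) < alt_tss_fraction
  } else {
    n_alt <- round(alt_tss_fraction * n_genes)
    is_alt[sample.int(n_genes, n_alt)] <- TRUE
  }

  margin <- 2500L          # promoter-window headroom at chromosome ends
  genes <- vector("list", n_genes)
  chrom_i <- 1L
  cursor <- margin
  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("g%03d", g)
    spec <- layout_gene(gene_id, alt_tss = is_alt[g])
    if (cursor + spec$length > chrom_length - margin) {
      chrom_i <- chrom_i + 1L
      cursor <- margin
      if (chrom_i > n_chrom || cursor + spec$length > chrom_length - margin)
        stop(sprintf(
          "n_genes = %d cannot fit a %d x %d bp genome with minimum spacing",
          n_genes, n_chrom, chrom_length))
    }
    genes[[g]] <- realize_gene(spec, chroms[chrom_i], cursor)
    cursor <- cursor + spec$length + sample(400:1200, 1)
  }

  gene_tab <- do.call(rbind, lapply(genes, `[[`, "gene"))
  tx_tab <- do.call(rbind, lapply(genes, `[[`, "transcripts"))
  jn_tab <- do.call(rbind, lapply(genes, `[[`, "junctions"))
  exons <- do.call(c, lapply(genes, `[[`, "exons"))
  forced <- do.call(rbind, lapply(genes, `[[`, "forced"))
  rownames(gene_tab) <- rownames(tx_tab) <- rownames(jn_tab) <- NULL

  # tier membership: primary transcripts always in tier 1 (sometimes copied
  # to lower tiers); variant transcripts homed in one tier only
  tx_tab$tiers <- vapply(seq_len(nrow(tx_tab)), function(i) {
    if (tx_tab$role[i] == "primary") {
      t <- 1L
      if (runif(1) < 0.5) t <- c(t, 2L)
      if (runif(1) < 0.3) t <- c(t, 3L)
    } else {
      t <- sample(1:3, 1, prob = c(0.6, 0.25, 0.15))
    }
    paste(t, collapse = ",")
  }, character(1))

  # TRIFID scores: alternative-TSS isoforms skew high so that gain-of-function
  # switches toward the alternative isoform are detectable downstream
  scored <- runif(nrow(tx_tab)) < trifid_fraction
  score <- ifelse(tx_tab$role == "alt_tss",
                  runif(nrow(tx_tab), 0.55, 0.95),
                  runif(nrow(tx_tab), 0.10, 0.80))
  trifid <- data.frame(transcript_id = tx_tab$transcript_id[scored],
                       trifid_score = round(score[scored], 4))

  # genome sequence with forced splice-site dinucleotides
  seqs <- lapply(chroms, function(ch) {
    s <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
    f <- forced[forced$chrom == ch, , drop = FALSE]
    s[f$pos] <- f$base
    paste(s, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms

  paths <- list(
    fasta = file.path(outdir, "genome.fa"),
    gtf = setNames(file.path(outdir, paste0("annotation_tier", 1:3, ".gtf")),
                   paste0("tier", 1:3)),
    trifid = file.path(outdir, "trifid.tsv")
  )
  Biostrings::writeXStringSet(genome, paths$fasta)
  if (requireNamespace("Rsamtools", quietly = TRUE))
    try(Rsamtools::indexFa(paths$fasta), silent = TRUE)
  for (tier in 1:3)
    write_sim_gtf(gene_tab, tx_tab, exons, tier, paths$gtf[tier])
  write.table(trifid, paths$trifid, sep = "\t", quote = FALSE,
              row.names = FALSE)

  structure(list(genes = gene_tab, transcripts = tx_tab, junctions = jn_tab,
                 exons = exons, trifid = trifid,
                 chrom_lengths = chrom_lengths, paths = paths, seed = seed),
            class = "sim_annotation")
}

#' @export
print.sim_annotation <- function(x, ...) {
  cat(sprintf(
    "sim_annotation: %d genes (%d alt-TSS) on %d chromosome(s), %d transcripts, %d junctions\n",
    nrow(x$genes), sum(x$genes$alt_tss), length(x$chrom_lengths),
    nrow(x$transcripts), nrow(x$junctions)))
  invisible(x)
}

# Decide a gene's internal layout on the transcription axis (0-based offsets).
layout_gene <- function(gene_id, alt_tss) {
  m <- sample(2:10, 1)
  xl <- sample(60:150, m, replace = TRUE)
  il <- if (m > 1) sample(150:500, m - 1, replace = TRUE) else integer(0)
  # the alternative first exon sits 1.5-3.5 kb upstream so that beige and
  # white promoter windows (-2 kb/+0.5 kb) sometimes, but not always, overlap
  alt_len <- if (alt_tss) sample(60:150, 1) else 0L
  alt_gap <- if (alt_tss) sample(1500:3500, 1) else 0L
  offset <- alt_len + alt_gap
  ts <- te <- integer(m)
  pos <- offset
  for (k in seq_len(m)) {
    ts[k] <- pos
    te[k] <- pos + xl[k] - 1L
    pos <- te[k] + 1L + if (k < m) il[k] else 0L
  }
  list(gene_id = gene_id, m = m, ts = ts, te = te, alt_tss = alt_tss,
       alt_len = alt_len, strand = sample(c("+", "-"), 1),
       length = te[m] + 1L)
}

# Map the layout to genomic coordinates, returning truth tables and the
# dinucleotides that must be written into the genome (GT donors / AG
# acceptors in transcription orientation).
realize_gene <- function(spec, chrom, gstart) {
  m <- spec$m; ts <- spec$ts; te <- spec$te
  strand <- spec$strand
  gene_id <- spec$gene_id
  gend <- gstart + spec$length - 1L
  tmap <- function(t) if (strand == "+") gstart + t else gend - t
  grange <- function(t1, t2) sort(c(tmap(t1), tmap(t2)))

  forced <- list()
  force_base <- function(t, base) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    forced[[length(forced) + 1L]] <<- data.frame(
      chrom = chrom, pos = tmap(t),
      base = if (strand == "+") base else unname(comp[base]))
  }
  force_intron <- function(d, a) {   # t-coords of first/last intronic base
    force_base(d, "G"); force_base(d + 1L, "T")
    force_base(a - 1L, "A"); force_base(a, "G")
  }
  force_donor <- function(d) { force_base(d, "G"); force_base(d + 1L, "T") }

  # primary transcript
  tid1 <- paste0(gene_id, ".t1")
  exons <- list()
  ex1 <- t(vapply(seq_len(m), function(k) grange(ts[k], te[k]), numeric(2)))
  exons[[tid1]] <- ex1
  introns_t <- if (m > 1)
    cbind(te[seq_len(m - 1)] + 1L, ts[-1] - 1L) else
    matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(introns_t))) force_intron(introns_t[k, 1], introns_t[k, 2])

  jn <- list()
  add_junction <- function(t1, t2, role, first_intron, in_cluster) {
    g <- grange(t1, t2)
    jn[[length(jn) + 1L]] <<- data.frame(
      gene_id = gene_id, chrom = chrom, strand = strand,
      start = g[1], end = g[2], role = role,
      first_intron = first_intron, in_cluster = in_cluster)
  }
  cluster_type <- "none"
  for (k in seq_len(nrow(introns_t))) {
    role <- "intron"
    in_cluster <- FALSE
    if (spec$alt_tss && k == 1L) in_cluster <- TRUE
    if (!spec$alt_tss && m >= 3 && k == 2L) in_cluster <- TRUE
    add_junction(introns_t[k, 1], introns_t[k, 2], role,
                 first_intron = (k == 1L), in_cluster = in_cluster)
  }

  tx <- data.frame(transcript_id = tid1, gene_id = gene_id, chrom = chrom,
                   strand = strand, tss = tmap(0L), role = "primary")

  if (spec$alt_tss) {
    cluster_type <- "alt_tss"
    tid2 <- paste0(gene_id, ".t2")
    aL <- spec$alt_len
    exons[[tid2]] <- rbind(grange(0L, aL - 1L),
                           ex1[-1, , drop = FALSE])
    # alternative first intron: from the alt exon to exon 2, sharing the
    # acceptor of the primary first intron
    force_donor(aL)
    add_junction(aL, ts[2] - 1L, "alt_first", first_intron = TRUE,
                 in_cluster = TRUE)
    tx <- rbind(tx, data.frame(transcript_id = tid2, gene_id = gene_id,
                               chrom = chrom, strand = strand, tss = tmap(0L),
                               role = "alt_tss"))
    # the alt transcript starts at t = 0, the primary at its own first exon
    tx$tss[tx$transcript_id == tid1] <- tmap(ts[1])
    # cryptic candidate: donor 60 bp inside the primary first intron
    d <- te[1] + 1L + 60L
    force_donor(d)
    add_junction(d, ts[2] - 1L, "cryptic_candidate", first_intron = NA,
                 in_cluster = TRUE)
  } else if (m >= 3) {
    cluster_type <- "internal"
    tid2 <- paste0(gene_id, ".t2")
    ex2 <- ex1
    # variant: exon 2 extended 30 bp into intron 2 (alternative 5' site)
    d2 <- te[2] + 1L
    ext <- grange(ts[2], te[2] + 30L)
    ex2[2, ] <- ext
    exons[[tid2]] <- ex2
    force_donor(d2 + 30L)
    add_junction(d2 + 30L, ts[3] - 1L, "alt_internal", first_intron = FALSE,
                 in_cluster = TRUE)
    tx <- rbind(tx, data.frame(transcript_id = tid2, gene_id = gene_id,
                               chrom = chrom, strand = strand, tss = tmap(0L),
                               role = "alt_internal"))
    d <- d2 + 60L
    force_donor(d)
    add_junction(d, ts[3] - 1L, "cryptic_candidate", first_intron = NA,
                 in_cluster = TRUE)
  }

  jn_tab <- do.call(rbind, jn)
  jn_tab$junction_id <- junction_key(jn_tab$chrom, jn_tab$strand,
                                     jn_tab$start, jn_tab$end)
  gene <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                     start = gstart, end = gend, n_exons = m,
                     alt_tss = spec$alt_tss, cluster_type = cluster_type)
  list(gene = gene, transcripts = tx, junctions = jn_tab, exons = exons,
       forced = do.call(rbind, forced))
}

# Write one annotation tier as GTF (gene, transcript and exon features with
# gene_id / transcript_id attributes).
write_sim_gtf <- function(gene_tab, tx_tab, exons, tier, path) {
  in_tier <- vapply(strsplit(tx_tab$tiers, ","),
                    function(t) as.character(tier) %in% t, logical(1))
  tx <- tx_tab[in_tier, , drop = FALSE]
  lines <- character(0)
  attr_str <- function(gid, tid = NULL) {
    if (is.null(tid)) sprintf('gene_id "%s";', gid)
    else sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
  }
  for (gid in unique(tx$gene_id)) {
    g <- gene_tab[gene_tab$gene_id == gid, ]
    gtx <- tx[tx$gene_id == gid, , drop = FALSE]
    span <- range(unlist(lapply(gtx$transcript_id, function(t) exons[[t]])))
    lines <- c(lines, paste(g$chrom, "sim", "gene", span[1], span[2], ".",
                            g$strand, ".", attr_str(gid), sep = "\t"))
    for (tid in gtx$transcript_id) {
      ex <- exons[[tid]]
      lines <- c(lines,
                 paste(g$chrom, "sim", "transcript", min(ex[, 1]),
                       max(ex[, 2]), ".", g$strand, ".", attr_str(gid, tid),
                       sep = "\t"),
                 paste(g$chrom, "sim", "exon", ex[, 1], ex[, 2], ".",
                       g$strand, ".", attr_str(gid, tid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
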