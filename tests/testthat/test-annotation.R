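# Transcript index construction, cascade matching, cryptic classification.

test_that("intron index, first intron and TSS follow transcript orientation", {
  gtf <- write_toy_gtf(list(
    tplus = list(gene = "gP", chrom = "chr1", strand = "+",
                 exons = rbind(c(1, 100), c(201, 300))),
    tminus = list(gene = "gM", chrom = "chr2", strand = "-",
                  exons = rbind(c(1, 100), c(201, 300)))))
  idx <- build_transcript_index(c(tier1 = gtf))
  tp <- idx$transcripts$tplus
  expect_equal(unname(tp$introns), cbind(101, 200), ignore_attr = TRUE)
  expect_equal(tp$tss, 1)
  expect_equal(tp$first_intron, "chr1:+:101:200")
  tm <- idx$transcripts$tminus
  expect_equal(tm$tss, 300)
  expect_equal(tm$first_intron, "chr2:-:101:200")
})

test_that("index keys equal brute-force enumeration of consecutive exon gaps", {
  sim <- shared_sim()
  idx <- build_transcript_index(sim$annotation$paths$gtf)
  # oracle: enumerate gaps directly from the generator's exon matrices
  oracle <- unique(unlist(lapply(
    sim$annotation$transcripts$transcript_id, function(tid) {
      ex <- sim$annotation$exons[[tid]]
      ex <- ex[order(ex[, 1]), , drop = FALSE]   # genomic order
      if (nrow(ex) < 2) return(NULL)
      tx <- sim$annotation$transcripts
      row <- tx[tx$transcript_id == tid, ]
      paste(row$chrom, row$strand, ex[-nrow(ex), 2] + 1,
            ex[-1, 1] - 1, sep = ":")
    })))
  got <- unique(unlist(lapply(idx$tiers, function(env) ls(env))))
  expect_setequal(got, oracle)
})

test_that("GTF errors are caught: missing transcript_id, overlapping exons", {
  bad1 <- tempfile(fileext = ".gtf")
  writeLines('chr1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id "g";', bad1)
  expect_error(build_transcript_index(bad1), "transcript_id")
  bad2 <- write_toy_gtf(list(t1 = list(gene = "g", chrom = "chr1",
                                       strand = "+",
                                       exons = rbind(c(1, 100), c(50, 200)))))
  expect_error(build_transcript_index(bad2), "overlapping exons")
})

test_that("the cascade stops at the first tier with a hit", {
  ex <- rbind(c(1, 100), c(201, 300))
  t1 <- write_toy_gtf(list(both_t1 = list(gene = "g1", chrom = "chr1",
                                          strand = "+", exons = ex)))
  t3 <- write_toy_gtf(list(
    both_t3 = list(gene = "g1", chrom = "chr1", strand = "+", exons = ex),
    only_t3 = list(gene = "g2", chrom = "chr1", strand = "+",
                   exons = rbind(c(401, 500), c(601, 700)))))
  idx <- build_transcript_index(c(tier1 = t1, tier2 = tempfile_gtf_empty(),
                                  tier3 = t3))
  shared <- annotate_junction("chr1", "+", 101, 200, idx)
  expect_equal(shared$source, "tier1")
  expect_equal(shared$transcripts, "both_t1")   # tier3 transcript ignored
  lower <- annotate_junction("chr1", "+", 501, 600, idx)
  expect_equal(lower$source, "tier3")
  none <- annotate_junction("chr1", "+", 901, 950, idx)
  expect_equal(none$source, "cryptic")
  expect_equal(none$transcripts, "")
})

test_that("cascade monotonicity: adding lower tiers never changes tier1 calls", {
  sim <- shared_sim()
  idx_full <- build_transcript_index(sim$annotation$paths$gtf)
  idx_t1 <- build_transcript_index(sim$annotation$paths$gtf[1])
  j <- sim$junctions$junctions[1:80, ]
  full <- annotate_junctions(j, idx_full)
  t1only <- annotate_junctions(j, idx_t1)
  was_t1 <- t1only$source == "tier1"
  expect_equal(full$source[was_t1], t1only$source[was_t1])
  expect_equal(full$transcripts[was_t1], t1only$transcripts[was_t1])
})

test_that("every junction gets exactly one source; cryptic = empty match", {
  sim <- shared_sim()
  idx <- build_transcript_index(sim$annotation$paths$gtf)
  calls <- annotate_junctions(sim$junctions, idx)
  expect_true(all(calls$source %in% c("tier1", "tier2", "tier3", "cryptic")))
  expect_true(all((calls$source == "cryptic") == (calls$transcripts == "")))
})

test_that("generator-injected cryptic junctions are cryptic and canonical", {
  sim <- shared_sim()
  idx <- build_transcript_index(sim$annotation$paths$gtf)
  cj <- sim$truth$cryptic_junctions
  jdf <- sim$junctions$junctions
  calls <- annotate_junctions(jdf[jdf$key %in% cj, ], idx)
  expect_true(all(calls$source == "cryptic"))
  calls <- classify_cryptic(calls, sim$annotation$paths$fasta, idx)
  expect_true(all(calls$motif == "GT-AG"))
  expect_true(all(calls$canonical))
  expect_true(all(calls$cryptic_event == "alt_5prime"))
})

test_that("motifs are reverse-complemented on the minus strand", {
  fa <- tempfile(fileext = ".fa")
  # forward bases: CT at [4,5], AC at [11,12] => intron [4,12] reads GT..AG
  # in minus-strand transcription orientation
  seq <- paste0("AAA", "CT", "GGGGG", "AC", "AAAA")
  writeLines(c(">chrM", seq), fa)
  gtf <- write_toy_gtf(list(t1 = list(gene = "g", chrom = "chrM",
                                      strand = "-",
                                      exons = rbind(c(1, 2), c(15, 16)))))
  idx <- build_transcript_index(gtf)
  call <- annotate_junction("chrM", "-", 4, 12, idx)
  expect_equal(call$source, "cryptic")
  call <- classify_cryptic(call, fa, idx)
  expect_equal(call$motif, "GT-AG")
  expect_true(call$canonical)
  expect_error(classify_cryptic(
    transform(call, end = 999), fa, idx),
    "outside genome bounds")
})

test_that("alt_5prime / alt_3prime use annotated site sharing, strand-aware", {
  gtf <- write_toy_gtf(list(t1 = list(gene = "g", chrom = "chr1",
                                      strand = "+",
                                      exons = rbind(c(1, 100), c(201, 300)))))
  idx <- build_transcript_index(gtf)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", paste(rep("A", 400), collapse = "")), fa)
  # shares only the end (acceptor on +) with intron [101, 200]
  alt5 <- classify_cryptic(annotate_junction("chr1", "+", 150, 200, idx),
                           fa, idx)
  expect_equal(alt5$cryptic_event, "alt_5prime")
  alt3 <- classify_cryptic(annotate_junction("chr1", "+", 101, 180, idx),
                           fa, idx)
  expect_equal(alt3$cryptic_event, "alt_3prime")
  novel <- classify_cryptic(annotate_junction("chr1", "+", 130, 180, idx),
                            fa, idx)
  expect_equal(novel$cryptic_event, "novel_pair")
})

test_that("first-intron flags and per-tier proportions count junctions", {
  # 20 junctions, 12 built as first introns of their transcript
  txs <- list()
  for (i in 1:20) {
    first <- i <= 12
    base <- i * 10000
    exons <- if (first)
      rbind(c(base, base + 99), c(base + 200, base + 299),
            c(base + 400, base + 499))
    else rbind(c(base - 300, base - 201), c(base, base + 99),
               c(base + 200, base + 299))
    txs[[paste0("t", i)]] <- list(gene = paste0("g", i), chrom = "chr1",
                                  strand = "+", exons = exons)
  }
  idx <- build_transcript_index(write_toy_gtf(txs))
  j <- data.frame(chrom = "chr1", strand = "+",
                  start = (1:20) * 10000 + 100, end = (1:20) * 10000 + 199)
  calls <- annotate_junctions(j, idx)
  expect_equal(sum(calls$is_first_intron), 12)
  prop <- first_intron_proportions(calls)
  expect_equal(prop$proportion[prop$source == "tier1"], 0.6)
})

test_that("most upstream TSS is strand-aware", {
  gtf <- write_toy_gtf(list(
    a_plus = list(gene = "gp", chrom = "chr1", strand = "+",
                  exons = rbind(c(1000, 1100), c(2001, 2100))),
    b_plus = list(gene = "gp", chrom = "chr1", strand = "+",
                  exons = rbind(c(1200, 1300), c(2001, 2100))),
    a_minus = list(gene = "gm", chrom = "chr2", strand = "-",
                   exons = rbind(c(101, 200), c(901, 1000))),
    b_minus = list(gene = "gm", chrom = "chr2", strand = "-",
                   exons = rbind(c(101, 200), c(1101, 1200)))))
  idx <- build_transcript_index(gtf)
  expect_equal(most_upstream_tss(c("a_plus", "b_plus"), idx), 1000L)
  expect_equal(most_upstream_tss(c("a_minus", "b_minus"), idx), 1200L)
  # random fixture: equals brute-force min/max by strand
  set.seed(50)
  txs <- lapply(1:10, function(i) {
    s <- i * 3000
    list(gene = "gr", chrom = "chr3", strand = "+",
         exons = rbind(c(s, s + 50), c(90000, 90100)))
  })
  names(txs) <- paste0("r", 1:10)
  idx2 <- build_transcript_index(write_toy_gtf(txs))
  expect_equal(most_upstream_tss(names(txs), idx2),
               as.integer(min(sapply(1:10, function(i) i * 3000))))
})

test_that("unstranded junctions match both strands and flag ties", {
  ex_p <- rbind(c(1, 100), c(201, 300))
  gtf <- write_toy_gtf(list(
    tp = list(gene = "g1", chrom = "chr1", strand = "+", exons = ex_p),
    tm = list(gene = "g2", chrom = "chr1", strand = "-", exons = ex_p)))
  idx <- build_transcript_index(gtf)
  call <- annotate_junction("chr1", ".", 101, 200, idx)
  expect_true(call$ambiguous_strand)
  expect_setequal(strsplit(call$transcripts, ",")[[1]], c("tp", "tm"))
})
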