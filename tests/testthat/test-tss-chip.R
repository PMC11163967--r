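# Promoter windows, signal tracks, window quantification, profiles.

lens <- c(chr1 = 100000L)

bedgraph_gr <- function(starts, ends, scores, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts + 1L, ends))
  gr$score <- scores
  GenomeInfoDb::seqlengths(gr) <- lens[chrom]
  gr
}

test_that("promoter window arithmetic is exact and strand-aware", {
  w <- promoter_windows(data.frame(chrom = "chr1", tss = 10000,
                                   strand = "+", class = "x"))
  expect_equal(c(w$start, w$end), c(8000, 10500))
  wm <- promoter_windows(data.frame(chrom = "chr1", tss = 10000,
                                    strand = "-", class = "x"))
  expect_equal(c(wm$start, wm$end), c(9500, 12000))
  expect_error(promoter_windows(data.frame(chrom = "chr1", tss = 2e5,
                                           strand = "+", class = "x"),
                                chrom_lengths = lens), "beyond")
})

test_that("overlapping windows merge per class; merging is idempotent and
           order-invariant", {
  tss <- data.frame(chrom = "chr1", tss = c(10000, 10400), strand = "+",
                    class = "x")
  w <- promoter_windows(tss)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$start, w$end), c(8000, 10900))   # interval-union oracle
  # different classes never merge
  tss$class <- c("a", "b")
  expect_equal(nrow(promoter_windows(tss)), 2)
  # order invariance
  w2 <- promoter_windows(tss[2:1, ])
  expect_setequal(paste(w2$class, w2$start), c("a 8000", "b 8400"))
  # random instance equals a reduce() oracle on the unmerged windows
  set.seed(80)
  tssr <- data.frame(chrom = "chr1", tss = sample(5000:50000, 40),
                     strand = sample(c("+", "-"), 40, TRUE), class = "x")
  raw <- promoter_windows(tssr, merge = FALSE)
  merged <- promoter_windows(tssr)
  oracle <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(raw$start + 1, raw$end)))
  expect_equal(merged$start, GenomicRanges::start(oracle) - 1)
  expect_equal(merged$end, GenomicRanges::end(oracle))
  expect_equal(promoter_windows(tssr), merged)      # same recipe, same result
})

test_that("log-ratio track: zeros for equal tracks, exact values otherwise", {
  chip <- bedgraph_gr(c(0, 100), c(100, 200), c(2, 2))
  expect_equal(log_ratio_track(chip, chip, lens)$score,
               rep(0, length(log_ratio_track(chip, chip, lens))))
  chip2 <- bedgraph_gr(0, 100, 3)
  input2 <- bedgraph_gr(0, 100, 1)
  lr <- log_ratio_track(chip2, input2, lens, pseudocount = 1)
  expect_equal(lr$score[1], 1)   # log2((3+1)/(1+1))
  expect_error(log_ratio_track(chip2, bedgraph_gr(0, 100, -1), lens),
               "negative input")
})

test_that("log-ratio equals a position-wise oracle on expanded base arrays", {
  set.seed(81)
  small <- c(chrT = 500L)
  mk <- function() {
    b <- sort(sample(0:499, 9))
    bounds <- unique(c(0, b, 500))
    gr <- GenomicRanges::GRanges("chrT",
                                 IRanges::IRanges(head(bounds, -1) + 1,
                                                  tail(bounds, -1)))
    gr$score <- round(runif(length(gr), 0, 5), 2)
    GenomeInfoDb::seqlengths(gr) <- small
    gr
  }
  chip <- mk(); input <- mk()
  lr <- log_ratio_track(chip, input, small)
  # oracle: expand to per-base vectors
  expand <- function(gr) {
    v <- numeric(500)
    for (i in seq_along(gr))
      v[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- gr$score[i]
    v
  }
  oracle <- log2((expand(chip) + 1) / (expand(input) + 1))
  expect_equal(expand(lr), oracle, tolerance = 1e-12)
})

test_that("window means are base-weighted; recipes rebuild around the TSS", {
  const <- bedgraph_gr(0, 100000, 2.5)
  w <- promoter_windows(data.frame(chrom = "chr1", tss = c(10000, 20000),
                                   strand = "+", class = "x"))
  wm <- window_mean_signal(const, w, lens)
  expect_equal(wm$windows$mean_signal, c(2.5, 2.5))

  # hand-built 3-interval track over one window: values 1 (500 bp),
  # 4 (1000 bp), 0 (1000 bp) -> mean = (500*1 + 1000*4) / 2500 = 1.8
  track <- bedgraph_gr(c(8000, 8500), c(8500, 9500), c(1, 4))
  w1 <- data.frame(chrom = "chr1", start = 8000, end = 10500, strand = "+",
                   class = "x", tss = 10000)
  expect_equal(window_mean_signal(track, w1, lens)$windows$mean_signal,
               (500 * 1 + 1000 * 4) / 2500)

  # pparg recipe: +/-250 bp around the TSS regardless of input window shape
  wp <- window_mean_signal(track, w1, lens, flank_spec = "pparg")
  expect_equal(wp$windows$end - wp$windows$start, 500)
  expect_equal(wp$windows$start, 10000 - 250)
  # h3k4me3 recipe is strand-aware: -1 kb/+2 kb
  w1m <- transform(w1, strand = "-")
  wh <- window_mean_signal(track, w1m, lens, flank_spec = "h3k4me3")
  expect_equal(c(wh$windows$start, wh$windows$end),
               c(10000 - 2000, 10000 + 1000))
})

test_that("within-condition scaling matches the closed form and contracts", {
  v <- c(1, 2, 3, 10, 20, 30)
  cond <- rep(c("w", "b"), each = 3)
  s <- scale_within_condition(v, cond)
  expect_equal(s[1:3], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  for (cc in c("w", "b")) {
    expect_equal(mean(s[cond == cc]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((s[cond == cc] - mean(s[cond == cc]))^2)), 1,
                 tolerance = 1e-9)
  }
  # scaling one condition never alters another's values
  v2 <- v; v2[cond == "b"] <- c(100, 200, 300)
  s2 <- scale_within_condition(v2, cond)
  expect_equal(s2[cond == "w"], s[cond == "w"])
  expect_warning(z <- scale_within_condition(c(5, 5, 1, 2), rep(c("a", "b"),
                                                                each = 2)),
                 "zero variance")
  expect_equal(z[1:2], c(0, 0))
  # minmax alternative
  expect_equal(scale_within_condition(v, cond, method = "minmax")[1:3],
               c(0, 0.5, 1))
})

test_that("peak overlap fractions count >= 1 bp intersections per class", {
  windows <- data.frame(chrom = "chr1", start = (0:9) * 1000,
                        end = (0:9) * 1000 + 500, strand = "+",
                        class = "nonsig", tss = (0:9) * 1000 + 250)
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges((0:3) * 1000 + 500, # 1 bp
                                                   (0:3) * 1000 + 600))
  res <- peak_overlap_fraction(windows, peaks)
  expect_equal(res$fraction, 0.4)   # 4 of 10, constructed by hand

  expect_equal(peak_overlap_fraction(windows,
                                     GenomicRanges::GRanges())$fraction, 0)
  all_in <- peak_overlap_fraction(windows,
                                  GenomicRanges::GRanges("chr1",
                                                         IRanges::IRanges(1, 1e4)))
  expect_equal(all_in$fraction, 1)

  # overlapping beige/white windows are pulled into their own class
  w2 <- data.frame(chrom = "chr1",
                   start = c(1000, 1200, 5000, 9000),
                   end = c(1500, 1700, 5500, 9500), strand = "+",
                   class = c("beige", "white", "beige", "white"),
                   tss = c(1250, 1450, 5250, 9250))
  res2 <- peak_overlap_fraction(w2, peaks)
  expect_setequal(res2$class, c("beige_white_overlap", "beige", "white"))
  expect_equal(res2$n[res2$class == "beige_white_overlap"], 2)
})

test_that("profile matrices bin, flip and pad correctly", {
  const <- bedgraph_gr(0, 100000, 1.5)
  tss <- data.frame(chrom = "chr1", tss = c(10000, 50000), strand = "+")
  pr <- profile_matrix(const, tss, lens, flank = 2000, bin = 50)
  expect_equal(dim(pr$matrix), c(2, 80))
  expect_equal(unname(pr$profile), rep(1.5, 80))

  # asymmetric step track: minus-strand profile equals the mirrored plus one
  step <- bedgraph_gr(c(0, 10000), c(10000, 100000), c(1, 3))
  plus <- profile_matrix(step, data.frame(chrom = "chr1", tss = 10000,
                                          strand = "+"), lens)
  minus <- profile_matrix(step, data.frame(chrom = "chr1", tss = 10000,
                                           strand = "-"), lens)
  expect_equal(minus$profile, rev(plus$profile))

  # single TSS, hand-built track, hand binning
  hand <- bedgraph_gr(c(9900, 10000), c(10000, 10100), c(2, 4))
  p1 <- profile_matrix(hand, data.frame(chrom = "chr1", tss = 10000,
                                        strand = "+"), lens,
                       flank = 100, bin = 50)
  expect_equal(unname(p1$matrix[1, ]), c(2, 2, 4, 4))

  # TSS at the chromosome edge: padded with NA, excluded from column means
  edge <- profile_matrix(const, data.frame(chrom = "chr1",
                                           tss = c(100, 50000),
                                           strand = "+"), lens)
  expect_true(all(is.na(edge$matrix[1, ])))
  expect_equal(unname(edge$profile), rep(1.5, 80))
})
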