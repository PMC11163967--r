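# Junction parsing, filtering and splice-site clustering.

design36 <- tiny_design()

write_bed12_line <- function(path, chrom = "chr1", chrom_start = 100,
                             count = 5, strand = "+", sizes = c(8, 10),
                             starts = c(0, 60), append = FALSE) {
  chrom_end <- chrom_start + starts[2] + sizes[2]
  line <- sprintf("%s\t%d\t%d\tJUNC\t%d\t%s\t%d\t%d\t255,0,0\t2\t%s\t%s",
                  chrom, chrom_start, chrom_end, count, strand, chrom_start,
                  chrom_end, paste(sizes, collapse = ","),
                  paste(starts, collapse = ","))
  cat(line, "\n", sep = "", file = path, append = append)
}

test_that("BED12 block arithmetic converts to 1-based inclusive introns", {
  # oracle, worked from the BED spec: blocks [100,108) and [160,170) =>
  # last exonic base 108 (1-based), intron = [109, 160]
  d <- design36[1, , drop = FALSE]
  d$donor <- factor(d$donor); d$condition <- factor(d$condition, "white")
  path <- tempfile(fileext = ".bed")
  write_bed12_line(path)
  jt <- read_junctions(setNames(path, d$library_id), d)
  expect_equal(jt$junctions$start, 109)
  expect_equal(jt$junctions$end, 160)
  expect_equal(jt$junctions$anchor, 8L)
  expect_equal(unname(jt$counts[1, 1]), 5L)
})

test_that("duplicate junctions within a library are summed; empty files ok", {
  d <- design36[1, , drop = FALSE]
  d$donor <- factor(d$donor); d$condition <- factor(d$condition, "white")
  path <- tempfile(fileext = ".bed")
  write_bed12_line(path, count = 3)
  write_bed12_line(path, count = 4, append = TRUE)
  jt <- read_junctions(setNames(path, d$library_id), d)
  expect_equal(nrow(jt$junctions), 1)
  expect_equal(unname(jt$counts[1, 1]), 7L)

  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  jt0 <- read_junctions(setNames(empty, d$library_id), d)
  expect_equal(nrow(jt0$junctions), 0)
})

test_that("malformed lines and unknown libraries raise informative errors", {
  d <- design36[1, , drop = FALSE]
  d$donor <- factor(d$donor); d$condition <- factor(d$condition, "white")
  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\tnot_a_number", bad)
  expect_error(read_junctions(setNames(bad, d$library_id), d),
               "malformed BED12.*:1")
  ok <- tempfile(fileext = ".bed")
  write_bed12_line(ok)
  expect_error(read_junctions(setNames(ok, "nonexistent_lib"), d),
               "unknown library_id")
})

test_that("BED12 writer and reader round-trip the junction table", {
  sim <- shared_sim()
  jt <- sim$junctions
  keep <- order(jt$junctions$key)[1:40]
  small <- junction_table(jt$junctions[keep, ], jt$counts[keep, , drop = FALSE])
  dir <- tempfile()
  paths <- write_junctions_bed12(small, dir)
  back <- read_junctions(paths, sim$design)
  ord <- match(small$junctions$key, back$junctions$key)
  expect_equal(back$junctions$start[ord], small$junctions$start)
  expect_equal(back$junctions$end[ord], small$junctions$end)
  expect_equal(unname(back$counts[ord, colnames(small$counts)]),
               unname(small$counts))
})

test_that("anchor and intron length filters use inclusive bounds", {
  counts <- matrix(10L, 4, 2, dimnames = list(NULL, c("L1", "L2")))
  jt <- mk_junction_table("chr1", start = c(100, 100, 100, 100),
                          end = c(118, 119, 100 + 1e6 - 1, 100 + 1e6),
                          strand = "+", anchor = c(10, 10, 10, 10), counts)
  f <- filter_junctions(jt)     # lengths 19, 20, 1e6, 1e6 + 1
  expect_equal(f$junctions$end, c(119, 100 + 1e6 - 1))

  jt2 <- mk_junction_table("chr1", start = c(100, 200), end = c(199, 299),
                           strand = "+", anchor = c(5, 6),
                           matrix(1L, 2, 2, dimnames = list(NULL, c("L1", "L2"))))
  f2 <- filter_junctions(jt2)
  expect_equal(f2$junctions$anchor, 6)

  expect_equal(nrow(filter_junctions(f2)$junctions), nrow(f2$junctions)) # idempotent
  empty <- filter_junctions(mk_junction_table(character(0), integer(0),
                                              integer(0), character(0),
                                              integer(0),
                                              matrix(0L, 0, 1,
                                                     dimnames = list(NULL, "L1"))))
  expect_equal(nrow(empty$junctions), 0)
})

test_that("introns sharing a splice site cluster together", {
  counts <- matrix(40L, 3, 2, dimnames = list(NULL, c("L1", "L2")))
  jt <- mk_junction_table("chr1", start = c(100, 100, 500),
                          end = c(200, 300, 600), strand = "+", anchor = 10,
                          counts)
  cl <- cluster_introns(jt, min_reads_per_library = 30)
  sizes <- sort(unname(vapply(cl, function(c) nrow(c$counts), integer(1))))
  expect_equal(sizes, c(1L, 2L))
})

test_that("per-library support rule is an every-library requirement", {
  base <- matrix(c(15L, 15L, 15L, 15L), 2, 2,
                 dimnames = list(NULL, c("L1", "L2")))   # totals 30, 30
  jt <- mk_junction_table("chr1", c(100, 100), c(200, 300), "+", 10, base)
  expect_length(cluster_introns(jt, 30), 1)
  base[1, 2] <- 14L                                      # one library at 29
  jt29 <- mk_junction_table("chr1", c(100, 100), c(200, 300), "+", 10, base)
  expect_length(cluster_introns(jt29, 30), 0)
  expect_length(cluster_introns(jt29, 30, support_mode = "pooled"), 1)
})

test_that("clustering equals a brute-force connected-components oracle", {
  set.seed(11)
  n <- 50
  grid <- expand.grid(s = (1:20) * 100, k = 1:15)
  pick <- grid[sample(nrow(grid), n), ]      # distinct (start, end) pairs
  starts <- pick$s
  ends <- starts + pick$k * 50
  counts <- matrix(50L, n, 2, dimnames = list(NULL, c("L1", "L2")))
  jt <- mk_junction_table("chr1", starts, ends, "+", 10, counts)
  cl <- cluster_introns(jt, min_reads_per_library = 1, min_fraction = 0)

  # oracle: transitive closure over the shared-site relation
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    starts[i] == starts[j] | ends[i] == ends[j])
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  oracle <- unique(apply(reach, 1, function(r) paste(sort(which(r)),
                                                     collapse = ",")))
  key <- jt$junctions$key
  got <- sort(vapply(cl, function(c)
    paste(sort(match(c$junctions$key, key)), collapse = ","), character(1)))
  expect_setequal(got, oracle)
})

test_that("cluster membership is invariant to record and library order", {
  set.seed(12)
  n <- 30
  starts <- sample(1:10, n, replace = TRUE) * 100
  ends <- starts + sample(1:10, n, replace = TRUE) * 30
  counts <- matrix(rpois(2 * n, 40), n, 2,
                   dimnames = list(NULL, c("L1", "L2")))
  jt <- mk_junction_table("chr1", starts, ends, "+", 10, counts)
  perm <- sample(n)
  jt2 <- mk_junction_table("chr1", starts[perm], ends[perm], "+", 10,
                           counts[perm, c("L2", "L1")])
  sig <- function(cl) sort(vapply(cl, function(c)
    paste(sort(c$junctions$key), collapse = "|"), character(1)))
  expect_equal(sig(cluster_introns(jt, 1, 0)), sig(cluster_introns(jt2, 1, 0)))
})

test_that("clustering neither creates nor loses retained reads", {
  sim <- shared_sim()
  jt <- filter_junctions(sim$junctions)
  cl <- cluster_introns(jt, min_reads_per_library = 0, min_fraction = 0)
  expect_equal(sum(vapply(cl, function(c) sum(c$counts), numeric(1))),
               sum(jt$counts))
})

test_that("prefilters apply the printed thresholds at their boundaries", {
  design <- design36
  # intron detected in exactly 13 vs 14 libraries
  c1 <- matrix(0L, 2, 36, dimnames = list(NULL, design$library_id))
  c1[1, 1:14] <- 50L
  c1[2, ] <- 50L
  cl14 <- mk_cluster(c1, "c14")
  c2 <- c1; c2[1, 14] <- 0L
  cl13 <- mk_cluster(c2, "c13")
  out <- prefilter_clusters(list(cl14, cl13), design,
                            min_libs_per_condition = 12)
  expect_true("c14" %in% names(out))
  # c13 keeps only one intron after detection filter -> dropped entirely
  expect_false("c13" %in% names(out))
  expect_equal(nrow(out$c14$counts), 2)

  # 11 supported libraries in one condition vs 12
  beige_libs <- design$library_id[design$condition == "beige"]
  c3 <- matrix(2L, 2, 36, dimnames = list(NULL, design$library_id))
  c3[, design$condition == "white"] <- 20L
  c3[, beige_libs[1:12]] <- 10L         # cluster totals 20 in 12 beige libs
  cl12 <- mk_cluster(c3, "c12")
  c4 <- c3; c4[, beige_libs[12]] <- 2L  # now only 11 beige libs reach 20
  cl11 <- mk_cluster(c4, "c11")
  out2 <- prefilter_clusters(list(cl12, cl11), design, min_libs_detected = 1)
  expect_true("c12" %in% names(out2))
  expect_false("c11" %in% names(out2))

  # all-zero cluster dropped; thresholds above design size rejected
  cl0 <- mk_cluster(matrix(0L, 2, 36,
                           dimnames = list(NULL, design$library_id)), "c0")
  expect_length(prefilter_clusters(list(cl0), design), 0)
  expect_error(prefilter_clusters(list(cl14), design, min_libs_detected = 37),
               "exceed")
})
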