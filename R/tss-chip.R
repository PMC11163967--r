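# Promoter-window construction and ChIP signal quantification.
# All window/peak arithmetic is 0-based half-open (BED-native); signal tracks
# use bedGraph semantics (sorted non-overlapping intervals, missing = 0).

#' Read a bedGraph signal track
#' @param path bedGraph path.
#' @param chrom_lengths Optional named chromosome lengths (sets seqlengths).
#' @return GRanges with a `score` column.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(chrom_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
    GenomeInfoDb::seqlengths(gr) <- chrom_lengths
  }
  gr
}

#' Read peak calls (BED or narrowPeak)
#' @param path BED3+/narrowPeak path.
#' @return GRanges of peak intervals.
#' @export
read_peaks <- function(path) {
  first <- readLines(path, n = 1)
  n_fields <- if (length(first) == 0) 0 else length(strsplit(first, "\t")[[1]])
  if (n_fields == 10) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric", qValue = "numeric",
                                      peak = "integer"))
  } else if (n_fields == 0) {
    GenomicRanges::GRanges()
  } else {
    rtracklayer::import(path, format = "BED")
  }
}

# Position -> value coverage as an RleList; missing positions are 0.
track_rle <- function(track, chrom_lengths) {
  if (is.character(track)) track <- read_bedgraph(track, chrom_lengths)
  gr <- track
  GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                       names(chrom_lengths))
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  GenomicRanges::coverage(gr, weight = "score")
}

#' Strand-aware promoter windows around TSSs, merged per class
#'
#' Plus-strand windows span `[tss - upstream, tss + downstream)`; minus-strand
#' windows are mirrored (`[tss - downstream, tss + upstream)`), keeping the
#' `upstream` extent on the transcription-upstream side. Windows are clipped
#' at chromosome bounds and, when `merge = TRUE`, overlapping windows of the
#' same class are unioned.
#'
#' @param tss data.frame `chrom tss strand class` (class optional; defaults
#'   to a single class).
#' @param upstream,downstream Window extents in bp (default -2 kb / +0.5 kb).
#' @param merge Union overlapping windows within each class.
#' @param chrom_lengths Optional named lengths for clipping/validation.
#' @return data.frame `chrom start end strand class` (0-based half-open).
#' @export
promoter_windows <- function(tss, upstream = 2000, downstream = 500,
                             merge = TRUE, chrom_lengths = NULL) {
  if (is.null(tss$class)) tss$class <- "all"
  if (!is.null(chrom_lengths)) {
    bad <- tss$tss > chrom_lengths[tss$chrom] | tss$tss < 1
    if (any(bad))
      stop("TSS beyond chromosome length: ",
           paste(utils::head(tss$tss[bad]), collapse = ", "))
  }
  minus <- tss$strand == "-"
  start <- ifelse(minus, tss$tss - downstream, tss$tss - upstream)
  end <- ifelse(minus, tss$tss + upstream, tss$tss + downstream)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) end <- pmin(end, chrom_lengths[tss$chrom])
  w <- data.frame(chrom = tss$chrom, start = start, end = end,
                  strand = tss$strand, class = tss$class, tss = tss$tss)
  if (!merge) return(w)
  out <- list()
  for (cls in unique(w$class)) {
    sub <- w[w$class == cls, , drop = FALSE]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$start + 1L, sub$end)))
    hit <- GenomicRanges::findOverlaps(
      gr, GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$tss, sub$tss)),
      select = "first")
    out[[cls]] <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = sub$strand[hit],
      class = cls,
      tss = sub$tss[hit])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Log2 ratio track of ChIP over input
#'
#' Computes `log2((chip + pseudocount) / (input + pseudocount))` position-wise
#' and re-segments the result into minimal bedGraph intervals.
#'
#' @param chip,input GRanges signal tracks (bedGraph semantics) or paths.
#' @param chrom_lengths Named chromosome lengths.
#' @param pseudocount Added to both tracks (bounds the ratio on empty bins).
#' @return GRanges with the log-ratio in `score`.
#' @export
log_ratio_track <- function(chip, input, chrom_lengths, pseudocount = 1) {
  chip_r <- track_rle(chip, chrom_lengths)
  input_r <- track_rle(input, chrom_lengths)
  if (any(vapply(input_r, function(r) min(S4Vectors::runValue(r)) < 0,
                 logical(1))))
    stop("negative input values")
  ratio <- log2((chip_r + pseudocount) / (input_r + pseudocount))
  gr <- GenomicRanges::GRanges(ratio)
  gr[!is.na(gr$score)]
}

# Named flank recipes (strand-aware upstream/downstream around the TSS).
flank_recipes <- list(
  h3k4me3 = c(upstream = 1000, downstream = 2000),
  pparg = c(upstream = 250, downstream = 250),
  med1 = c(upstream = 500, downstream = 500)
)

#' Mean signal per window with per-class summaries
#'
#' Computes the base-weighted mean of a signal track over each window.
#' `flank_spec` may name a preset recipe rebuilt around each window's TSS
#' (`"h3k4me3"`: -1 kb/+2 kb strand-aware; `"pparg"`: +/-250 bp; `"med1"`:
#' +/-500 bp), give explicit `c(upstream =, downstream =)` bounds, or be
#' `NULL` to use the windows as supplied.
#'
#' @param track Signal GRanges (or bedGraph path).
#' @param windows data.frame from [promoter_windows()].
#' @param chrom_lengths Named chromosome lengths.
#' @param flank_spec Recipe name, numeric bounds, or NULL.
#' @return List: `windows` (with `mean_signal` and `zero_coverage` flag) and
#'   `class_summary` (n, mean of window means per class).
#' @export
window_mean_signal <- function(track, windows, chrom_lengths,
                               flank_spec = NULL) {
  if (!is.null(flank_spec)) {
    spec <- if (is.character(flank_spec)) {
      if (!flank_spec %in% names(flank_recipes))
        stop("unknown flank recipe: ", flank_spec)
      flank_recipes[[flank_spec]]
    } else flank_spec
    windows <- promoter_windows(
      data.frame(chrom = windows$chrom, tss = windows$tss,
                 strand = windows$strand, class = windows$class),
      upstream = spec[["upstream"]], downstream = spec[["downstream"]],
      merge = FALSE, chrom_lengths = chrom_lengths)
  }
  rle <- track_rle(track, chrom_lengths)
  means <- numeric(nrow(windows))
  zero <- logical(nrow(windows))
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    s <- windows$start[idx] + 1L
    e <- windows$end[idx]
    bad <- e < s
    v <- IRanges::Views(rle[[ch]], pmin(s, e), pmax(e, s))
    m <- IRanges::viewMeans(v)
    m[bad] <- 0
    zero[idx] <- bad
    means[idx] <- m
  }
  windows$mean_signal <- means
  windows$zero_coverage <- zero
  summ <- do.call(rbind, lapply(split(windows, windows$class), function(d)
    data.frame(class = d$class[1], n = nrow(d),
               mean = mean(d$mean_signal), median = median(d$mean_signal))))
  rownames(summ) <- NULL
  list(windows = windows, class_summary = summ)
}

#' Scale values within each condition
#'
#' Z-scores values separately per condition using the population standard
#' deviation (mean 0, population s.d. 1 within each condition);
#' `method = "minmax"` rescales to [0, 1] instead. Zero-variance conditions
#' yield all zeros with a warning.
#'
#' @param values Numeric vector.
#' @param condition Factor/character of the same length.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return Scaled numeric vector.
#' @export
scale_within_condition <- function(values, condition,
                                   method = c("zscore", "minmax")) {
  method <- match.arg(method)
  out <- numeric(length(values))
  for (cond in unique(condition)) {
    idx <- condition == cond
    v <- values[idx]
    s <- sqrt(mean((v - mean(v))^2))
    if (length(v) < 2 || s == 0) {
      warning("zero variance in condition ", cond, "; scaled to zeros")
      out[idx] <- 0
      next
    }
    out[idx] <- if (method == "zscore") (v - mean(v)) / s
    else (v - min(v)) / (max(v) - min(v))
  }
  out
}

#' Fraction of promoter windows intersecting peaks, per class
#'
#' A window intersects on >= 1 bp of overlap. Windows whose intervals overlap
#' between the two enriched classes are reported separately as
#' `<class1>_<class2>_overlap` and removed from their own classes.
#'
#' @param windows data.frame from [promoter_windows()] (0-based half-open).
#' @param peaks GRanges of peaks (or a BED path).
#' @return data.frame `class n n_overlapping fraction`.
#' @export
peak_overlap_fraction <- function(windows, peaks) {
  if (is.character(peaks)) peaks <- read_peaks(peaks)
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  cls <- as.character(windows$class)
  enr <- setdiff(unique(cls), "nonsig")
  if (length(enr) == 2) {
    a <- which(cls == enr[1]); b <- which(cls == enr[2])
    ov <- GenomicRanges::findOverlaps(wgr[a], wgr[b])
    shared <- union(a[S4Vectors::queryHits(ov)], b[S4Vectors::subjectHits(ov)])
    if (length(shared) > 0)
      cls[shared] <- paste0(sort(enr)[1], "_", sort(enr)[2], "_overlap")
  }
  hit <- GenomicRanges::countOverlaps(wgr, peaks) > 0
  res <- do.call(rbind, lapply(split(seq_along(cls), cls), function(idx)
    data.frame(class = cls[idx[1]], n = length(idx),
               n_overlapping = sum(hit[idx]),
               fraction = mean(hit[idx]))))
  rownames(res) <- NULL
  res
}

#' TSS-anchored signal profile matrix
#'
#' Tiles `bin`-bp bins across `[tss - flank, tss + flank)`, flipping bin
#' order on the minus strand so bin 1 is always 5' of the TSS. Each cell is
#' the base-weighted mean of the track in that bin; TSSs too close to a
#' chromosome edge are padded with NA and excluded from the column means.
#'
#' @param track Signal GRanges or bedGraph path.
#' @param tss data.frame `chrom tss strand`.
#' @param chrom_lengths Named chromosome lengths.
#' @param flank Half-width of the profiled region (bp).
#' @param bin Bin width (bp); must divide `2 * flank`.
#' @return List: `matrix` (TSS x bins), `profile` (column means),
#'   `positions` (bin centers relative to the TSS).
#' @export
profile_matrix <- function(track, tss, chrom_lengths, flank = 2000,
                           bin = 50) {
  n_bins <- as.integer(2 * flank / bin)
  if (n_bins * bin != 2 * flank) stop("bin must divide 2 * flank")
  rle <- track_rle(track, chrom_lengths)
  mat <- matrix(NA_real_, nrow(tss), n_bins)
  for (i in seq_len(nrow(tss))) {
    ch <- tss$chrom[i]
    w_start <- tss$tss[i] - flank          # 0-based half-open window
    w_end <- tss$tss[i] + flank
    if (w_start < 0 || w_end > chrom_lengths[[ch]]) next
    starts <- w_start + bin * (seq_len(n_bins) - 1) + 1L
    v <- IRanges::Views(rle[[ch]], starts, starts + bin - 1L)
    m <- IRanges::viewMeans(v)
    if (tss$strand[i] == "-") m <- rev(m)
    mat[i, ] <- m
  }
  list(matrix = mat, profile = colMeans(mat, na.rm = TRUE),
       positions = -flank + bin * (seq_len(n_bins) - 1) + bin / 2)
}
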