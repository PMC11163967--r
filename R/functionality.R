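# TRIFID-based isoform functionality scoring of junctions.

#' Read a TRIFID score table
#' @param path TSV with header `transcript_id trifid_score` (scores in [0,1]).
#' @return Named numeric vector of scores.
#' @export
read_trifid <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "trifid_score") %in% names(d)))
    stop("TRIFID table must have columns transcript_id, trifid_score")
  if (any(d$trifid_score < 0 | d$trifid_score > 1))
    stop("TRIFID scores outside [0, 1]")
  setNames(d$trifid_score, d$transcript_id)
}

#' Score junctions by averaged TRIFID over matched transcripts
#'
#' The score of a junction is the mean TRIFID score over its matched
#' transcripts that are present in the score table; matched-but-unscored
#' transcripts are excluded from the mean. A junction with zero scored
#' transcripts -- including every cryptic junction -- receives the sentinel
#' -0.1.
#'
#' @param calls Annotation calls from [annotate_junctions()] (or a single
#'   comma-separated transcript string for `score_junction`).
#' @param trifid Named score vector from [read_trifid()] (values in [0,1]).
#' @return `score_junctions`: `calls` with `trifid` and `n_scored_transcripts`
#'   columns. `score_junction`: a single score.
#' @export
score_junctions <- function(calls, trifid) {
  if (any(trifid < 0 | trifid > 1)) stop("TRIFID scores outside [0, 1]")
  scored <- lapply(strsplit(calls$transcripts, ","), function(tx) {
    tx <- tx[nzchar(tx)]
    trifid[intersect(tx, names(trifid))]
  })
  calls$n_scored_transcripts <- lengths(scored)
  calls$trifid <- vapply(scored, function(s)
    if (length(s) == 0) -0.1 else mean(s), numeric(1))
  calls
}

#' @rdname score_junctions
#' @param transcripts Character vector of matched transcript ids (empty for a
#'   cryptic junction).
#' @export
score_junction <- function(transcripts, trifid) {
  score_junctions(data.frame(transcripts = paste(transcripts, collapse = ",")),
                  trifid)$trifid
}

#' Per-cluster TRIFID difference between the top two intron-excision events
#'
#' For every cluster with adjusted p below `alpha` and at least one junction
#' with `|dPSI| > dpsi_threshold`, the two dominant junctions are selected
#' (by pooled read count by default, or by `|dPSI|`) and the TRIFID
#' difference is `score(junction with larger dPSI) - score(junction with
#' smaller dPSI)`, so a positive value means the isoform favoured in the
#' second condition (beige) is predicted more functional.
#'
#' @param result A `splicing_result`.
#' @param scores Scored calls from [score_junctions()].
#' @param alpha,dpsi_threshold Eligibility thresholds.
#' @param rank_by `"reads"` (pooled read count, default) or `"abs_dpsi"`.
#' @return data.frame `cluster_id delta_trifid junction_hi junction_lo
#'   gene_id` -- `junction_hi` is the junction with the larger dPSI.
#' @export
cluster_delta_trifid <- function(result, scores, alpha = 0.05,
                                 dpsi_threshold = 0.1,
                                 rank_by = c("reads", "abs_dpsi")) {
  rank_by <- match.arg(rank_by)
  t <- result$table
  t$trifid <- scores$trifid[match(t$key, scores$key)]
  t$gene_id <- scores$gene_id[match(t$key, scores$key)]
  eligible <- unique(t$cluster_id[!is.na(t$cluster_q) &
                                    t$cluster_q < alpha &
                                    !is.na(t$dPSI) &
                                    abs(t$dPSI) > dpsi_threshold])
  out <- list()
  for (cid in eligible) {
    sub <- t[t$cluster_id == cid & !is.na(t$trifid) & !is.na(t$dPSI), ,
             drop = FALSE]
    if (nrow(sub) < 2) {
      message("cluster ", cid, " skipped: fewer than two scorable junctions")
      next
    }
    ord <- if (rank_by == "reads") order(-sub$pooled_reads)
    else order(-abs(sub$dPSI))
    top2 <- sub[ord[1:2], ]
    hi <- which.max(top2$dPSI)
    lo <- 3 - hi
    out[[cid]] <- data.frame(
      cluster_id = cid,
      delta_trifid = top2$trifid[hi] - top2$trifid[lo],
      junction_hi = top2$key[hi], junction_lo = top2$key[lo],
      gene_id = top2$gene_id[hi] %||% NA_character_)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(cluster_id = character(0), delta_trifid = numeric(0),
               junction_hi = character(0), junction_lo = character(0),
               gene_id = character(0))
  rownames(res) <- NULL
  res
}

#' Four-group TRIFID score comparison with control subsampling
#'
#' Compares TRIFID scores between condition-enriched junctions and two
#' control groups -- low-differential junctions from significant clusters and
#' non-significant junctions -- each subsampled to `n_subsample` (all members
#' are used, with a warning, when a control group is smaller). A
#' Kruskal-Wallis test across groups is followed by pairwise t-tests with
#' Holm adjustment.
#'
#' @param result A `splicing_result`.
#' @param scores Scored calls from [score_junctions()].
#' @param n_subsample Control group size (default 280).
#' @param seed Seed for the subsampling.
#' @return List: `groups` (junction, group, trifid), `group_stats`
#'   (n, mean, median per group), `kruskal_p`, `pairwise_p` (Holm-adjusted
#'   matrix).
#' @export
trifid_group_comparison <- function(result, scores, n_subsample = 280, seed) {
  assert_seed(seed)
  set.seed(stream_seed(seed, "trifid_groups"))
  t <- result$table
  t$trifid <- scores$trifid[match(t$key, scores$key)]
  t <- t[!is.na(t$trifid), , drop = FALSE]
  enriched <- grepl("_enriched$", t$class)
  if (!any(enriched)) {
    message("no enriched junctions; group comparison skipped")
    return(NULL)
  }
  take <- function(d) {
    if (nrow(d) > n_subsample) d[sample.int(nrow(d), n_subsample), ,
                                 drop = FALSE]
    else {
      if (nrow(d) < n_subsample)
        warning(sprintf(
          "group %s has %d < %d members; using all", d$class[1] %||% "",
          nrow(d), n_subsample), call. = FALSE)
      d
    }
  }
  parts <- c(
    split(t[enriched, , drop = FALSE], t$class[enriched]),
    list(low_differential = take(t[t$class == "low_differential", ,
                                   drop = FALSE]),
         non_significant = take(t[t$class == "non_significant", ,
                                  drop = FALSE])))
  groups <- do.call(rbind, lapply(names(parts), function(g) {
    d <- parts[[g]]
    if (nrow(d) == 0) return(NULL)
    data.frame(junction = d$key, group = g, trifid = d$trifid)
  }))
  groups$group <- factor(groups$group)
  kw <- kruskal.test(trifid ~ group, data = groups)
  pw <- pairwise.t.test(groups$trifid, groups$group,
                        p.adjust.method = "holm")
  stats <- do.call(rbind, lapply(split(groups, groups$group), function(d)
    data.frame(group = d$group[1], n = nrow(d), mean = mean(d$trifid),
               median = median(d$trifid))))
  rownames(stats) <- NULL
  list(groups = groups, group_stats = stats,
       kruskal_p = kw$p.value, pairwise_p = pw$p.value)
}
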