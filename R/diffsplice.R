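#' Differential intron excision across clusters
#'
#' Fits the donor-only (null) and condition (alternative) Dirichlet-
#' multinomial models to every cluster, tests each cluster by likelihood
#' ratio, adjusts cluster p-values for multiple testing
#' (Benjamini-Hochberg by default) and classifies every junction:
#' enriched toward the second condition if `dPSI > dpsi_threshold` in a
#' significant cluster (`q < alpha`), enriched toward the first if
#' `dPSI < -dpsi_threshold`, `low_differential` if `|dPSI| <= dpsi_threshold`
#' inside a significant cluster, and `non_significant` otherwise. The
#' threshold is strict (`>`), so `|dPSI|` exactly at the threshold is
#' low-differential. Clusters whose fits fail to converge are reported with
#' `p = NA` and excluded from the adjustment family.
#'
#' @param clusters List of prefiltered `intron_cluster` objects.
#' @param design A `study_design`.
#' @param alpha Significance level on adjusted cluster p-values.
#' @param dpsi_threshold Effect-size threshold on |delta PSI|.
#' @param p_adjust_method Method passed to [stats::p.adjust()].
#' @param keep_fits Retain the per-cluster `dm_fit` objects.
#' @return An object of class `splicing_result`: `$table` has one row per
#'   junction (`cluster_id chrom strand intron_start intron_end dPSI
#'   pooled_reads cluster_p cluster_q class`), `$cluster_stats` one row per
#'   cluster.
#' @export
differential_splicing <- function(clusters, design, alpha = 0.05,
                                  dpsi_threshold = 0.1,
                                  p_adjust_method = "BH",
                                  keep_fits = FALSE) {
  conds <- levels(design$condition)
  if (length(clusters) == 0) {
    warning("no clusters to test")
    empty <- data.frame(cluster_id = character(0), chrom = character(0),
                        strand = character(0), intron_start = integer(0),
                        intron_end = integer(0), key = character(0),
                        dPSI = numeric(0), pooled_reads = numeric(0),
                        cluster_p = numeric(0), cluster_q = numeric(0),
                        class = character(0))
    return(structure(list(table = empty,
                          cluster_stats = data.frame(),
                          alpha = alpha, dpsi_threshold = dpsi_threshold,
                          conditions = conds, fits = NULL),
                     class = "splicing_result"))
  }

  stats_rows <- vector("list", length(clusters))
  junc_rows <- vector("list", length(clusters))
  fits <- if (keep_fits) vector("list", length(clusters)) else NULL
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    fit0 <- fit_cluster_dm(cl, design, include_condition = FALSE)
    fit1 <- fit_cluster_dm(cl, design, include_condition = TRUE)
    lrt <- lrt_cluster(fit0, fit1)
    dpsi <- effect_sizes(fit1)
    stats_rows[[i]] <- data.frame(
      cluster_id = cl$cluster_id, n_introns = fit1$J,
      stat = lrt$stat, df = lrt$df, p = lrt$p,
      converged = fit0$converged && fit1$converged)
    junc_rows[[i]] <- data.frame(
      cluster_id = cl$cluster_id,
      chrom = cl$junctions$chrom, strand = cl$junctions$strand,
      intron_start = cl$junctions$start, intron_end = cl$junctions$end,
      key = cl$junctions$key,
      dPSI = unname(dpsi),
      pooled_reads = unname(rowSums(cl$counts)))
    if (keep_fits) fits[[i]] <- list(null = fit0, alt = fit1)
  }
  cluster_stats <- do.call(rbind, stats_rows)
  cluster_stats$q <- NA_real_
  tested <- !is.na(cluster_stats$p)
  cluster_stats$q[tested] <- p.adjust(cluster_stats$p[tested],
                                      method = p_adjust_method)

  table <- do.call(rbind, junc_rows)
  idx <- match(table$cluster_id, cluster_stats$cluster_id)
  table$cluster_p <- cluster_stats$p[idx]
  table$cluster_q <- cluster_stats$q[idx]
  sig <- !is.na(table$cluster_q) & table$cluster_q < alpha
  table$class <- "non_significant"
  table$class[sig & !is.na(table$dPSI) & abs(table$dPSI) <= dpsi_threshold] <-
    "low_differential"
  table$class[sig & !is.na(table$dPSI) & table$dPSI > dpsi_threshold] <-
    paste0(conds[2], "_enriched")
  table$class[sig & !is.na(table$dPSI) & table$dPSI < -dpsi_threshold] <-
    paste0(conds[1], "_enriched")
  rownames(table) <- NULL

  structure(list(table = table, cluster_stats = cluster_stats,
                 alpha = alpha, dpsi_threshold = dpsi_threshold,
                 conditions = conds,
                 fits = if (keep_fits) setNames(fits, names(clusters))),
            class = "splicing_result")
}

#' @export
print.splicing_result <- function(x, ...) {
  n_cl <- nrow(x$cluster_stats)
  n_sig <- sum(x$cluster_stats$q < x$alpha, na.rm = TRUE)
  cat(sprintf(
    "splicing_result: %d clusters tested, %d significant at q < %g\n",
    n_cl, n_sig, x$alpha))
  if (nrow(x$table) > 0) {
    tab <- table(x$table$class)
    cat("junction classes:\n")
    for (cls in names(tab)) cat(sprintf("  %-20s %d\n", cls, tab[[cls]]))
  }
  invisible(x)
}

#' @export
summary.splicing_result <- function(object, ...) {
  list(n_clusters = nrow(object$cluster_stats),
       n_significant = sum(object$cluster_stats$q < object$alpha,
                           na.rm = TRUE),
       n_failed = sum(!object$cluster_stats$converged),
       classes = table(object$table$class),
       alpha = object$alpha, dpsi_threshold = object$dpsi_threshold)
}

#' Volcano-style plot of junction effect sizes
#' @param x A `splicing_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.splicing_result <- function(x, ...) {
  t <- x$table[!is.na(x$table$dPSI) & !is.na(x$table$cluster_q), ]
  cols <- c(non_significant = "grey60", low_differential = "grey30")
  cols[paste0(x$conditions[1], "_enriched")] <- "steelblue3"
  cols[paste0(x$conditions[2], "_enriched")] <- "firebrick3"
  graphics::plot(t$dPSI, -log10(pmax(t$cluster_q, 1e-300)),
                 col = cols[t$class], pch = 16, cex = 0.6,
                 xlab = expression(Delta * "PSI"),
                 ylab = expression(-log[10] ~ "adjusted p"), ...)
  graphics::abline(v = c(-1, 1) * x$dpsi_threshold, lty = 3)
  graphics::abline(h = -log10(x$alpha), lty = 3)
  invisible(x)
}

#' Write the merged effect-size / cluster-significance table
#' @param result A `splicing_result`.
#' @param path Output TSV path.
#' @export
write_splicing_table <- function(result, path) {
  write.table(result$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
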