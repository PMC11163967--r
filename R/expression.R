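# Gene-level normalization, filtering, a simplified moderated differential
# expression test, marker summaries, DSG/DEG overlap and Fisher
# overrepresentation analysis.

#' Normalize a count matrix (CPM, FPKM, TMM factors)
#'
#' TMM factors follow the trimmed-mean-of-M-values method (Robinson &
#' Oshlack): the reference library has the upper-quartile CPM closest to the
#' mean upper quartile, 30% of M-values and 5% of A-values are trimmed, M is
#' averaged with inverse asymptotic-variance weights, and factors are
#' rescaled to geometric mean 1 (computed by `edgeR::calcNormFactors`). FPKM
#' uses gene length / 1e3 and effective library size / 1e6.
#'
#' @param counts Non-negative integer matrix, genes x libraries.
#' @param lengths Named gene lengths in bp (required for FPKM).
#' @return List: `cpm`, `fpkm` (or NULL), `tmm`, `lib_sizes`,
#'   `effective_lib_sizes`.
#' @export
normalize_counts <- function(counts, lengths = NULL) {
  if (ncol(counts) < 2) stop("need at least 2 libraries")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero-count library: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  tmm <- edgeR::calcNormFactors(counts, method = "TMM")
  eff <- lib * tmm
  cpm <- t(t(counts) / eff * 1e6)
  fpkm <- NULL
  if (!is.null(lengths)) {
    len <- lengths[rownames(counts)]
    fpkm <- counts / (len / 1e3)
    fpkm <- t(t(fpkm) / (eff / 1e6))
  }
  list(cpm = cpm, fpkm = fpkm, tmm = setNames(tmm, colnames(counts)),
       lib_sizes = lib, effective_lib_sizes = eff)
}

#' Filter low-abundance genes
#'
#' Keeps genes whose CPM exceeds `min_count` rescaled by the median library
#' size (in millions) in at least as many libraries as the smallest design
#' group, and whose total count is at least `min_total`.
#'
#' @param counts Count matrix.
#' @param design A `study_design` (condition defines the groups).
#' @param min_count Count threshold at the median library size.
#' @param min_total Minimum total count across libraries.
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, design, min_count = 10,
                                  min_total = 15) {
  lib <- colSums(counts)
  cutoff <- min_count / (median(lib) / 1e6)
  cpm <- t(t(counts) / lib * 1e6)
  n_min <- min(table(design$condition))
  keep <- rowSums(cpm >= cutoff) >= n_min & rowSums(counts) >= min_total
  counts[keep, , drop = FALSE]
}

# Inverse of trigamma by Newton iteration (for the eBayes moment estimator).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Empirical-Bayes variance shrinkage: moment matching on log s^2.
squeeze_variances <- function(s2, df) {
  s2 <- pmax(s2, 1e-10)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(z) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
    s2_post <- rep(s02, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  list(df_prior = d0, var_prior = s02, var_post = s2_post)
}

#' Moderated differential expression on log2-CPM
#'
#' Fits a per-gene linear model on log2-CPM (prior count 0.5, effective
#' library sizes) with condition and donor terms (optionally one extra
#' continuous covariate), shrinks residual variances by empirical Bayes
#' (`s2_post = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, with `(d0, s0^2)` from
#' moment matching on `log s_g^2`) and reports moderated t statistics with
#' `d0 + d_g` degrees of freedom and Benjamini-Hochberg q-values. This is a
#' deliberate simplification of the voom/eBayes pipeline: no precision
#' weights, no robust outlier handling.
#'
#' @param counts Filtered count matrix.
#' @param design A `study_design`.
#' @param covariate Optional numeric per-library covariate (e.g. assigned
#'   read fraction).
#' @return data.frame `gene logFC t p q mean_expr df_total`, one row per gene.
#' @export
moderated_de <- function(counts, design, covariate = NULL) {
  norm <- normalize_counts(counts)
  eff <- norm$effective_lib_sizes
  logcpm <- log2(t(t(counts + 0.5) / (eff + 1)) * 1e6)

  X <- stats::model.matrix(~condition + donor, design)
  if (!is.null(covariate)) X <- cbind(X, covariate = covariate)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; aliased columns: ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))

  fit <- lm.fit(X, t(logcpm))
  res <- as.matrix(fit$residuals)
  dfr <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / dfr
  sq <- squeeze_variances(s2, dfr)

  cc <- which(colnames(X) == paste0("condition", levels(design$condition)[2]))
  xtxi <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  u <- sqrt(xtxi[cc, cc])
  beta <- as.matrix(fit$coefficients)[cc, ]
  se <- u * sqrt(sq$var_post)
  tstat <- beta / se
  df_total <- sq$df_prior + dfr
  p <- 2 * pt(-abs(tstat), df = df_total)
  data.frame(gene = rownames(counts), logFC = unname(beta),
             t = unname(tstat), p = unname(p),
             q = p.adjust(p, "BH"),
             mean_expr = rowMeans(logcpm),
             df_total = df_total, row.names = NULL)
}

#' Marker gene summaries for heatmaps and medians
#'
#' @param expr Expression matrix (e.g. FPKM), genes x libraries.
#' @param markers Marker gene ids.
#' @return List: `medians` (per-library median over markers) and `zscores`
#'   (per-gene z-score across libraries; 0 when a gene has zero variance).
#' @export
marker_summary <- function(expr, markers) {
  present <- intersect(markers, rownames(expr))
  if (length(present) == 0) stop("no marker gene overlaps the matrix")
  sub <- expr[present, , drop = FALSE]
  z <- t(apply(sub, 1, function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  colnames(z) <- colnames(sub)
  list(medians = apply(sub, 2, median), zscores = z, markers_used = present)
}

#' Overlap between differentially spliced and differentially expressed genes
#'
#' @param dsg_genes,deg_genes Gene id vectors.
#' @return List: sizes, intersection and `fraction` = |DSG & DEG| / |DSG|.
#' @export
dsg_deg_overlap <- function(dsg_genes, deg_genes) {
  dsg <- unique(dsg_genes); deg <- unique(deg_genes)
  both <- intersect(dsg, deg)
  list(n_dsg = length(dsg), n_deg = length(deg), n_overlap = length(both),
       overlap_genes = both,
       fraction = if (length(dsg) > 0) length(both) / length(dsg) else NA_real_)
}

#' Read gene sets from a GMT file
#' @param path GMT path (set name, description, genes...).
#' @return Named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  sets <- lapply(lines, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(lines, `[[`, character(1), 1)
  sets
}

#' Fisher overrepresentation analysis
#'
#' One-sided (greater) Fisher's exact test of each gene set against the hit
#' list within the universe, with Benjamini-Hochberg adjustment. The gene
#' ratio is the fraction of hits falling in the set.
#'
#' @param hits Hit gene ids (must be a subset of `universe`).
#' @param universe Background gene ids.
#' @param gene_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha Reporting threshold recorded in the output.
#' @return data.frame `set n_set n_hit_in_set gene_ratio p q`, ordered by p.
#' @export
ora_fisher <- function(hits, universe, gene_sets, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(intersect(hits, universe))
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    a <- length(intersect(hits, set))
    b <- length(hits) - a
    c <- length(set) - a
    d <- length(universe) - a - b - c
    p <- fisher.test(matrix(c(a, b, c, d), 2), alternative = "greater")$p.value
    data.frame(set = nm, n_set = length(set), n_hit_in_set = a,
               gene_ratio = if (length(hits) > 0) a / length(hits) else 0,
               p = p)
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, "BH")
  res$significant <- res$q < alpha
  res[order(res$p), , drop = FALSE]
}
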