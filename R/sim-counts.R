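# Dirichlet-multinomial junction-count simulator with per-donor effects.
#
# True condition proportions are defined at the donor-average linear
# predictor; donor effects are drawn on the logit scale and centred per
# junction so the truth is exactly the designed proportion vector.

# One Dirichlet-multinomial draw: total N, mean proportions p, concentration a0.
rdirmult <- function(N, p, a0) {
  if (N <= 0) return(rep(0L, length(p)))
  w <- rgamma(length(p), shape = a0 * p)
  if (sum(w) <= 0) w <- p
  as.integer(rmultinom(1, N, w / sum(w)))
}

#' Simulate counts for a single intron cluster
#'
#' Draws per-library junction counts from a Dirichlet-multinomial model with
#' additive donor effects on the softmax scale. Used by the main generator
#' and directly useful for calibration studies.
#'
#' @param design A `study_design`.
#' @param p_white,p_beige True proportion vectors (each sums to 1); equal
#'   vectors give a null cluster.
#' @param a0 Dirichlet-multinomial concentration (> 0).
#' @param donor_sd Standard deviation of logit-scale donor effects (centred
#'   per junction across donors).
#' @param depth Expected per-library cluster read total (Poisson).
#' @return Integer matrix, junctions x libraries.
#' @export
simulate_cluster_counts <- function(design, p_white, p_beige = p_white,
                                    a0 = 30, donor_sd = 0.25, depth = 300) {
  J <- length(p_white)
  stopifnot(length(p_beige) == J,
            abs(sum(p_white) - 1) < 1e-9, abs(sum(p_beige) - 1) < 1e-9,
            a0 > 0, depth > 0)
  donors <- levels(design$donor)
  gam <- matrix(rnorm(length(donors) * J, 0, donor_sd), length(donors), J,
                dimnames = list(donors, NULL))
  gam <- sweep(gam, 2, colMeans(gam))
  beige <- condition_indicator(design) == 1L
  counts <- matrix(0L, J, nrow(design),
                   dimnames = list(NULL, design$library_id))
  for (i in seq_len(nrow(design))) {
    eta <- log(if (beige[i]) p_beige else p_white) +
      gam[as.character(design$donor[i]), ]
    p <- exp(eta - max(eta)); p <- p / sum(p)
    counts[, i] <- rdirmult(rpois(1, depth), p, a0)
  }
  counts
}

#' Simulate a study-wide junction count table with known truth
#'
#' For every gene with a junction cluster in `annotation`, draws
#' Dirichlet-multinomial counts across the design's libraries. A
#' `dsg_fraction` of clusters receive a condition effect with maximum
#' |delta PSI| uniform on `dpsi_range`; for alternative-TSS genes the effect
#' is placed on the alternative first-intron junction (beige-up), emulating
#' TSS-switch-driven splicing differences. A subset of clusters additionally
#' express their pre-designated cryptic GT-AG junction, which is present in
#' the genome but absent from every GTF. Junctions outside clusters receive
#' independent Poisson counts and no condition effect.
#'
#' @param annotation A `sim_annotation`.
#' @param design A `study_design`; its libraries become count columns.
#' @param dsg_fraction Fraction of clusters made truly differential.
#' @param depth Expected per-library cluster read total.
#' @param donor_sd Logit-scale donor effect standard deviation.
#' @param a0_meanlog,a0_sdlog Log-normal parameters of the per-cluster
#'   concentration (median `exp(a0_meanlog)`, default 30).
#' @param n_cryptic Number of clusters whose cryptic candidate junction is
#'   expressed.
#' @param dpsi_range Range of the true maximum |delta PSI| for differential
#'   clusters.
#' @param alt_tss_dsg_weight Fraction of differential clusters drawn from
#'   alternative-TSS genes (the study this emulates found most differential
#'   junctions at first introns).
#' @param seed Master seed (dedicated RNG stream).
#' @return A list with `junctions` (a [junction_table]) and `truth`
#'   (class `sim_truth`).
#' @export
simulate_junction_counts <- function(annotation, design,
                                     dsg_fraction = 0.1,
                                     depth = 300,
                                     donor_sd = 0.25,
                                     a0_meanlog = log(30),
                                     a0_sdlog = 0.5,
                                     n_cryptic = 8,
                                     dpsi_range = c(0.1, 0.5),
                                     alt_tss_dsg_weight = 0.7,
                                     seed) {
  assert_seed(seed)
  assert_proportion(dsg_fraction, "dsg_fraction")
  stopifnot(depth > 0)
  set.seed(stream_seed(seed, "junction_counts"))

  jn <- annotation$junctions
  genes <- annotation$genes
  cl_genes <- genes$gene_id[genes$cluster_type != "none"]
  n_cl <- length(cl_genes)
  n_cryptic <- min(n_cryptic, n_cl)
  cryptic_cl <- sample(cl_genes, n_cryptic)

  n_dsg <- round(dsg_fraction * n_cl)
  alt_genes <- genes$gene_id[genes$cluster_type == "alt_tss"]
  int_genes <- genes$gene_id[genes$cluster_type == "internal"]
  n_alt_dsg <- min(round(n_dsg * alt_tss_dsg_weight), length(alt_genes))
  dsg <- c(sample(alt_genes, n_alt_dsg),
           sample(int_genes, min(n_dsg - n_alt_dsg, length(int_genes))))

  libs <- design$library_id
  rows <- list(); counts <- list(); truth_rows <- list()

  for (gid in cl_genes) {
    gj <- jn[jn$gene_id == gid & jn$in_cluster, , drop = FALSE]
    ref <- gj[gj$role == "intron", , drop = FALSE]
    alt <- gj[gj$role %in% c("alt_first", "alt_internal"), , drop = FALSE]
    cry <- gj[gj$role == "cryptic_candidate", , drop = FALSE]
    use_cry <- gid %in% cryptic_cl
    members <- rbind(ref, alt, if (use_cry) cry)
    J <- nrow(members)
    jstar <- which(members$role %in% c("alt_first", "alt_internal"))[1]

    is_dsg <- gid %in% dsg
    sign <- if (is_dsg) {
      if (genes$cluster_type[genes$gene_id == gid] == "alt_tss") 1
      else sample(c(-1, 1), 1)
    } else 0
    u <- if (is_dsg) runif(1, dpsi_range[1], dpsi_range[2]) else 0

    # white proportions: designated junction placed so the effect fits
    p_star <- if (sign >= 0) runif(1, 0.15, 0.93 - u) else runif(1, u + 0.07, 0.85)
    rest <- rgamma(J - 1, 1) + 0.05
    if (use_cry) rest[length(rest)] <- sum(rest) * runif(1, 0.03, 0.08)
    p_white <- numeric(J)
    p_white[jstar] <- p_star
    p_white[-jstar] <- rest / sum(rest) * (1 - p_star)
    p_beige <- p_white
    if (is_dsg) {
      p_beige[jstar] <- p_white[jstar] + sign * u
      p_beige[-jstar] <- p_white[-jstar] *
        (1 - p_beige[jstar]) / (1 - p_white[jstar])
    }
    a0 <- rlnorm(1, a0_meanlog, a0_sdlog)
    cm <- simulate_cluster_counts(design, p_white, p_beige, a0 = a0,
                                  donor_sd = donor_sd, depth = depth)
    rows[[gid]] <- members
    counts[[gid]] <- cm
    truth_rows[[gid]] <- data.frame(
      gene_id = gid,
      type = genes$cluster_type[genes$gene_id == gid],
      n_members = J, a0 = a0, is_dsg = is_dsg,
      designated = members$junction_id[jstar],
      sign = sign, max_dpsi = u, has_cryptic = use_cry)
    truth_rows[[gid]]$members <- list(members$junction_id)
    truth_rows[[gid]]$p_white <- list(p_white)
    truth_rows[[gid]]$p_beige <- list(p_beige)
    truth_rows[[gid]]$dpsi <- list(p_beige - p_white)
  }

  # background junctions: annotated introns outside clusters, no condition
  # effect, independent per-library Poisson counts
  bg <- jn[!jn$in_cluster & jn$role == "intron", , drop = FALSE]
  if (nrow(bg) > 0) {
    base <- rlnorm(nrow(bg), log(depth * 0.5), 0.6)
    bgc <- matrix(rpois(nrow(bg) * length(libs), rep(base, length(libs))),
                  nrow(bg), length(libs), dimnames = list(NULL, libs))
    rows[["background"]] <- bg
    counts[["background"]] <- bgc
  }

  all_rows <- do.call(rbind, rows)
  all_counts <- do.call(rbind, counts)
  jt <- junction_table(
    data.frame(chrom = all_rows$chrom, start = all_rows$start,
               end = all_rows$end, strand = all_rows$strand,
               anchor = 25L),
    all_counts)

  clusters <- do.call(rbind, truth_rows)
  rownames(clusters) <- NULL
  truth <- structure(list(
    clusters = clusters,
    dsg_genes = clusters$gene_id[clusters$is_dsg],
    beige_tss_genes = clusters$gene_id[clusters$is_dsg &
                                         clusters$type == "alt_tss"],
    cryptic_junctions = unlist(lapply(seq_len(nrow(clusters)), function(i)
      if (clusters$has_cryptic[i])
        clusters$members[[i]][length(clusters$members[[i]])])),
    depth = depth, donor_sd = donor_sd, seed = seed), class = "sim_truth")
  list(junctions = jt, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d clusters (%d differential, %d with a cryptic junction)\n",
    nrow(x$clusters), sum(x$clusters$is_dsg),
    sum(x$clusters$has_cryptic)))
  invisible(x)
}

#' Simulate a gene-level count matrix with a controlled DSG/DEG overlap
#'
#' Negative-binomial counts with log-scale donor effects. A `de_fraction` of
#' genes receive a condition log2 fold change drawn from a standard normal
#' truncated away from zero (|logFC| >= 0.3). The differentially expressed
#' set is chosen so that its intersection with `dsg_genes` is as close as
#' possible to `overlap_target` of the DSG set.
#'
#' @param design A `study_design`.
#' @param genes Gene identifiers (character) or a gene count.
#' @param de_fraction Fraction of genes made truly differential.
#' @param overlap_target Target |DSG intersect DEG| / |DSG|.
#' @param dsg_genes Differentially spliced gene set to overlap against.
#' @param mean_depth Median expected count per gene and library.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param donor_sd Log-scale donor effect standard deviation.
#' @param seed Master seed (dedicated RNG stream).
#' @return List: `counts` (genes x libraries), `lengths` (bp), `truth`
#'   (per-gene logFC and DE flag), `de_genes`, `realized_overlap`.
#' @export
simulate_gene_counts <- function(design, genes = 200, de_fraction = 0.2,
                                 overlap_target = 0.1,
                                 dsg_genes = character(0),
                                 mean_depth = 500, dispersion = 0.1,
                                 donor_sd = 0.1, seed) {
  assert_seed(seed)
  assert_proportion(overlap_target, "overlap_target")
  assert_proportion(de_fraction, "de_fraction")
  if (mean_depth <= 0 || dispersion < 0)
    stop("mean_depth must be positive and dispersion non-negative")
  set.seed(stream_seed(seed, "gene_counts"))

  gene_ids <- if (is.character(genes)) genes else sprintf("g%03d", seq_len(genes))
  n <- length(gene_ids)
  dsg_genes <- intersect(dsg_genes, gene_ids)

  n_de <- round(de_fraction * n)
  k <- min(round(overlap_target * length(dsg_genes)), n_de, length(dsg_genes))
  pool <- setdiff(gene_ids, dsg_genes)
  de_genes <- c(if (k > 0) sample(dsg_genes, k),
                sample(pool, min(n_de - k, length(pool))))

  logfc <- setNames(rep(0, n), gene_ids)
  if (length(de_genes) > 0) {
    lf <- rnorm(length(de_genes))
    while (any(abs(lf) < 0.3))
      lf[abs(lf) < 0.3] <- rnorm(sum(abs(lf) < 0.3))
    logfc[de_genes] <- lf
  }

  base <- rlnorm(n, log(mean_depth), 1)
  donors <- levels(design$donor)
  don_eff <- matrix(rnorm(n * length(donors), 0, donor_sd), n,
                    dimnames = list(gene_ids, donors))
  beige <- condition_indicator(design)
  mu <- sapply(seq_len(nrow(design)), function(i)
    base * 2^(logfc * beige[i]) * exp(don_eff[, as.character(design$donor[i])]))
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = if (dispersion > 0) 1 / dispersion else Inf),
                   n, nrow(design),
                   dimnames = list(gene_ids, design$library_id))

  realized <- if (length(dsg_genes) > 0)
    length(intersect(dsg_genes, de_genes)) / length(dsg_genes) else NA_real_
  list(counts = counts,
       lengths = setNames(sample(500:5000, n, replace = TRUE), gene_ids),
       truth = data.frame(gene_id = gene_ids, logFC = unname(logfc),
                          is_de = gene_ids %in% de_genes),
       de_genes = de_genes, realized_overlap = realized)
}

#' Write / read a gene count matrix TSV (gene_id, length, one column per library)
#' @param sim Result of [simulate_gene_counts()] (or a list with `counts` and
#'   `lengths`).
#' @param path Output TSV path.
#' @export
write_gene_counts <- function(sim, path) {
  df <- data.frame(gene_id = rownames(sim$counts),
                   length = sim$lengths[rownames(sim$counts)], sim$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_counts
#' @export
read_gene_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("gene_id", "length")),
                         drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$gene_id
  list(counts = counts, lengths = setNames(df$length, df$gene_id))
}
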