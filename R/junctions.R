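# Junction tables: introns are stored 1-based inclusive (start = first
# intronic base, end = last intronic base); BED I/O converts at the boundary.

#' Construct a junction table
#'
#' @param junctions data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `anchor` (introns 1-based inclusive).
#' @param counts Integer matrix, one row per junction, one column per library.
#' @return An object of class `junction_table`.
#' @export
junction_table <- function(junctions, counts) {
  need <- c("chrom", "start", "end", "strand", "anchor")
  stopifnot(all(need %in% names(junctions)),
            nrow(junctions) == nrow(counts),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("negative junction counts")
  if (any(junctions$end < junctions$start))
    stop("intron_end < intron_start")
  junctions <- junctions[, need]
  junctions$key <- junction_key(junctions$chrom, junctions$strand,
                                junctions$start, junctions$end)
  rownames(junctions) <- rownames(counts) <- NULL
  structure(list(junctions = junctions, counts = counts),
            class = "junction_table")
}

#' @export
print.junction_table <- function(x, ...) {
  cat(sprintf("junction_table: %d junctions x %d libraries (%s reads)\n",
              nrow(x$junctions), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.junction_table <- function(x) dim(x$counts)

#' Read per-library junction files or a combined TSV count table
#'
#' `regtools_bed12` reads one BED12 junction file per library (the output
#' dialect of `regtools junctions extract`): the score column holds the read
#' count, the two blocks are the flanking anchors, and the intron is the gap
#' between them. BED 0-based half-open block arithmetic is converted to
#' 1-based inclusive intron coordinates; the anchor is the shorter block.
#' Duplicate junctions within a library are summed. The `tsv` format is a
#' single table `chrom start end strand anchor <lib1> ... <libN>` with
#' 1-based inclusive coordinates.
#'
#' @param paths Character vector of file paths. For `regtools_bed12` the
#'   library ids are the names of `paths` (or basenames without extension).
#' @param design A `study_design`; library ids must match.
#' @param format One of `"regtools_bed12"` or `"tsv"`.
#' @return A [junction_table] with one count column per design library
#'   (libraries without a file contribute zeros only if absent from `paths`
#'   is an error, so all must be present).
#' @export
read_junctions <- function(paths, design, format = c("regtools_bed12", "tsv")) {
  format <- match.arg(format)
  libs <- design$library_id
  if (format == "tsv") {
    stopifnot(length(paths) == 1)
    df <- read.table(paths, header = TRUE, sep = "\t", check.names = FALSE)
    need <- c("chrom", "start", "end", "strand", "anchor")
    if (!all(need %in% names(df)))
      stop("junction TSV must have columns: ", paste(need, collapse = ", "))
    count_cols <- setdiff(names(df), need)
    unknown <- setdiff(count_cols, libs)
    if (length(unknown) > 0)
      stop("unknown library_id in junction TSV: ",
           paste(unknown, collapse = ", "))
    counts <- matrix(0L, nrow(df), length(libs), dimnames = list(NULL, libs))
    counts[, count_cols] <- as.matrix(df[, count_cols, drop = FALSE])
    return(junction_table(df[, need], counts))
  }

  ids <- names(paths) %||% sub("\\.[^.]*$", "", basename(paths))
  if (is.null(names(paths))) names(paths) <- ids
  unknown <- setdiff(ids, libs)
  if (length(unknown) > 0)
    stop("unknown library_id: ", paste(unknown, collapse = ", "))

  per_lib <- lapply(ids, function(id) parse_regtools_bed12(paths[[id]]))
  names(per_lib) <- ids
  keys <- unique(unlist(lapply(per_lib, function(d) d$key)))
  if (length(keys) == 0)
    return(junction_table(
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), anchor = integer(0)),
      matrix(0L, 0, length(libs), dimnames = list(NULL, libs))))
  counts <- matrix(0L, length(keys), length(libs),
                   dimnames = list(keys, libs))
  meta <- NULL
  for (id in ids) {
    d <- per_lib[[id]]
    counts[d$key, id] <- counts[d$key, id] + d$count
    meta <- rbind(meta, d)
  }
  meta <- meta[!duplicated(meta$key), , drop = FALSE]
  meta <- meta[match(keys, meta$key), , drop = FALSE]
  # anchor = max overhang observed across libraries
  anchor <- tapply(unlist(lapply(per_lib, `[[`, "anchor")),
                   unlist(lapply(per_lib, `[[`, "key")), max)
  meta$anchor <- as.integer(anchor[keys])
  rownames(counts) <- NULL
  junction_table(meta[, c("chrom", "start", "end", "strand", "anchor")],
                 counts)
}

parse_regtools_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      anchor = integer(0), count = integer(0),
                      key = character(0)))
  fields <- strsplit(lines, "\t| +")
  parse_line <- function(i) {
    f <- fields[[i]]
    if (length(f) < 12)
      stop(sprintf("malformed BED12 line (%d fields) at %s:%d",
                   length(f), path, i), call. = FALSE)
    chrom_start <- suppressWarnings(as.integer(f[2]))
    count <- suppressWarnings(as.numeric(f[5]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
    starts <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
    if (anyNA(c(chrom_start, count, n_blocks, sizes, starts)) ||
        n_blocks != 2 || length(sizes) != 2 || length(starts) != 2)
      stop(sprintf("malformed BED12 line at %s:%d", path, i), call. = FALSE)
    # intron: 1-based first..last intronic base from 0-based block arithmetic
    data.frame(chrom = f[1],
               start = chrom_start + sizes[1] + 1L,
               end = chrom_start + starts[2],
               strand = f[6],
               anchor = min(sizes),
               count = as.integer(count))
  }
  d <- do.call(rbind, lapply(seq_along(fields), parse_line))
  d$key <- junction_key(d$chrom, d$strand, d$start, d$end)
  # duplicate junctions within a library are summed
  agg <- tapply(d$count, d$key, sum)
  d <- d[!duplicated(d$key), , drop = FALSE]
  d$count <- as.integer(agg[d$key])
  d
}

#' Write a junction table as a single TSV
#' @param jt A [junction_table].
#' @param path Output path.
#' @export
write_junction_table <- function(jt, path) {
  df <- cbind(jt$junctions[, c("chrom", "start", "end", "strand", "anchor")],
              as.data.frame(jt$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-library regtools-style BED12 junction files
#' @param jt A [junction_table].
#' @param dir Output directory; one `<library_id>.bed` file per library.
#' @export
write_junctions_bed12 <- function(jt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  j <- jt$junctions
  a <- pmax(j$anchor, 1L)
  paths <- setNames(file.path(dir, paste0(colnames(jt$counts), ".bed")),
                    colnames(jt$counts))
  for (lib in colnames(jt$counts)) {
    keep <- jt$counts[, lib] > 0
    chrom_start <- j$start - a - 1L            # 0-based left anchor start
    chrom_end <- j$end + a                     # half-open right anchor end
    lines <- sprintf("%s\t%d\t%d\tJUNC\t%d\t%s\t%d\t%d\t255,0,0\t2\t%d,%d\t0,%d",
                     j$chrom, chrom_start, chrom_end, jt$counts[, lib],
                     j$strand, chrom_start, chrom_end, a, a,
                     j$end - chrom_start)
    writeLines(lines[keep], paths[lib])
  }
  invisible(paths)
}

#' Filter junctions on anchor length and intron size
#'
#' Retains junctions with anchor >= `min_anchor` and an intron length
#' (end - start + 1) between `min_intron` and `max_intron`, bounds inclusive.
#'
#' @param jt A [junction_table].
#' @param min_anchor Minimum anchor (bp).
#' @param min_intron,max_intron Intron length bounds (bp).
#' @return The filtered [junction_table].
#' @export
filter_junctions <- function(jt, min_anchor = 6, min_intron = 20,
                             max_intron = 1e6) {
  len <- jt$junctions$end - jt$junctions$start + 1L
  keep <- jt$junctions$anchor >= min_anchor &
    len >= min_intron & len <= max_intron
  junction_table(jt$junctions[keep, , drop = FALSE],
                 jt$counts[keep, , drop = FALSE])
}

#' Cluster introns sharing splice sites
#'
#' Within each (chromosome, strand), introns are nodes of a graph with edges
#' between introns sharing an identical start or end coordinate; connected
#' components are clusters. Clusters are then iteratively refined: members
#' contributing less than `min_fraction` of their cluster's pooled reads are
#' dropped and components re-formed until stable. Finally a support rule is
#' applied: in `per_library` mode a cluster is kept only if its per-library
#' read total is at least `min_reads_per_library` in every library; `pooled`
#' mode compares the all-library total against the same threshold.
#'
#' @param jt A filtered [junction_table].
#' @param min_reads_per_library Support threshold (reads).
#' @param min_fraction Refinement threshold on a member's share of cluster
#'   pooled reads.
#' @param support_mode `"per_library"` (default) or `"pooled"`.
#' @return A list of `intron_cluster` objects (cluster_id, junctions,
#'   counts matrix with one row per member junction).
#' @export
cluster_introns <- function(jt, min_reads_per_library = 30,
                            min_fraction = 0.001,
                            support_mode = c("per_library", "pooled")) {
  support_mode <- match.arg(support_mode)
  j <- jt$junctions
  n <- nrow(j)
  if (n == 0) return(list())
  active <- rep(TRUE, n)

  components <- function(idx) {
    # edges between introns sharing a start or an end, per (chrom, strand)
    sub <- j[idx, , drop = FALSE]
    ekey <- function(coord) paste(sub$chrom, sub$strand, coord)
    edges <- integer(0)
    for (key in list(ekey(sub$start), ekey(sub$end))) {
      grp <- split(seq_along(idx), key)
      for (g in grp) if (length(g) > 1)
        edges <- c(edges, rbind(g[-length(g)], g[-1]))
    }
    gr <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(edges) > 0) gr <- igraph::add_edges(gr, edges)
    split(idx, igraph::components(gr)$membership)
  }

  repeat {
    comps <- components(which(active))
    drop <- logical(n)
    for (comp in comps) {
      pooled <- rowSums(jt$counts[comp, , drop = FALSE])
      total <- sum(pooled)
      if (total > 0) drop[comp[pooled < min_fraction * total]] <- TRUE
    }
    if (!any(drop)) break
    active[drop] <- FALSE
    if (!any(active)) return(list())
  }

  comps <- comps[order(vapply(comps, function(ix) min(j$start[ix]), numeric(1)))]
  comps <- comps[order(vapply(comps, function(ix) j$chrom[ix[1]], character(1)))]
  out <- list()
  k <- 0L
  for (comp in comps) {
    cm <- jt$counts[comp, , drop = FALSE]
    ok <- if (support_mode == "per_library")
      all(colSums(cm) >= min_reads_per_library)
    else sum(cm) >= min_reads_per_library
    if (!ok) next
    k <- k + 1L
    cid <- sprintf("%s:clu_%d_%s", j$chrom[comp[1]], k, j$strand[comp[1]])
    out[[cid]] <- structure(
      list(cluster_id = cid,
           junctions = j[comp, , drop = FALSE],
           counts = cm),
      class = "intron_cluster")
  }
  out
}

#' @export
print.intron_cluster <- function(x, ...) {
  cat(sprintf("intron_cluster %s: %d introns x %d libraries\n",
              x$cluster_id, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Apply strict prefilters to clusters before differential testing
#'
#' Drops introns detected (count > 0) in fewer than `min_libs_detected`
#' libraries, then drops clusters that do not have at least
#' `min_libs_per_condition` libraries in every condition whose cluster read
#' total is at least `min_cluster_reads`. Clusters reduced to fewer than two
#' introns are removed.
#'
#' @param clusters List of `intron_cluster` objects.
#' @param design A `study_design` covering all count columns.
#' @param min_libs_detected Minimum libraries with a non-zero count per intron.
#' @param min_libs_per_condition Minimum supported libraries per condition.
#' @param min_cluster_reads Read total defining a "supported" library.
#' @return The filtered cluster list.
#' @export
prefilter_clusters <- function(clusters, design, min_libs_detected = 14,
                               min_libs_per_condition = 12,
                               min_cluster_reads = 20) {
  n_lib <- nrow(design)
  cond_sizes <- table(design$condition)
  if (min_libs_detected > n_lib || min_libs_per_condition > min(cond_sizes))
    stop("prefilter thresholds exceed the number of libraries in the design")
  out <- list()
  for (cl in clusters) {
    stopifnot(all(design$library_id %in% colnames(cl$counts)))
    cm <- cl$counts[, design$library_id, drop = FALSE]
    keep <- rowSums(cm > 0) >= min_libs_detected
    if (sum(keep) < 2) next
    cm <- cm[keep, , drop = FALSE]
    totals <- colSums(cm)
    ok <- vapply(levels(design$condition), function(cond) {
      sum(totals[design$condition == cond] >= min_cluster_reads) >=
        min_libs_per_condition
    }, logical(1))
    if (!all(ok)) next
    out[[cl$cluster_id]] <- structure(
      list(cluster_id = cl$cluster_id,
           junctions = cl$junctions[keep, , drop = FALSE],
           counts = cm),
      class = "intron_cluster")
  }
  out
}
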