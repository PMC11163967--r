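# End-to-end orchestration: simulate -> cluster -> diffsplice -> annotate ->
# score -> expression -> tss, with a plain-text config and a JSON manifest.

pipeline_defaults <- list(
  min_anchor = 6, min_intron = 20, max_intron = 1e6,
  min_reads = 30, min_fraction = 0.001,
  min_libs_detected = 14, min_libs_per_condition = 12, min_cluster_reads = 20,
  alpha = 0.05, dpsi = 0.1, subsample = 280, seed = 1)

#' Read a key=value pipeline config file
#'
#' Lines of the form `key = value` (comments with `#`). Numeric values are
#' coerced; everything else stays character. Unset thresholds take the
#' package defaults.
#'
#' @param path Config file path.
#' @return Named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- setNames(lapply(kv, function(x) {
    v <- paste(x[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, `[[`, character(1), 1))
  cfg <- utils::modifyList(pipeline_defaults, cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

validation_error <- function(...) {
  stop(structure(class = c("isoswitch_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

validate_config <- function(cfg, through) {
  need <- c("design", "junctions")
  if (match(through, pipeline_stages) >= 3) need <- c(need, "gtf_tier1", "genome")
  if (match(through, pipeline_stages) >= 4) need <- c(need, "trifid")
  if (match(through, pipeline_stages) >= 5) need <- c(need, "counts")
  if (match(through, pipeline_stages) >= 6) need <- c(need, "chip", "input", "peaks")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    validation_error("config missing required keys: ",
                     paste(miss, collapse = ", "))
  for (key in intersect(names(cfg),
                        c("design", "junctions", "genome", "trifid", "counts",
                          "chip", "input", "peaks", "gmt",
                          paste0("gtf_tier", 1:5)))) {
    if (!file.exists(cfg[[key]]))
      validation_error("config path does not exist: ", key, " = ", cfg[[key]])
  }
  for (key in setdiff(names(pipeline_defaults), "seed"))
    if (cfg[[key]] <= 0) validation_error("threshold must be positive: ", key)
  invisible(cfg)
}

pipeline_stages <- c("cluster", "diffsplice", "annotate", "score",
                     "expression", "tss")

#' Run the junction-centric splicing pipeline
#'
#' Executes the stages cluster -> diffsplice -> annotate -> score ->
#' expression -> tss in order (up to `through`), writing one TSV per result
#' and a JSON manifest recording input hashes, parameters and row counts. A
#' stage failure halts the run with the failing stage named.
#'
#' @param config A `pipeline_config` (or path to a config file).
#' @param outdir Output directory (defaults to `config$outdir`).
#' @param through Last stage to run.
#' @return Invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         through = c("tss", "cluster", "diffsplice",
                                     "annotate", "score", "expression")) {
  through <- match.arg(through)
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(pipeline_defaults, config)
  validate_config(cfg, through)
  outdir <- outdir %||% cfg$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n_through <- match(through, pipeline_stages)

  manifest <- list(parameters = cfg[setdiff(names(pipeline_defaults), "")],
                   stages = list())
  results <- list()
  outfile <- function(name) file.path(outdir, name)
  record <- function(stage, inputs, outputs, rows) {
    manifest$stages[[stage]] <<- list(
      inputs = lapply(inputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))),
      outputs = outputs, rows = rows)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      if (inherits(e, "isoswitch_validation_error")) stop(e)
      stop(structure(class = c("isoswitch_stage_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", stage,
                                            conditionMessage(e)),
                          call = NULL, stage = stage)))
    })
  }

  # cluster
  run_stage("cluster", function() {
    design <- read_design(cfg$design)
    jt <- read_junctions(cfg$junctions, design, format = "tsv")
    jt <- filter_junctions(jt, cfg$min_anchor, cfg$min_intron, cfg$max_intron)
    clusters <- cluster_introns(jt, cfg$min_reads, cfg$min_fraction)
    clusters <- prefilter_clusters(clusters, design, cfg$min_libs_detected,
                                   cfg$min_libs_per_condition,
                                   cfg$min_cluster_reads)
    cl_tab <- do.call(rbind, lapply(clusters, function(cl)
      cbind(cluster_id = cl$cluster_id, cl$junctions,
            pooled_reads = rowSums(cl$counts))))
    write.table(cl_tab, outfile("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$design <<- design
    results$junctions <<- jt
    results$clusters <<- clusters
    record("cluster", c(cfg$design, cfg$junctions),
           "clusters.tsv", length(clusters))
  })

  if (n_through >= 2) run_stage("diffsplice", function() {
    res <- differential_splicing(results$clusters, results$design,
                                 alpha = cfg$alpha,
                                 dpsi_threshold = cfg$dpsi)
    write_splicing_table(res, outfile("splicing.tsv"))
    results$splicing <<- res
    record("diffsplice", character(0), "splicing.tsv", nrow(res$table))
  })

  if (n_through >= 3) run_stage("annotate", function() {
    gtfs <- unlist(cfg[grepl("^gtf_tier", names(cfg))])
    names(gtfs) <- sub("gtf_", "", names(gtfs))
    index <- build_transcript_index(gtfs[order(names(gtfs))])
    calls <- annotate_junctions(
      data.frame(chrom = results$splicing$table$chrom,
                 strand = results$splicing$table$strand,
                 start = results$splicing$table$intron_start,
                 end = results$splicing$table$intron_end), index)
    calls <- classify_cryptic(calls, cfg$genome, index)
    write.table(calls, outfile("annotation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    fip <- first_intron_proportions(calls, results$splicing)
    write.table(fip, outfile("first_intron_proportions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tsst <- tss_table(calls, results$splicing)
    export_tss_bed(tsst, outfile("tss.bed"))
    results$index <<- index
    results$annotation <<- calls
    results$tss <<- tsst
    record("annotate", unname(c(gtfs, cfg$genome)),
           c("annotation.tsv", "first_intron_proportions.tsv", "tss.bed"),
           nrow(calls))
  })

  if (n_through >= 4) run_stage("score", function() {
    trifid <- read_trifid(cfg$trifid)
    scores <- score_junctions(results$annotation, trifid)
    write.table(scores[, c("key", "trifid", "n_scored_transcripts")],
                outfile("junction_trifid.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    dt <- cluster_delta_trifid(results$splicing, scores, alpha = cfg$alpha,
                               dpsi_threshold = cfg$dpsi)
    write.table(dt, outfile("delta_trifid.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    groups <- trifid_group_comparison(results$splicing, scores,
                                      n_subsample = cfg$subsample,
                                      seed = cfg$seed)
    if (!is.null(groups))
      write.table(groups$group_stats, outfile("trifid_groups.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    results$scores <<- scores
    results$delta_trifid <<- dt
    results$trifid_groups <<- groups
    record("score", cfg$trifid,
           c("junction_trifid.tsv", "delta_trifid.tsv", "trifid_groups.tsv"),
           nrow(dt))
  })

  if (n_through >= 5) run_stage("expression", function() {
    gc <- read_gene_counts(cfg$counts)
    counts <- filter_low_expression(gc$counts, results$design)
    de <- moderated_de(counts, results$design)
    write.table(de, outfile("de.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    sig <- grepl("_enriched$", results$splicing$table$class)
    dsg <- unique(stats::na.omit(
      results$annotation$gene_id[results$annotation$key %in%
                                   results$splicing$table$key[sig]]))
    deg <- de$gene[de$q < cfg$alpha]
    overlap <- dsg_deg_overlap(dsg, deg)
    results$de <<- de
    results$dsg_genes <<- dsg
    results$overlap <<- overlap
    if (!is.null(cfg$gmt)) {
      ora <- ora_fisher(deg, de$gene, read_gmt(cfg$gmt), alpha = cfg$alpha)
      write.table(ora, outfile("ora.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      results$ora <<- ora
    }
    record("expression", cfg$counts, "de.tsv", nrow(de))
  })

  if (n_through >= 6) run_stage("tss", function() {
    fai <- paste0(cfg$genome, ".fai")
    chrom_lengths <- if (file.exists(fai)) {
      fx <- read.table(fai)
      setNames(fx[[2]], fx[[1]])
    } else {
      g <- Biostrings::readDNAStringSet(cfg$genome)
      setNames(Biostrings::width(g), sub("\\s.*", "", names(g)))
    }
    windows <- promoter_windows(results$tss, chrom_lengths = chrom_lengths)
    ratio <- log_ratio_track(cfg$chip, cfg$input, chrom_lengths)
    wm <- window_mean_signal(ratio, windows, chrom_lengths)
    write.table(wm$windows, outfile("tss_window_signal.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pk <- peak_overlap_fraction(windows, cfg$peaks)
    write.table(pk, outfile("peak_overlap.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    prof <- profile_matrix(ratio, results$tss, chrom_lengths)
    results$windows <<- windows
    results$window_signal <<- wm
    results$peak_overlap <<- pk
    results$profile <<- prof
    record("tss", c(cfg$chip, cfg$input, cfg$peaks),
           c("tss_window_signal.tsv", "peak_overlap.tsv"), nrow(windows))
  })

  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}

#' Generate a complete self-contained synthetic dataset
#'
#' Runs all synthetic-data generators with one master seed, writes every
#' input the pipeline consumes (genome, three GTF tiers, TRIFID table, design
#' file, junction count TSV, gene count TSV, ChIP/input bedGraphs, peak BED)
#' plus a ready-to-run config file, and returns the in-memory ground truth.
#'
#' @param outdir Output directory.
#' @param seed Master seed; each artifact uses a derived RNG stream.
#' @param n_genes,alt_tss_fraction Passed to [make_genome_and_annotation()].
#' @param dsg_fraction,depth,n_cryptic Passed to [simulate_junction_counts()].
#' @param de_fraction,overlap_target Passed to [simulate_gene_counts()].
#' @return List: `annotation`, `design`, `junctions`, `truth`, `gene_sim`,
#'   `chip`, `config` (path), `paths`.
#' @export
simulate_dataset <- function(outdir, seed, n_genes = 200,
                             alt_tss_fraction = 0.3, dsg_fraction = 0.1,
                             depth = 300, n_cryptic = 8, de_fraction = 0.2,
                             overlap_target = 0.1) {
  assert_seed(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  anno <- make_genome_and_annotation(outdir, n_genes = n_genes,
                                     alt_tss_fraction = alt_tss_fraction,
                                     seed = seed)
  design <- make_study_design()
  sim <- simulate_junction_counts(anno, design, dsg_fraction = dsg_fraction,
                                  depth = depth, n_cryptic = n_cryptic,
                                  seed = seed)
  gene_sim <- simulate_gene_counts(design, genes = anno$genes$gene_id,
                                   de_fraction = de_fraction,
                                   overlap_target = overlap_target,
                                   dsg_genes = sim$truth$dsg_genes,
                                   seed = seed)
  chip <- simulate_chip(anno, sim$truth$beige_tss_genes, outdir, seed = seed)

  paths <- list(design = file.path(outdir, "design.tsv"),
                junctions = file.path(outdir, "junctions.tsv"),
                counts = file.path(outdir, "gene_counts.tsv"),
                config = file.path(outdir, "config.txt"))
  write_design(design, paths$design)
  write_junction_table(sim$junctions, paths$junctions)
  write_gene_counts(gene_sim, paths$counts)

  cfg <- c(list(design = paths$design, junctions = paths$junctions,
                genome = anno$paths$fasta,
                gtf_tier1 = unname(anno$paths$gtf[1]),
                gtf_tier2 = unname(anno$paths$gtf[2]),
                gtf_tier3 = unname(anno$paths$gtf[3]),
                trifid = anno$paths$trifid, counts = paths$counts,
                chip = chip$paths$chip, input = chip$paths$input,
                peaks = chip$paths$peaks, outdir = file.path(outdir, "results")),
           pipeline_defaults)
  cfg$seed <- seed
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, as.character, character(1))),
             paths$config)
  list(annotation = anno, design = design, junctions = sim$junctions,
       truth = sim$truth, gene_sim = gene_sim, chip = chip,
       config = paths$config, paths = c(paths, anno$paths, chip$paths))
}
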