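# Priority-cascade junction annotation across prioritized GTF tiers.
# Matching is exact-coordinate on (chrom, strand, intron_start, intron_end);
# a junction missing from every tier is cryptic.

#' Build an exact-coordinate transcript/intron index from prioritized GTFs
#'
#' @param gtf_paths Character vector of GTF paths in priority order (tier 1
#'   first, e.g. GENCODE > RefSeq > FANTOM). Names are kept as tier labels;
#'   unnamed paths are labelled `tier1..tierN`.
#' @return An object of class `transcript_index`: per-tier maps from intron
#'   key to transcript ids, per-transcript structure (TSS, introns, first
#'   intron), and genome-wide annotated donor/acceptor site sets.
#' @export
build_transcript_index <- function(gtf_paths) {
  stopifnot(length(gtf_paths) >= 1)
  tier_names <- names(gtf_paths) %||% paste0("tier", seq_along(gtf_paths))
  tier_names[tier_names == ""] <- paste0("tier",
                                         which(tier_names == ""))

  transcripts <- list()
  tiers <- list()
  donors <- new.env(hash = TRUE, parent = emptyenv())
  acceptors <- new.env(hash = TRUE, parent = emptyenv())

  for (t in seq_along(gtf_paths)) {
    has_content <- length(readLines(gtf_paths[[t]], n = 1)) > 0
    gr <- if (has_content) rtracklayer::import(gtf_paths[[t]], format = "gtf")
    else GenomicRanges::GRanges()
    ex <- if (length(gr) == 0) gr else gr[gr$type == "exon"]
    if (length(ex) == 0) {
      tiers[[tier_names[t]]] <- new.env(hash = TRUE, parent = emptyenv())
      next
    }
    if (is.null(ex$transcript_id) || any(is.na(ex$transcript_id)))
      stop(sprintf("exon without transcript_id in %s (exon record %d)",
                   gtf_paths[[t]],
                   if (is.null(ex$transcript_id)) 1L
                   else which(is.na(ex$transcript_id))[1]))
    tier_env <- new.env(hash = TRUE, parent = emptyenv())
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(ex)),
                     start = GenomicRanges::start(ex),
                     end = GenomicRanges::end(ex),
                     strand = as.character(GenomicRanges::strand(ex)),
                     transcript_id = ex$transcript_id,
                     gene_id = ex$gene_id %||% NA_character_)
    for (tid in unique(df$transcript_id)) {
      sub <- df[df$transcript_id == tid, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
        stop(sprintf("overlapping exons within transcript %s in %s",
                     tid, gtf_paths[[t]]))
      strand <- sub$strand[1]
      chrom <- sub$chrom[1]
      tss <- if (strand == "-") max(sub$end) else min(sub$start)
      introns <- if (nrow(sub) > 1)
        cbind(start = sub$end[-nrow(sub)] + 1L, end = sub$start[-1] - 1L)
      else cbind(start = integer(0), end = integer(0))
      if (is.null(transcripts[[tid]])) {
        first <- if (nrow(introns) == 0) NA_character_
        else {
          k <- if (strand == "-") nrow(introns) else 1L
          junction_key(chrom, strand, introns[k, 1], introns[k, 2])
        }
        transcripts[[tid]] <- list(
          transcript_id = tid, gene_id = sub$gene_id[1], chrom = chrom,
          strand = strand, tss = tss, introns = introns,
          first_intron = first, tiers = tier_names[t])
      } else {
        transcripts[[tid]]$tiers <- union(transcripts[[tid]]$tiers,
                                          tier_names[t])
      }
      if (nrow(introns) > 0) {
        keys <- junction_key(chrom, strand, introns[, 1], introns[, 2])
        for (k in keys)
          assign(k, union(if (exists(k, tier_env)) get(k, tier_env), tid),
                 envir = tier_env)
        dcoord <- if (strand == "-") introns[, 2] else introns[, 1]
        acoord <- if (strand == "-") introns[, 1] else introns[, 2]
        for (k in paste(chrom, strand, dcoord)) assign(k, TRUE, donors)
        for (k in paste(chrom, strand, acoord)) assign(k, TRUE, acceptors)
      }
    }
    tiers[[tier_names[t]]] <- tier_env
  }
  structure(list(tiers = tiers, transcripts = transcripts,
                 donors = donors, acceptors = acceptors,
                 tier_names = tier_names), class = "transcript_index")
}

#' @export
print.transcript_index <- function(x, ...) {
  cat(sprintf("transcript_index: %d tiers (%s), %d transcripts\n",
              length(x$tiers), paste(x$tier_names, collapse = " > "),
              length(x$transcripts)))
  invisible(x)
}

tier_hits <- function(index, tier, chrom, strand, start, end) {
  k <- junction_key(chrom, strand, start, end)
  env <- index$tiers[[tier]]
  if (exists(k, env)) get(k, env) else character(0)
}

#' Annotate junctions by the tier priority cascade
#'
#' The first tier with an exact coordinate hit wins; its transcripts are the
#' matched set and lower tiers are ignored. Junctions absent from every tier
#' are `cryptic`. Unstranded junctions (`.`) are matched against both
#' strands; double hits are resolved toward the strand with more matched
#' transcripts, with ties keeping `.` and flagging the call.
#'
#' @param junctions A [junction_table] or a data.frame with columns `chrom`,
#'   `strand`, `start`, `end`.
#' @param index A `transcript_index`.
#' @return data.frame of annotation calls: `key source transcripts
#'   n_transcripts is_first_intron tss ambiguous_strand` plus coordinates.
#' @export
annotate_junctions <- function(junctions, index) {
  j <- if (inherits(junctions, "junction_table")) junctions$junctions
  else junctions
  out <- vector("list", nrow(j))
  for (i in seq_len(nrow(j))) {
    chrom <- j$chrom[i]; strand <- j$strand[i]
    start <- j$start[i]; end <- j$end[i]
    source <- "cryptic"; matched <- character(0)
    res_strand <- strand; ambiguous <- FALSE
    for (tier in index$tier_names) {
      if (strand == ".") {
        hp <- tier_hits(index, tier, chrom, "+", start, end)
        hm <- tier_hits(index, tier, chrom, "-", start, end)
        if (length(hp) + length(hm) > 0) {
          source <- tier
          if (length(hp) > length(hm)) { matched <- hp; res_strand <- "+" }
          else if (length(hm) > length(hp)) { matched <- hm; res_strand <- "-" }
          else { matched <- union(hp, hm); ambiguous <- TRUE }
          break
        }
      } else {
        hits <- tier_hits(index, tier, chrom, strand, start, end)
        if (length(hits) > 0) { source <- tier; matched <- hits; break }
      }
    }
    key <- junction_key(chrom, res_strand, start, end)
    first <- if (length(matched) == 0) NA else
      any(vapply(matched, function(tid)
        identical(index$transcripts[[tid]]$first_intron, key), logical(1)))
    tss <- if (length(matched) == 0) NA_integer_
    else most_upstream_tss(matched, index)
    out[[i]] <- data.frame(
      key = junction_key(chrom, j$strand[i], start, end),
      chrom = chrom, strand = res_strand, start = start, end = end,
      source = source,
      transcripts = paste(matched, collapse = ","),
      n_transcripts = length(matched),
      is_first_intron = first, tss = tss,
      gene_id = if (length(matched) > 0)
        index$transcripts[[matched[1]]]$gene_id else NA_character_,
      ambiguous_strand = ambiguous)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname annotate_junctions
#' @param chrom,strand,start,end A single junction (1-based inclusive intron).
#' @export
annotate_junction <- function(chrom, strand, start, end, index) {
  annotate_junctions(data.frame(chrom = chrom, strand = strand,
                                start = start, end = end), index)
}

#' Most upstream TSS among matched transcripts
#'
#' The TSS that is 5'-most in transcription direction: the minimum coordinate
#' on the plus strand, the maximum on the minus strand.
#'
#' @param transcripts Character vector of matched transcript ids.
#' @param index A `transcript_index`.
#' @return TSS coordinate (integer).
#' @export
most_upstream_tss <- function(transcripts, index) {
  if (length(transcripts) == 0) return(NA_integer_)
  info <- index$transcripts[transcripts]
  tss <- vapply(info, `[[`, numeric(1), "tss")
  strand <- info[[1]]$strand
  as.integer(if (strand == "-") max(tss) else min(tss))
}

#' Classify cryptic junctions by splice-site motif and event type
#'
#' The motif is the first two plus last two intronic bases in transcription
#' orientation (reverse-complemented on the minus strand); canonical motifs
#' are GT-AG, GC-AG and AT-AC. The event type compares the junction's splice
#' sites to all annotated sites: `alt_5prime` when the acceptor (3' site)
#' matches an annotated acceptor but the donor does not, `alt_3prime` for
#' the converse, `novel_pair` otherwise.
#'
#' @param calls Annotation calls from [annotate_junctions()].
#' @param genome A `DNAStringSet` or path to the genome FASTA.
#' @param index A `transcript_index` (for the annotated site sets).
#' @return `calls` with `motif`, `canonical` and `cryptic_event` columns
#'   filled for cryptic junctions (`none` for annotated ones).
#' @export
classify_cryptic <- function(calls, genome, index) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  calls$motif <- NA_character_
  calls$canonical <- NA
  calls$cryptic_event <- "none"
  canon <- c("GT-AG", "GC-AG", "AT-AC")
  for (i in which(calls$source == "cryptic")) {
    chrom <- calls$chrom[i]
    if (!chrom %in% names(genome))
      stop("chromosome not in genome: ", chrom)
    if (calls$start[i] < 1 || calls$end[i] > length(genome[[chrom]]))
      stop(sprintf("junction %s outside genome bounds", calls$key[i]))
    left <- as.character(Biostrings::subseq(genome[[chrom]],
                                            calls$start[i], calls$start[i] + 1))
    right <- as.character(Biostrings::subseq(genome[[chrom]],
                                             calls$end[i] - 1, calls$end[i]))
    rc <- function(s) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    motif <- if (calls$strand[i] == "-")
      paste0(rc(right), "-", rc(left)) else paste0(left, "-", right)
    calls$motif[i] <- motif
    calls$canonical[i] <- motif %in% canon

    strand <- calls$strand[i]
    dcoord <- if (strand == "-") calls$end[i] else calls$start[i]
    acoord <- if (strand == "-") calls$start[i] else calls$end[i]
    donor_known <- exists(paste(chrom, strand, dcoord), index$donors)
    acceptor_known <- exists(paste(chrom, strand, acoord), index$acceptors)
    calls$cryptic_event[i] <-
      if (acceptor_known && !donor_known) "alt_5prime"
      else if (donor_known && !acceptor_known) "alt_3prime"
      else "novel_pair"
  }
  calls
}

#' Proportion of junctions mapping to a first intron, by annotation tier
#'
#' For each annotation source, the fraction of junctions flagged as the
#' first intron (transcription order) of at least one matched transcript.
#' When a `splicing_result` is supplied, only differentially spliced
#' junctions (enriched classes) are counted.
#'
#' @param calls Annotation calls.
#' @param result Optional `splicing_result` to restrict to significant
#'   junctions.
#' @return data.frame `source n n_first proportion`.
#' @export
first_intron_proportions <- function(calls, result = NULL) {
  keep <- calls$source != "cryptic"
  if (!is.null(result)) {
    sig <- result$table$key[grepl("_enriched$", result$table$class)]
    keep <- keep & calls$key %in% sig
  }
  sub <- calls[keep, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(source = character(0), n = integer(0),
                      n_first = integer(0), proportion = numeric(0)))
  agg <- lapply(split(sub, sub$source), function(d)
    data.frame(source = d$source[1], n = nrow(d),
               n_first = sum(d$is_first_intron, na.rm = TRUE),
               proportion = mean(d$is_first_intron, na.rm = TRUE)))
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  res
}

#' Junction-level TSS table with condition classes
#'
#' Selects, per junction, the most upstream annotated TSS and labels it by
#' the junction's differential-splicing class: the condition name for
#' enriched junctions, `nonsig` otherwise. Used to build promoter windows.
#'
#' @param calls Annotation calls (non-cryptic rows contribute).
#' @param result A `splicing_result`.
#' @return data.frame `chrom tss strand class key` (duplicates per
#'   (TSS, class) removed).
#' @export
tss_table <- function(calls, result) {
  sub <- calls[!is.na(calls$tss), , drop = FALSE]
  cls <- result$table$class[match(sub$key, result$table$key)]
  cls[is.na(cls)] <- "non_significant"
  lab <- ifelse(grepl("_enriched$", cls), sub("_enriched$", "", cls), "nonsig")
  out <- data.frame(chrom = sub$chrom, tss = sub$tss, strand = sub$strand,
                    class = lab, key = sub$key)
  out[!duplicated(out[, c("chrom", "tss", "strand", "class")]), , drop = FALSE]
}

#' Export TSSs as BED6
#' @param tss A data.frame from [tss_table()].
#' @param path Output BED path (0-based half-open single-base intervals).
#' @export
export_tss_bed <- function(tss, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   tss$chrom, tss$tss - 1L, tss$tss, tss$class, tss$strand)
  writeLines(lines, path)
  invisible(path)
}
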