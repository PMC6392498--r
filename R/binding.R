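# Replicated peak files -> gene-level binding calls: blacklist filtering,
# summit-to-TSS assignment, control subtraction, replicate consensus, and
# promoter signal quantification.

#' Construct a peak table
#'
#' @param chrom,start,end peak interval, 0-based half-open.
#' @param summit absolute 0-based summit position (must satisfy
#'   `start <= summit < end`).
#' @param score peak score (an opaque monotone quantity: MACS2-style
#'   significance or a simulator score).
#' @param replicate_id replicate index.
#' @param condition `"FLAG"` (tagged ChIP) or `"control"`.
#' @return `data.frame` of class `"peak_set"`.
#' @export
peak_set <- function(chrom, start, end, summit, score,
                     replicate_id = 1L, condition = "FLAG") {
  pk <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), summit = as.integer(summit),
                   score = as.numeric(score),
                   replicate_id = rep_len(replicate_id, length(chrom)),
                   condition = rep_len(condition, length(chrom)),
                   stringsAsFactors = FALSE)
  if (any(pk$start > pk$summit | pk$summit >= pk$end))
    stop("need start <= summit < end")
  class(pk) <- c("peak_set", "data.frame")
  pk
}

#' Read peaks from a narrowPeak / BED file
#'
#' Reads ENCODE narrowPeak (BED6+4) via [rtracklayer::import()]. The 10th
#' column is the summit offset from the peak start; a value of -1 (summit
#' absent) falls back to the interval midpoint with a warning.
#'
#' @param path narrowPeak file.
#' @param replicate_id,condition labels attached to every peak.
#' @param score_column which field to use as the peak score: `"signalValue"`
#'   (default), `"pValue"`, `"qValue"` or `"score"`.
#' @return A `"peak_set"`.
#' @export
read_narrowpeak <- function(path, replicate_id = 1L, condition = "FLAG",
                            score_column = c("signalValue", "pValue",
                                             "qValue", "score")) {
  score_column <- match.arg(score_column)
  extra <- c(signalValue = "numeric", pValue = "numeric", qValue = "numeric",
             peak = "integer")
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  start0 <- GenomicRanges::start(gr) - 1L
  offset <- gr$peak
  missing_summit <- is.na(offset) | offset < 0
  if (any(missing_summit)) {
    warning(sum(missing_summit),
            " peak(s) without a summit; using interval midpoints")
    offset[missing_summit] <-
      (GenomicRanges::width(gr)[missing_summit]) %/% 2L
  }
  score <- switch(score_column,
                  signalValue = gr$signalValue, pValue = gr$pValue,
                  qValue = gr$qValue, score = as.numeric(gr$score))
  peak_set(as.character(GenomicRanges::seqnames(gr)), start0,
           GenomicRanges::end(gr), start0 + offset, score,
           replicate_id = replicate_id, condition = condition)
}

#' Write peaks as narrowPeak
#'
#' @param peaks a `"peak_set"`.
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   name = sprintf("peak_%d", seq_len(nrow(peaks))),
                   score = 0L, strand = ".",
                   signalValue = peaks$score, pValue = -1, qValue = -1,
                   peak = peaks$summit - peaks$start)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Remove peaks overlapping blacklist regions
#'
#' Drops every peak whose interval shares at least one base with a blacklist
#' interval; order of the surviving peaks is preserved.
#'
#' @param peaks a `"peak_set"`.
#' @param blacklist an `"interval_set"`.
#' @return The filtered `"peak_set"`.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (nrow(peaks) == 0 || nrow(blacklist) == 0) return(peaks)
  peaks[!overlaps_any(peaks, blacklist), , drop = FALSE]
}

#' Assign peaks to transcription start sites
#'
#' A peak is associated with a TSS when its summit lies within `flank` bp of
#' the TSS (window `[tss - flank, tss + flank)`, half-open). Assignment uses
#' the summit only; a summit within reach of several TSSs is assigned to all
#' of them.
#'
#' @param peaks a `"peak_set"`.
#' @param ann a `"gene_annotation"`.
#' @param flank assignment half-width in bp (default 1000).
#' @return `data.frame` with one row per (peak, transcript) assignment:
#'   `peak_row` (row index into `peaks`), `transcript_id`, `gene_id`.
#' @export
assign_peaks_to_tss <- function(peaks, ann, flank = 1000L) {
  if (nrow(ann) == 0) stop("empty annotation")
  if (nrow(peaks) == 0)
    return(data.frame(peak_row = integer(0), transcript_id = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  summits <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$summit + 1L, peaks$summit + 1L))
  windows <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$tss - flank + 1L, ann$tss + flank))
  hits <- GenomicRanges::findOverlaps(summits, windows)
  data.frame(peak_row = S4Vectors::queryHits(hits),
             transcript_id = ann$transcript_id[S4Vectors::subjectHits(hits)],
             gene_id = ann$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Genes whose promoter is hit by at least one peak
#'
#' @param peaks a `"peak_set"`.
#' @param ann a `"gene_annotation"`.
#' @param flank assignment half-width in bp.
#' @return Character vector of gene IDs (set semantics: each gene once).
#' @export
promoter_genes <- function(peaks, ann, flank = 1000L) {
  unique(assign_peaks_to_tss(peaks, ann, flank)$gene_id)
}

#' Fraction of peaks at promoters
#'
#' The proportion of peaks assigned to at least one transcript by
#' [assign_peaks_to_tss()]. Peaks on contigs absent from the annotation stay
#' in the denominator.
#'
#' @inheritParams promoter_genes
#' @return A proportion in \[0, 1\].
#' @export
promoter_fraction <- function(peaks, ann, flank = 1000L) {
  if (nrow(peaks) == 0) stop("promoter fraction undefined for an empty peak set")
  asg <- assign_peaks_to_tss(peaks, ann, flank)
  length(unique(asg$peak_row)) / nrow(peaks)
}

#' Call consensus-bound genes from replicated gene sets
#'
#' A gene is called bound when its promoter carries a peak in at least
#' `min_replicates` of the tagged-ChIP replicates and in none of the control
#' replicates (control filtering uses the union of all control replicates and
#' is applied before consensus counting).
#'
#' @param flag_reps list of character vectors: per-replicate promoter gene
#'   sets from the tagged ChIP.
#' @param control_reps list of character vectors: per-replicate gene sets
#'   from the control ChIP.
#' @param min_replicates consensus threshold (default 2).
#' @return List of class `"binding_calls"`: `bound` (character vector) and
#'   `calls`, a `data.frame` with `gene_id`, `n_flag_replicates_with_peak`,
#'   `control_hit`, `bound` for every gene seen in any replicate.
#' @export
call_bound_genes <- function(flag_reps, control_reps = list(),
                             min_replicates = 2L) {
  if (min_replicates > length(flag_reps))
    stop("min_replicates exceeds the number of FLAG replicates")
  flag_reps <- lapply(flag_reps, unique)
  control_union <- unique(unlist(control_reps))
  tab <- table(unlist(flag_reps))
  genes <- sort(union(names(tab), control_union))
  n_flag <- as.integer(tab[genes])
  n_flag[is.na(n_flag)] <- 0L
  control_hit <- genes %in% control_union
  bound <- n_flag >= min_replicates & !control_hit
  calls <- data.frame(gene_id = genes,
                      n_flag_replicates_with_peak = n_flag,
                      control_hit = control_hit, bound = bound,
                      stringsAsFactors = FALSE)
  out <- list(bound = genes[bound], calls = calls,
              min_replicates = min_replicates,
              n_flag_replicates = length(flag_reps),
              n_control_replicates = length(control_reps))
  class(out) <- "binding_calls"
  out
}

#' @export
print.binding_calls <- function(x, ...) {
  cat(sprintf(
    "Binding calls: %d bound gene(s) (>= %d of %d replicates, %d control rep(s))\n",
    length(x$bound), x$min_replicates, x$n_flag_replicates,
    x$n_control_replicates))
  cat(sprintf("  genes seen in any replicate: %d; control-filtered: %d\n",
              nrow(x$calls), sum(x$calls$control_hit)))
  invisible(x)
}

#' Write binding calls as TSV
#'
#' @param calls a `"binding_calls"` object.
#' @param path output TSV for the per-gene table.
#' @param list_path optional newline-delimited file for the bound-gene list.
#' @export
write_binding_calls <- function(calls, path, list_path = NULL) {
  write.table(calls$calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(list_path)) writeLines(calls$bound, list_path)
  invisible(path)
}

#' Input-subtracted promoter read density
#'
#' Normalizes promoter read counts to reads per million and subtracts the
#' normalized input-chromatin count:
#' `count / library_size * 1e6 - input_count / input_library_size * 1e6`.
#' Negative values are permitted (not clipped). When `ann` is supplied the
#' counts are taken as transcript-level and are summed to gene level before
#' normalization.
#'
#' @param counts named numeric vector of promoter read counts (per gene, or
#'   per transcript when `ann` is given).
#' @param library_size total read count of the ChIP library.
#' @param input_counts named numeric vector of input-chromatin counts over
#'   the same names.
#' @param input_library_size total read count of the input library.
#' @param ann optional `"gene_annotation"` used to sum transcript counts by
#'   gene.
#' @return Named numeric vector of input-subtracted rpm values.
#' @export
promoter_read_density <- function(counts, library_size, input_counts,
                                  input_library_size, ann = NULL) {
  if (library_size <= 0 || input_library_size <= 0)
    stop("library sizes must be positive")
  if (any(counts < 0) || any(input_counts < 0))
    stop("negative read counts")
  if (!is.null(ann)) {
    map <- setNames(ann$gene_id, ann$transcript_id)
    sum_by_gene <- function(v) {
      g <- map[names(v)]
      if (anyNA(g)) stop("transcripts not in annotation: ",
                         paste(names(v)[is.na(g)], collapse = ", "))
      tapply(v, g, sum)
    }
    counts <- sum_by_gene(counts)
    input_counts <- sum_by_gene(input_counts)
  }
  shared <- intersect(names(counts), names(input_counts))
  rpm <- counts[shared] / library_size * 1e6 -
    input_counts[shared] / input_library_size * 1e6
  setNames(as.numeric(rpm), shared)
}
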