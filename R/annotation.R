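#' @importFrom stats median rnorm rpois runif setNames
#' @importFrom utils read.table write.table head modifyList
#' @importFrom methods is
NULL

# Internal coordinate convention, used everywhere in the package:
# 0-based, half-open [start, end). GTF input (1-based, closed) is converted on
# load; BED-dialect input is native. A TSS is a single 0-based position.

#' Build a gene annotation table
#'
#' Constructs the transcript-level annotation that anchors every promoter
#' window in the pipeline. Each row is one transcript with a resolved
#' transcription start site (TSS).
#'
#' @param transcript_id,gene_id character vectors, one entry per transcript.
#' @param chrom chromosome name per transcript.
#' @param strand `"+"` or `"-"` per transcript.
#' @param tss 0-based TSS position per transcript.
#' @param biotype transcript biotype (default `"protein_coding"`).
#' @param seqlengths optional named integer vector of chromosome lengths; when
#'   supplied, TSS positions are validated against it and promoter windows are
#'   clipped to chromosome bounds.
#' @return A `data.frame` of class `"gene_annotation"` with columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `tss`, `biotype`.
#' @export
gene_annotation <- function(transcript_id, gene_id, chrom, strand, tss,
                            biotype = "protein_coding", seqlengths = NULL) {
  ann <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    tss = as.integer(tss),
    biotype = rep_len(as.character(biotype), length(transcript_id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(ann$transcript_id[duplicated(ann$transcript_id)]),
               collapse = ", "))
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(ann$tss < 0)) stop("tss must be >= 0")
  if (!is.null(seqlengths)) {
    len <- seqlengths[ann$chrom]
    bad <- !is.na(len) & ann$tss >= len
    if (any(bad))
      stop("tss beyond chromosome end for: ",
           paste(ann$transcript_id[bad], collapse = ", "))
    attr(ann, "seqlengths") <- seqlengths
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Load a gene annotation from GTF or TSV
#'
#' Reads transcript records and resolves each transcript's TSS: for a `+`
#' strand transcript the 0-based start, for a `-` strand transcript the
#' 0-based position of the last base. GTF coordinates (1-based, closed) are
#' converted on load; the TSV dialect (columns `transcript_id`, `gene_id`,
#' `chrom`, `strand`, `tss`) is already 0-based.
#'
#' @param path a `.gtf` file (Ensembl attribute dialect, read via
#'   [rtracklayer::import()]) or a tab-separated table.
#' @param biotype_filter keep only transcripts with this biotype
#'   (default `"protein_coding"`); `NULL` keeps all.
#' @param tss_override optional `data.frame` with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `tss_1based`: manually curated TSSs appended
#'   to the annotation. Override positions are 1-based (the convention of
#'   curated genome-browser coordinates) and converted on load.
#' @param seqlengths optional named chromosome lengths (see [gene_annotation()]).
#' @return A `"gene_annotation"` object. Records with an unknown strand are
#'   dropped with a warning reporting how many were rejected.
#' @export
load_annotation <- function(path, biotype_filter = "protein_coding",
                            tss_override = NULL, seqlengths = NULL) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) stop("malformed GTF '", path, "': ",
                                            conditionMessage(e)))
    gr <- gr[gr$type == "transcript"]
    df <- data.frame(
      transcript_id = gr$transcript_id,
      gene_id = gr$gene_id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start1 = GenomicRanges::start(gr),
      end1 = GenomicRanges::end(gr),
      biotype = if (!is.null(gr$transcript_biotype)) gr$transcript_biotype
                else NA_character_,
      stringsAsFactors = FALSE
    )
    n_bad <- sum(!df$strand %in% c("+", "-"))
    if (n_bad > 0) {
      warning(n_bad, " transcript record(s) with unknown strand rejected")
      df <- df[df$strand %in% c("+", "-"), , drop = FALSE]
    }
    df$tss <- ifelse(df$strand == "+", df$start1 - 1L, df$end1 - 1L)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("transcript_id", "gene_id", "chrom", "strand", "tss")
    if (!all(need %in% names(df)))
      stop("annotation TSV '", path, "' lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    if (is.null(df$biotype)) df$biotype <- "protein_coding"
    n_bad <- sum(!df$strand %in% c("+", "-"))
    if (n_bad > 0) {
      warning(n_bad, " record(s) with unknown strand rejected")
      df <- df[df$strand %in% c("+", "-"), , drop = FALSE]
    }
  }
  if (!is.null(biotype_filter))
    df <- df[!is.na(df$biotype) & df$biotype %in% biotype_filter, ,
             drop = FALSE]
  if (!is.null(tss_override) && nrow(tss_override) > 0) {
    ov <- data.frame(
      transcript_id = tss_override$transcript_id,
      gene_id = tss_override$gene_id,
      chrom = tss_override$chrom,
      strand = tss_override$strand,
      tss = as.integer(tss_override$tss_1based) - 1L,
      biotype = if (is.null(biotype_filter)) "protein_coding"
                else biotype_filter[1],
      stringsAsFactors = FALSE
    )
    df <- rbind(df[, names(ov)], ov)
  }
  gene_annotation(df$transcript_id, df$gene_id, df$chrom, df$strand, df$tss,
                  df$biotype, seqlengths = seqlengths)
}

#' Write a gene annotation as TSV
#'
#' Inverse of the TSV branch of [load_annotation()]: the retained fields
#' round-trip exactly.
#'
#' @param ann a `"gene_annotation"` object.
#' @param path output file.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann[, c("transcript_id", "gene_id", "chrom", "strand",
                      "tss", "biotype")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Create an interval set
#'
#' Holds genomic intervals (blacklist regions, CpG islands, ...) in 0-based
#' half-open coordinates.
#'
#' @param chrom,start,end interval coordinates, 0-based half-open.
#' @param label what the intervals are (`"blacklist"`, `"CGI"`, `"other"`).
#' @return A `data.frame` of class `"interval_set"`.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), label = "other") {
  iv <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (any(iv$start >= iv$end)) stop("intervals require start < end")
  attr(iv, "label") <- label
  class(iv) <- c("interval_set", "data.frame")
  iv
}

#' Read a BED file into an interval set
#'
#' @param path a 3+ column BED file (0-based half-open, BED native).
#' @param label label for the set (see [interval_set()]).
#' @export
read_bed <- function(path, label = "other") {
  gr <- rtracklayer::import(path, format = "bed")
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               label = label)
}

#' Write an interval set as 3-column BED
#'
#' @param iv an `"interval_set"`.
#' @param path output file.
#' @export
write_bed <- function(iv, path) {
  write.table(iv[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Overlap of query intervals (0-based half-open data.frame chrom/start/end)
# with subject intervals; >=1 shared base. Returns logical per query row.
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  q <- GenomicRanges::GRanges(query$chrom,
                              IRanges::IRanges(query$start + 1L, query$end))
  s <- GenomicRanges::GRanges(subject$chrom,
                              IRanges::IRanges(subject$start + 1L, subject$end))
  IRanges::overlapsAny(q, s)
}

#' Promoter window around a TSS
#'
#' The window `[tss - flank, tss + flank)`, clipped to chromosome bounds when
#' lengths are known. Strand-independent: `+` and `-` transcripts with the
#' same TSS get identical windows.
#'
#' @param tss 0-based TSS position(s).
#' @param flank half-width in bp (default 1000, i.e. the 2 kb promoter window).
#' @param chrom_length optional chromosome length(s) for clipping.
#' @return `data.frame` with columns `start`, `end` (0-based half-open).
#' @export
promoter_window <- function(tss, flank = 1000L, chrom_length = NULL) {
  stopifnot(flank > 0)
  start <- pmax(0L, as.integer(tss) - as.integer(flank))
  end <- as.integer(tss) + as.integer(flank)
  if (!is.null(chrom_length)) end <- pmin(end, as.integer(chrom_length))
  data.frame(start = start, end = end)
}

#' Promoter windows for every transcript of an annotation
#'
#' @param ann a `"gene_annotation"`.
#' @param flank half-width in bp.
#' @return `data.frame` with `transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`.
#' @export
promoter_windows <- function(ann, flank = 1000L) {
  sl <- attr(ann, "seqlengths")
  w <- promoter_window(ann$tss, flank,
                       chrom_length = if (is.null(sl)) NULL else sl[ann$chrom])
  data.frame(transcript_id = ann$transcript_id, gene_id = ann$gene_id,
             chrom = ann$chrom, start = w$start, end = w$end,
             stringsAsFactors = FALSE)
}

#' Does a gene have a CpG-island promoter?
#'
#' A gene has a CGI promoter if a CGI interval overlaps (by at least one base)
#' the 2 kb window surrounding the TSS of at least one of its transcripts.
#'
#' @param gene_id gene identifier(s).
#' @param ann a `"gene_annotation"`.
#' @param cgi an `"interval_set"` of CpG islands.
#' @param flank promoter half-width (default 1000 bp).
#' @return Named logical, one entry per requested gene.
#' @export
has_cgi_promoter <- function(gene_id, ann, cgi, flank = 1000L) {
  unknown <- setdiff(gene_id, ann$gene_id)
  if (length(unknown) > 0)
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  w <- promoter_windows(ann, flank)
  hit <- overlaps_any(w, cgi)
  per_gene <- tapply(hit, w$gene_id, any)
  setNames(as.logical(per_gene[gene_id]), gene_id)
}
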