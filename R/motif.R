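# IUPAC nucleotide classes. A subject-sequence N matches nothing, including a
# motif N: the scan is a "perfect match" scan in which only the four
# unambiguous bases can satisfy a motif position.
IUPAC_CLASS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of an IUPAC pattern or sequence
#'
#' @param x a character string over the IUPAC alphabet.
#' @return The reverse complement, ambiguity codes complemented correctly
#'   (delegates to [Biostrings::reverseComplement()]).
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_motif <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CLASS))
  if (length(bad) > 0)
    stop("invalid IUPAC code(s) in motif: ", paste(bad, collapse = ", "))
  chars
}

SUBJECT_ALPHABET <- c("A", "C", "G", "T", "N")

# Start positions (0-based) of IUPAC pattern matches on one strand.
# seq_codes are integer codes into SUBJECT_ALPHABET; for each motif position
# a logical lookup of which subject letters satisfy it, vectorized over all
# start positions.
scan_one_strand <- function(seq_codes, motif_chars) {
  n <- length(seq_codes)
  L <- length(motif_chars)
  if (L > n) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    allowed <- SUBJECT_ALPHABET %in% IUPAC_CLASS[[motif_chars[j]]]
    ok <- ok & allowed[seq_codes[j:(j + n - L)]]
    if (!any(ok)) return(integer(0))
  }
  which(ok) - 1L
}

#' Scan a sequence for a degenerate motif
#'
#' Finds every occurrence of an IUPAC motif (default-relevant example:
#' `CNCCTCAG`). Matching is "perfect match": literal motif positions must
#' match exactly, an ambiguity code in the motif matches any base of its
#' class, and an `N` in the subject sequence matches nothing. Overlapping
#' matches are all reported.
#'
#' @param seq a nucleotide string over `A/C/G/T/N` (case-insensitive).
#' @param motif an IUPAC pattern string.
#' @param both_strands if `TRUE` (default) the reverse complement of the
#'   pattern is also scanned; such hits are reported on the `-` strand at the
#'   forward (0-based) coordinate of the match start.
#' @return `data.frame` with columns `pos` (0-based match start on the forward
#'   sequence) and `strand`, sorted by position.
#' @export
scan_motif <- function(seq, motif = "CNCCTCAG", both_strands = TRUE) {
  motif_chars <- check_motif(motif)
  seq_chars <- strsplit(toupper(seq), "")[[1]]
  seq_codes <- match(seq_chars, SUBJECT_ALPHABET)
  if (anyNA(seq_codes)) stop("sequence must be over A/C/G/T/N")
  pos <- scan_one_strand(seq_codes, motif_chars)
  hits <- data.frame(pos = pos,
                     strand = rep("+", length(pos)),
                     stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- check_motif(reverse_complement(paste(motif_chars, collapse = "")))
    pos_m <- scan_one_strand(seq_codes, rc)
    hits <- rbind(hits, data.frame(pos = pos_m,
                                   strand = rep("-", length(pos_m)),
                                   stringsAsFactors = FALSE))
  }
  hits[order(hits$pos, hits$strand), , drop = FALSE]
}

#' Count motif instances in promoter windows
#'
#' Counts motif occurrences (both strands by default) in the 2 kb window
#' surrounding each transcript's TSS; the per-gene count is the maximum over
#' the gene's transcripts. Windows extending past the sequence ends are
#' clipped with a warning.
#'
#' @param ann a `"gene_annotation"`.
#' @param genome named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param motif IUPAC pattern (default `"CNCCTCAG"`).
#' @param flank promoter half-width in bp (default 1000).
#' @param both_strands scan both strands (default `TRUE`).
#' @param gene_id optional subset of genes; default all genes in `ann`.
#' @return Named integer vector of promoter motif counts per gene.
#' @export
count_promoter_motifs <- function(ann, genome, motif = "CNCCTCAG",
                                  flank = 1000L, both_strands = TRUE,
                                  gene_id = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  keep <- if (is.null(gene_id)) ann else ann[ann$gene_id %in% gene_id, ]
  if (!is.null(gene_id)) {
    unknown <- setdiff(gene_id, ann$gene_id)
    if (length(unknown) > 0)
      stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  clipped <- FALSE
  per_tx <- vapply(seq_len(nrow(keep)), function(i) {
    chrom_seq <- genome[[keep$chrom[i]]]
    if (is.null(chrom_seq)) stop("no sequence for chromosome ", keep$chrom[i])
    len <- nchar(chrom_seq)
    s <- keep$tss[i] - flank
    e <- keep$tss[i] + flank
    if (s < 0 || e > len) clipped <<- TRUE
    s <- max(0L, s); e <- min(len, e)
    nrow(scan_motif(substr(chrom_seq, s + 1L, e), motif, both_strands))
  }, integer(1))
  if (clipped) warning("promoter window(s) clipped at sequence boundary")
  counts <- tapply(per_tx, keep$gene_id, max)
  out <- setNames(as.integer(counts), names(counts))
  if (!is.null(gene_id)) out <- out[gene_id]
  out
}

#' Motif counts in summit windows
#'
#' Counts motif occurrences in the 100 bp window `[summit - 50, summit + 50)`
#' around each peak summit.
#'
#' @param peaks a peak `data.frame` (see [read_narrowpeak()]) with `chrom` and
#'   `summit` columns.
#' @param genome named character vector of chromosome sequences or a
#'   `DNAStringSet`.
#' @param motif IUPAC pattern.
#' @param halfwidth bases on each side of the summit (default 50).
#' @param both_strands scan both strands (default `TRUE`).
#' @return Integer vector, one count per peak.
#' @export
count_summit_motifs <- function(peaks, genome, motif = "CNCCTCAG",
                                halfwidth = 50L, both_strands = TRUE) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  vapply(seq_len(nrow(peaks)), function(i) {
    chrom_seq <- genome[[peaks$chrom[i]]]
    len <- nchar(chrom_seq)
    s <- max(0L, peaks$summit[i] - halfwidth)
    e <- min(len, peaks$summit[i] + halfwidth)
    nrow(scan_motif(substr(chrom_seq, s + 1L, e), motif, both_strands))
  }, integer(1))
}

#' Correlation of summit motif count with peak score
#'
#' Spearman rank correlation (average ranks for ties) between per-peak motif
#' counts and peak scores, with a permutation p-value: scores are permuted
#' `n_permutations` times and `p = (1 + #(|rho*| >= |rho|)) / (1 + n)`.
#'
#' @param counts integer motif counts, one per peak.
#' @param scores numeric peak scores, same length.
#' @param n_permutations number of permutations (>= 100).
#' @param seed integer seed for the permutation generator.
#' @return List with `rho`, `p`, `n_peaks`, `n_permutations`.
#' @export
motif_score_correlation <- function(counts, scores, n_permutations = 10000L,
                                    seed = 1L) {
  if (length(counts) != length(scores)) stop("length mismatch")
  if (length(counts) < 10) stop("need at least 10 peaks")
  if (n_permutations < 100) stop("need at least 100 permutations")
  if (length(unique(counts)) < 2 || length(unique(scores)) < 2)
    stop("correlation undefined for constant input")
  rc <- rank(counts)
  rs <- rank(scores)
  rho <- stats::cor(rc, rs)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    if (abs(stats::cor(rc, sample(rs))) >= abs(rho)) hits <- hits + 1L
  }
  list(rho = rho, p = (1 + hits) / (1 + n_permutations),
       n_peaks = length(counts), n_permutations = n_permutations)
}

#' Stratify values by promoter motif count
#'
#' The dose-response view: genes (or peaks) are grouped by motif count, counts
#' above `max_stratum` pooled into the top stratum, and each stratum is
#' summarized by median and IQR. Adjacent strata are compared with
#' Mann-Whitney U tests.
#'
#' @param values named numeric vector (e.g. log2 fold changes or binding
#'   signal per gene).
#' @param counts named integer motif counts over the same names.
#' @param max_stratum top stratum (default 5; the pooled stratum is
#'   `">= max_stratum"` when pooling occurs).
#' @param alternative alternative for adjacent-stratum tests, passed to
#'   [mann_whitney()] (default two-sided).
#' @return List with `strata` (`data.frame`: stratum, n, median, q1, q3),
#'   `adjacent_p` (Mann-Whitney p for each adjacent pair; `NA` when a stratum
#'   is empty), and `monotone_medians` (`TRUE` when non-empty stratum medians
#'   are non-decreasing).
#' @export
stratify_by_motif_count <- function(values, counts, max_stratum = 5L,
                                    alternative = "two.sided") {
  shared <- intersect(names(values), names(counts))
  v <- values[shared]
  k <- pmin(as.integer(counts[shared]), max_stratum)
  levels <- 0:max_stratum
  groups <- lapply(levels, function(s) v[k == s])
  strata <- data.frame(
    stratum = levels,
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, function(g) if (length(g)) median(g) else NA_real_,
                    numeric(1)),
    q1 = vapply(groups, function(g)
      if (length(g)) unname(stats::quantile(g, 0.25)) else NA_real_, numeric(1)),
    q3 = vapply(groups, function(g)
      if (length(g)) unname(stats::quantile(g, 0.75)) else NA_real_, numeric(1))
  )
  adjacent_p <- vapply(seq_len(length(levels) - 1L), function(i) {
    a <- groups[[i]]; b <- groups[[i + 1L]]
    if (length(a) == 0 || length(b) == 0) return(NA_real_)
    mann_whitney(a, b, alternative = alternative)$p
  }, numeric(1))
  names(adjacent_p) <- paste(head(levels, -1), levels[-1], sep = "_vs_")
  med <- strata$median[!is.na(strata$median)]
  list(strata = strata, adjacent_p = adjacent_p,
       monotone_medians = all(diff(med) >= 0))
}
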