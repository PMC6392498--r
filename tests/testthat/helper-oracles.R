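# Independent brute-force oracles. Deliberately naive implementations,
# written without reference to the package internals, used to pin down the
# behaviour of the fast paths.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_rc <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# character-by-character double loop; subject N matches nothing
oracle_scan_strand <- function(seq, motif) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  hits <- integer(0)
  if (length(m) > length(s)) return(hits)
  for (i in seq_len(length(s) - length(m) + 1L)) {
    ok <- TRUE
    for (j in seq_along(m)) {
      if (!(s[i + j - 1L] %in% ORACLE_IUPAC[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

oracle_scan <- function(seq, motif, both_strands = TRUE) {
  fwd <- oracle_scan_strand(seq, motif)
  out <- data.frame(pos = fwd, strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    neg <- oracle_scan_strand(seq, oracle_rc(motif))
    out <- rbind(out, data.frame(pos = neg, strand = rep("-", length(neg)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$pos, out$strand), , drop = FALSE]
}

# all-pairs summit-to-TSS distance scan
oracle_assign <- function(peaks, ann, flank = 1000L) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(ann))) {
      if (peaks$chrom[i] == ann$chrom[j] &&
          peaks$summit[i] >= ann$tss[j] - flank &&
          peaks$summit[i] < ann$tss[j] + flank) {
        rows[[length(rows) + 1L]] <-
          data.frame(peak_row = i, transcript_id = ann$transcript_id[j],
                     gene_id = ann$gene_id[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(peak_row = integer(0), transcript_id = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# O(n*m) interval overlap (0-based half-open, >=1 shared base)
oracle_overlaps <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

oracle_hypergeom_over <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

oracle_hypergeom_under <- function(N, K, n, k) {
  kk <- max(0, K + n - N):k
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# two-tailed Fisher p by full enumeration over tables with fixed margins
oracle_fisher_two_tail <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_range <- max(0, r1 + c1 - N):min(r1, c1)
  prob <- vapply(a_range, function(a)
    choose(c1, a) * choose(N - c1, r1 - a) / choose(N, r1), numeric(1))
  p_obs <- prob[a_range == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# exact Mann-Whitney by enumeration of all group assignments of the combined
# sample; alternative is phrased for y ("greater" means y tends larger)
oracle_mw <- function(x, y, alternative = "two.sided") {
  u_stat <- function(xx, yy)
    sum(outer(yy, xx, ">")) + 0.5 * sum(outer(yy, xx, "=="))
  comb <- c(x, y)
  n <- length(x)
  obs <- u_stat(x, y)
  idx <- utils::combn(length(comb), n)
  us <- apply(idx, 2, function(ii) u_stat(comb[ii], comb[-ii]))
  switch(alternative,
         greater = mean(us >= obs),
         less = mean(us <= obs),
         two.sided = min(1, 2 * min(mean(us >= obs), mean(us <= obs))))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# sample one element of a vector (safe for length-1 vectors)
pick <- function(v) v[sample.int(length(v), 1L)]

tiny_ann <- function(tss, gene_id = sprintf("g%d", seq_along(tss)),
                     transcript_id = paste0(gene_id, ".t1"),
                     chrom = "chr1", strand = "+", ...) {
  gene_annotation(transcript_id, gene_id, chrom, strand, tss, ...)
}

small_sim_config <- function(...) {
  args <- modifyList(list(n_genes = 150L, chrom_length = 4e5,
                          spurious_peak_rate = 15, n_downregulated = 25L),
                     list(...))
  do.call(sim_config, args)
}
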