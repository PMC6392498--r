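# Expression-side logic: TPM aggregation, expressed filter, the plumbing DE
# stage standing in for a count-model fit, bound-by-direction classification,
# fold-change concordance, and the nine-tissue testis-bias classifier.

#' Renormalize columns to TPM semantics
#'
#' Rescales every column of a non-negative matrix to sum to 1e6.
#'
#' @param m numeric matrix (genes x samples).
#' @return The renormalized matrix.
#' @export
renormalize_tpm <- function(m) {
  if (any(m < 0)) stop("negative expression values")
  cs <- colSums(m)
  if (any(cs == 0)) stop("cannot renormalize an all-zero column")
  sweep(m, 2, cs / 1e6, "/")
}

#' Aggregate transcript TPM to gene level
#'
#' Sums transcript abundances by gene and renormalizes each column to TPM
#' units (sum 1e6).
#'
#' @param transcript_tpm numeric matrix, transcripts x samples, rownames are
#'   transcript IDs.
#' @param ann a `"gene_annotation"` mapping transcripts to genes.
#' @return Gene x sample TPM matrix.
#' @export
gene_tpm <- function(transcript_tpm, ann) {
  map <- setNames(ann$gene_id, ann$transcript_id)
  g <- map[rownames(transcript_tpm)]
  if (anyNA(g))
    stop("transcripts not in annotation: ",
         paste(rownames(transcript_tpm)[is.na(g)], collapse = ", "))
  renormalize_tpm(rowsum(transcript_tpm, group = g))
}

#' Expressed genes
#'
#' Genes whose abundance reaches `threshold` in at least one sample
#' (inclusive: a gene at exactly the threshold is expressed).
#'
#' @param m gene x sample TPM matrix.
#' @param threshold TPM threshold (default 1).
#' @param op comparison operator, `">="` (default) or `">"`.
#' @return Character vector of expressed gene IDs.
#' @export
expressed_genes <- function(m, threshold = 1, op = c(">=", ">")) {
  op <- match.arg(op)
  mx <- apply(m, 1, max)
  keep <- if (op == ">=") mx >= threshold else mx > threshold
  rownames(m)[keep]
}

#' Plumbing differential expression test
#'
#' A two-group test on the log2(TPM + 1) scale, standing in behaviourally for
#' a count-model DE fit. Two pieces of that behaviour matter and are kept:
#'
#' * size factors — by default the samples are first put on a common scale
#'   with a median-of-ratios offset: per sample, the median across genes of
#'   `log2(x+1) - reference` is subtracted, where the reference is the
#'   per-gene mean over all samples. Without this the compositional
#'   renormalization of TPM columns converts any large planted up-regulated
#'   mass into an apparent global down-shift of every null gene
#'   (`normalize = "none"` skips it);
#' * dispersion sharing — with 2-3 samples per group a per-gene variance
#'   estimate is hopelessly noisy, so the default method is the moderated
#'   t-statistic of [limma::eBayes()] (variance shrunk across genes), the
#'   standard small-sample treatment in this field. `method = "welch"` gives
#'   an unmoderated per-gene Welch t-test instead.
#'
#' @param m gene x sample TPM matrix.
#' @param group1,group2 character vectors of column names (each of size >= 2);
#'   `log2fc` is group2 over group1.
#' @param alpha FDR threshold for calling a direction (default 0.05).
#' @param method `"moderated"` (default) or `"welch"`.
#' @param normalize `"median_ratio"` (default) or `"none"`.
#' @return `data.frame` with `gene_id`, `log2fc`, `p`, `q` (BH-adjusted) and
#'   `direction` (`"up"`, `"down"`, `"ns"`). Genes with zero variance and
#'   equal means get `p = 1`.
#' @export
simple_de_test <- function(m, group1, group2, alpha = 0.05,
                           method = c("moderated", "welch"),
                           normalize = c("median_ratio", "none")) {
  method <- match.arg(method)
  normalize <- match.arg(normalize)
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 samples")
  missing_cols <- setdiff(c(group1, group2), colnames(m))
  if (length(missing_cols) > 0)
    stop("samples not in matrix: ", paste(missing_cols, collapse = ", "))
  lg <- log2(m[, c(group1, group2), drop = FALSE] + 1)
  if (normalize == "median_ratio") {
    ref <- rowMeans(lg)
    offsets <- apply(lg - ref, 2, median)
    lg <- sweep(lg, 2, offsets, "-")
  }
  a <- lg[, group1, drop = FALSE]
  b <- lg[, group2, drop = FALSE]
  log2fc <- rowMeans(b) - rowMeans(a)
  if (method == "moderated") {
    design <- cbind(intercept = 1,
                    grp2 = as.integer(colnames(lg) %in% group2))
    fit <- limma::lmFit(lg, design)
    if (all(fit$sigma < 1e-10)) {
      p <- ifelse(abs(log2fc) < 1e-10, 1, 0)
    } else {
      fit <- limma::eBayes(fit)
      p <- fit$p.value[, "grp2"]
    }
  } else {
    p <- vapply(seq_len(nrow(lg)), function(i) {
      xi <- a[i, ]; yi <- b[i, ]
      if (stats::var(xi) == 0 && stats::var(yi) == 0) {
        return(if (mean(yi) == mean(xi)) 1 else 0)
      }
      tryCatch(stats::t.test(yi, xi)$p.value, error = function(e) 1)
    }, numeric(1))
  }
  q <- bh_fdr(p)
  direction <- ifelse(q < alpha & log2fc > 0, "up",
                      ifelse(q < alpha & log2fc < 0, "down", "ns"))
  data.frame(gene_id = rownames(m), log2fc = log2fc, p = p, q = q,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read / write a DE table
#'
#' TSV with columns `gene_id`, `log2fc`, `p`, `q` (and optionally
#' `direction`), so externally computed DE results can be dropped into the
#' pipeline.
#'
#' @param path TSV file.
#' @param alpha FDR threshold used to (re)derive `direction` when absent.
#' @return A DE `data.frame` as from [simple_de_test()].
#' @export
read_de_table <- function(path, alpha = 0.05) {
  de <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p", "q")
  if (!all(need %in% names(de)))
    stop("DE table lacks columns: ", paste(setdiff(need, names(de)),
                                           collapse = ", "))
  if (is.null(de$direction))
    de$direction <- ifelse(de$q < alpha & de$log2fc > 0, "up",
                           ifelse(de$q < alpha & de$log2fc < 0, "down", "ns"))
  de
}

#' @rdname read_de_table
#' @param de a DE `data.frame`.
#' @export
write_de_table <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify genes by binding and expression change
#'
#' Restricts to expressed genes, flags each as bound/up/down, derives the
#' activated set (bound and up), and tabulates the bound-by-direction 2x2
#' contingency table over differentially expressed genes with its Fisher
#' exact test and odds ratio (Woolf CI; Haldane correction, flagged, when a
#' cell is zero).
#'
#' @param bound character vector of bound gene IDs.
#' @param de DE table (see [simple_de_test()]).
#' @param expressed character vector of expressed gene IDs.
#' @return List of class `"gene_classification"`: `flags` (per-gene logical
#'   `data.frame`), `activated`, `bound_down`, `table` (2x2: bound/unbound x
#'   up/down), `fraction_up` (per stratum), `fraction_activated_of_up`,
#'   `fisher` (a `"fisher_result"` or `NULL` when a margin is empty, then
#'   `degenerate = TRUE`).
#' @export
classify_and_tabulate <- function(bound, de, expressed) {
  de <- de[de$gene_id %in% expressed, , drop = FALSE]
  flags <- data.frame(
    gene_id = de$gene_id,
    expressed = TRUE,
    bound = de$gene_id %in% bound,
    up = de$direction == "up",
    down = de$direction == "down",
    stringsAsFactors = FALSE
  )
  flags$activated <- flags$bound & flags$up
  tab <- matrix(c(sum(flags$bound & flags$up), sum(flags$bound & flags$down),
                  sum(!flags$bound & flags$up),
                  sum(!flags$bound & flags$down)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("bound", "unbound"), c("up", "down")))
  row_n <- rowSums(tab)
  fraction_up <- ifelse(row_n > 0, tab[, "up"] / row_n, NA_real_)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  fisher <- if (!degenerate) fisher_exact(tab) else NULL
  n_up <- sum(flags$up)
  out <- list(flags = flags,
              activated = flags$gene_id[flags$activated],
              bound_down = flags$gene_id[flags$bound & flags$down],
              table = tab,
              fraction_up = fraction_up,
              fraction_activated_of_up =
                if (n_up > 0) sum(flags$activated) / n_up else NA_real_,
              fisher = fisher, degenerate = degenerate)
  class(out) <- "gene_classification"
  out
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("Bound x direction classification (expressed, differentially expressed genes)\n")
  print(x$table)
  cat(sprintf("  activated (bound & up): %d; activated/up = %.1f%%\n",
              length(x$activated), 100 * x$fraction_activated_of_up))
  if (!is.null(x$fisher)) print(x$fisher)
  else cat("  degenerate table: odds ratio undefined\n")
  invisible(x)
}

#' Write a gene classification as TSV
#'
#' @param cls a `"gene_classification"`.
#' @param path output file.
#' @export
write_classification <- function(cls, path) {
  write.table(cls$flags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fold-change concordance between two DE tables
#'
#' Pearson correlation of log2 fold changes over the genes present in both
#' tables.
#'
#' @param de_a,de_b DE tables.
#' @return Pearson r.
#' @export
fold_change_concordance <- function(de_a, de_b) {
  shared <- intersect(de_a$gene_id, de_b$gene_id)
  if (length(shared) < 3) stop("need at least 3 shared genes")
  a <- de_a$log2fc[match(shared, de_a$gene_id)]
  b <- de_b$log2fc[match(shared, de_b$gene_id)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant fold-change vector")
  stats::cor(a, b)
}

#' Testis-biased genes from a multi-tissue panel
#'
#' A gene is testis-biased when its testis expression exceeds half of its
#' summed expression across all tissues (strict inequality). When a tissue
#' has replicate columns, the per-tissue value is the median across
#' individuals.
#'
#' @param panel gene x sample TPM matrix.
#' @param tissues character vector of tissue labels, one per column; by
#'   default derived from column names of the form `tissue.rep`.
#' @param testis name of the testis tissue (default `"testis"`).
#' @return Named logical vector over genes.
#' @export
testis_bias <- function(panel, tissues = NULL, testis = "testis") {
  if (is.null(tissues)) tissues <- sub("\\..*$", "", colnames(panel))
  if (!testis %in% tissues) stop("no '", testis, "' column in the panel")
  per_tissue <- vapply(unique(tissues), function(t) {
    apply(panel[, tissues == t, drop = FALSE], 1, median)
  }, numeric(nrow(panel)))
  if (is.null(dim(per_tissue)))
    per_tissue <- matrix(per_tissue, nrow = 1,
                         dimnames = list(rownames(panel), unique(tissues)))
  total <- rowSums(per_tissue)
  biased <- per_tissue[, testis] > 0.5 * total
  setNames(as.logical(biased), rownames(panel))
}
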