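# Statistical toolbox. p-values at the edge of double precision are carried
# as log10(p) alongside the (possibly underflowing) p, since gene-list
# overlaps of thousands of genes routinely produce p below 1e-300.

log10_from_lnp <- function(lnp) lnp / log(10)

#' One-tailed hypergeometric overlap test
#'
#' Tests the overlap `k` between a set of size `K` and a set of size `n`
#' drawn from a universe of size `N`. `p_over = P[X >= k]` and
#' `p_under = P[X <= k]` for `X ~ Hypergeometric(N, K, n)`, computed in log
#' space so extreme depletions/enrichments keep a finite `log10_p`.
#'
#' @param N universe size.
#' @param K size of the first set.
#' @param n size of the second set.
#' @param k overlap size.
#' @return List of class `"overlap_test"`: `N`, `K`, `n`, `k`, `expected`,
#'   `fold` (`k / (K n / N)`), `p_over`, `p_under`, `log10_p_over`,
#'   `log10_p_under`.
#' @export
hypergeom_overlap <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || k < max(0, K + n - N))
    stop("inconsistent counts: need max(0, K+n-N) <= k <= min(K, n) <= N")
  ln_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                           log.p = TRUE)
  ln_under <- stats::phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE)
  expected <- K * n / N
  out <- list(N = N, K = K, n = n, k = k, expected = expected,
              fold = if (expected > 0) k / expected else NA_real_,
              p_over = exp(ln_over), p_under = exp(ln_under),
              log10_p_over = log10_from_lnp(ln_over),
              log10_p_under = log10_from_lnp(ln_under))
  class(out) <- "overlap_test"
  out
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap: k = %d of K = %d x n = %d in N = %d\n",
              x$k, x$K, x$n, x$N))
  cat(sprintf("  expected %.2f, fold %.2f\n", x$expected, x$fold))
  cat(sprintf("  p_over  = %.3g (log10 %.1f)\n", x$p_over, x$log10_p_over))
  cat(sprintf("  p_under = %.3g (log10 %.1f)\n", x$p_under, x$log10_p_under))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-tailed p-value by the "probability mass at most that of the observed
#' table" rule (the definition used by [stats::fisher.test()]); the odds ratio
#' reported is the sample odds ratio `ad/bc` with a Woolf log-interval 95% CI.
#' When a cell is zero, the Haldane-Anscombe 0.5 correction is applied to the
#' odds ratio and CI (flagged in the result); the p-value remains exact.
#'
#' @param table a 2x2 matrix of non-negative integer counts.
#' @return List of class `"fisher_result"`: `odds_ratio`, `ci95` (length-2),
#'   `p`, `log10_p`, `haldane` (was the 0.5 correction applied).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table)))
    stop("need a 2x2 matrix of non-negative integer counts")
  p <- stats::fisher.test(table)$p.value
  haldane <- any(table == 0)
  tt <- if (haldane) table + 0.5 else table
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  se <- sqrt(sum(1 / tt))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  out <- list(odds_ratio = or, ci95 = ci, p = p, log10_p = log10(p),
              haldane = haldane)
  class(out) <- "fisher_result"
  out
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher's exact test: OR = %.3g (95%% CI %.3g-%.3g), p = %.3g%s\n",
              x$odds_ratio, x$ci95[1], x$ci95[2], x$p,
              if (x$haldane) " [Haldane-corrected OR]" else ""))
  invisible(x)
}

#' Binomial gene-set enrichment with Bonferroni correction
#'
#' For each category, the number of target genes in the category is compared
#' to the expectation under the background proportion: with
#' `prop = |category intersect background| / |background|`,
#' `p_raw = P[Bin(|target|, prop) >= observed]` (one-tailed), Bonferroni
#' corrected over the categories actually tested. Categories may be built by
#' set difference beforehand (e.g. a "cell cycle minus meiotic cell cycle"
#' category).
#'
#' @param target character vector of target genes (must be a subset of
#'   `background`).
#' @param categories named list of character vectors (gene sets).
#' @param background character vector: the gene universe.
#' @return `data.frame` with one row per category: `category`, `n_category`
#'   (in background), `observed`, `expected`, `fold_enrichment`, `p_raw`,
#'   `p_bonferroni`, `log10_p_raw`.
#' @export
binomial_enrichment <- function(target, categories, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  target <- unique(target)
  if (!all(target %in% background))
    stop("target must be a subset of background")
  m <- length(categories)
  rows <- lapply(names(categories), function(nm) {
    cat_bg <- intersect(unique(categories[[nm]]), background)
    prop <- length(cat_bg) / length(background)
    obs <- length(intersect(target, cat_bg))
    expected <- length(target) * prop
    lnp <- if (obs == 0) 0
           else stats::pbinom(obs - 1, length(target), prop,
                              lower.tail = FALSE, log.p = TRUE)
    data.frame(category = nm, n_category = length(cat_bg), observed = obs,
               expected = expected,
               fold_enrichment = if (expected > 0) obs / expected else NA_real_,
               p_raw = exp(lnp),
               p_bonferroni = min(1, m * exp(lnp)),
               log10_p_raw = log10_from_lnp(lnp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_raw), , drop = FALSE]
}

#' Mann-Whitney U test (Wilcoxon rank sum)
#'
#' Wrapper around [stats::wilcox.test()] with the alternative phrased for the
#' second sample: `alternative = "greater"` tests whether values in `y` tend
#' to exceed those in `x`. Uses the exact distribution for small samples
#' without ties and the normal approximation with tie and continuity
#' correction otherwise.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (y > x) or `"less"` (y < x).
#' @return List with `U` (the Mann-Whitney statistic for `y` vs `x`) and `p`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty input")
  ht <- suppressWarnings(stats::wilcox.test(y, x, alternative = alternative))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment via [stats::p.adjust()].
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Read gene sets from a GMT file
#'
#' @param path a GMT file (one set per line: name, description, members).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[`, character(1), 1))
}
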