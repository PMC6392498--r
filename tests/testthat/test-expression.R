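test_that("transcript TPM aggregates to genes and renormalizes to 1e6", {
  ann <- gene_annotation(c("t1", "t2", "t3"), c("gA", "gA", "gB"), "chr1",
                         "+", c(100L, 300L, 900L))
  m <- matrix(c(10, 30, 999960), ncol = 1,
              dimnames = list(c("t1", "t2", "t3"), "s1"))
  g <- gene_tpm(m, ann)
  expect_equal(g["gA", 1], 40)
  expect_equal(sum(g[, 1]), 1e6)
  # single-gene column renormalizes to 1e6 regardless of scale
  m1 <- matrix(42, dimnames = list("t1", "s1"))
  expect_equal(gene_tpm(m1, ann)[1, 1], 1e6)
  # 30/70 split
  m2 <- matrix(c(30, 70), ncol = 1, dimnames = list(c("t1", "t3"), "s1"))
  g2 <- gene_tpm(m2, ann)
  expect_equal(unname(g2[c("gA", "gB"), 1]), c(3e5, 7e5))
  bad <- matrix(1, dimnames = list("tX", "s1"))
  expect_error(gene_tpm(bad, ann), "tX")
})

test_that("the expressed filter is inclusive at the threshold", {
  m <- matrix(c(0.9, 0.2, 1.0, 0.0, 5.0, 0.0), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  expect_setequal(expressed_genes(m), c("gB", "gC"))  # gB hits exactly 1.0
  expect_false("gA" %in% expressed_genes(m))
  expect_setequal(expressed_genes(m, threshold = 0, op = ">"),
                  c("gA", "gB", "gC"))
})

test_that("identical groups give null DE results", {
  set.seed(2)
  base <- 2^rnorm(50, 8, 1)
  m <- renormalize_tpm(cbind(s1 = base, s2 = base * 1.01, s3 = base,
                             s4 = base * 1.01))
  rownames(m) <- sprintf("g%02d", 1:50)
  de <- simple_de_test(m, c("s1", "s2"), c("s3", "s4"))
  expect_true(all(abs(de$log2fc) < 1e-9))
  expect_true(all(de$direction == "ns"))
  expect_error(simple_de_test(m, "s1", c("s3", "s4")), "at least 2")
})

test_that("a planted 8-fold gene is recovered as upregulated", {
  set.seed(4)
  for (method in c("moderated", "welch")) {
    base <- 2^rnorm(200, 8, 1.5)
    mk <- function(eff) base * 2^(eff + rnorm(200, 0, 0.1))
    eff <- c(3, rep(0, 199))
    m <- cbind(a1 = mk(0), a2 = mk(0), a3 = mk(0),
               b1 = mk(eff), b2 = mk(eff), b3 = mk(eff))
    rownames(m) <- sprintf("g%03d", 1:200)
    m <- renormalize_tpm(m)
    de <- simple_de_test(m, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                         method = method)
    expect_equal(de$direction[1], "up", info = method)
    expect_gt(de$log2fc[1], 2.5)
    expect_lt(de$log2fc[1], 3.5)
  }
})

test_that("DE p-values are well calibrated under the global null", {
  set.seed(6)
  frac_sig <- replicate(20, {
    m <- renormalize_tpm(matrix(2^rnorm(150 * 5, 8, 1), nrow = 150,
                                dimnames = list(sprintf("g%03d", 1:150),
                                                c("a1", "a2", "a3",
                                                  "b1", "b2"))))
    de <- simple_de_test(m, c("a1", "a2", "a3"), c("b1", "b2"))
    mean(de$q < 0.05)
  })
  expect_lt(mean(frac_sig), 0.01)
})

test_that("classification reproduces closed-form and reconstructed odds ratios", {
  mk_de <- function(n_up_b, n_down_b, n_up_u, n_down_u) {
    genes <- sprintf("g%05d", seq_len(n_up_b + n_down_b + n_up_u + n_down_u))
    dir <- rep(c("up", "down", "up", "down"),
               c(n_up_b, n_down_b, n_up_u, n_down_u))
    bound <- genes[seq_len(n_up_b + n_down_b)]
    de <- data.frame(gene_id = genes,
                     log2fc = ifelse(dir == "up", 1, -1),
                     p = 0.001, q = 0.01, direction = dir,
                     stringsAsFactors = FALSE)
    list(de = de, bound = bound, genes = genes)
  }
  x <- mk_de(90, 10, 10, 90)
  cls <- classify_and_tabulate(x$bound, x$de, x$genes)
  expect_equal(cls$fisher$odds_ratio, 81)
  expect_equal(sum(cls$table), 200)
  # counts reconstructed from the printed 1,351 / 89% / 32.4% figures
  y <- mk_de(1351, 167, 1010, 2111)
  cls2 <- classify_and_tabulate(y$bound, y$de, y$genes)
  expect_equal(cls2$fisher$odds_ratio, 16.9, tolerance = 0.01)
  expect_gt(cls2$fisher$odds_ratio, 14.3)
  expect_lt(cls2$fisher$odds_ratio, 20.6)
  expect_equal(cls2$fraction_up["bound"], c(bound = 0.89), tolerance = 0.01)
  expect_equal(cls2$fraction_activated_of_up, 1351 / 2361, tolerance = 1e-12)
  # fractions up and down within the bound stratum sum to 1
  expect_equal(cls2$fraction_up[["bound"]] +
                 sum(cls2$table["bound", "down"]) / sum(cls2$table["bound", ]),
               1)
  # empty bound set: degenerate, no odds ratio
  cls3 <- classify_and_tabulate(character(0), x$de, x$genes)
  expect_true(cls3$degenerate)
  expect_null(cls3$fisher)
})

test_that("classification counts cover exactly the expressed DE genes", {
  set.seed(44)
  genes <- sprintf("g%03d", 1:300)
  de <- data.frame(gene_id = genes, log2fc = rnorm(300), p = runif(300),
                   stringsAsFactors = FALSE)
  de$q <- bh_fdr(de$p)
  de$direction <- ifelse(de$q < 0.5 & de$log2fc > 0, "up",
                         ifelse(de$q < 0.5 & de$log2fc < 0, "down", "ns"))
  expressed <- sample(genes, 250)
  bound <- sample(genes, 80)
  cls <- classify_and_tabulate(bound, de, expressed)
  n_de_expressed <- sum(de$gene_id %in% expressed & de$direction != "ns")
  expect_equal(sum(cls$table), n_de_expressed)
  expect_true(all(cls$activated %in% bound))
  expect_true(all(cls$activated %in% de$gene_id[de$direction == "up"]))
})

test_that("fold-change concordance behaves as a correlation", {
  de_a <- data.frame(gene_id = sprintf("g%02d", 1:20), log2fc = rnorm(20),
                     p = 0.5, q = 0.5, direction = "ns")
  expect_equal(fold_change_concordance(de_a, de_a), 1)
  de_b <- de_a; de_b$log2fc <- -de_b$log2fc
  expect_equal(fold_change_concordance(de_a, de_b), -1)
  de_c <- de_a; de_c$log2fc <- 0
  expect_error(fold_change_concordance(de_a, de_c), "constant")
  expect_error(fold_change_concordance(de_a[1:2, ], de_a[1:2, ]), "3 shared")
})

test_that("testis bias uses medians across individuals and a strict majority rule", {
  tissues <- c("brain", "testis")
  m <- matrix(c(8, 10,   # gA: testis 10 vs brain 8 -> 10 > 9 biased
                10, 10,  # gB: tie -> not biased (strict)
                0, 0),   # gC: all zero -> not biased
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("brain.1", "testis.1")))
  b <- testis_bias(m)
  expect_true(b[["gA"]])
  expect_false(b[["gB"]])
  expect_false(b[["gC"]])
  # replicate columns enter through the median: outlier replicate is ignored
  m2 <- matrix(c(1, 1, 1, 100, 100, 1000), nrow = 1,
               dimnames = list("gA", c("brain.1", "brain.2", "brain.3",
                                       "testis.1", "testis.2", "testis.3")))
  expect_true(testis_bias(m2)[["gA"]])  # medians: brain 1, testis 100
  m3 <- m2; colnames(m3) <- sub("testis", "liver", colnames(m3))
  expect_error(testis_bias(m3), "testis")
})
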