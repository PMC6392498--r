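test_that("blacklist filtering is half-open and order-preserving", {
  pk <- peak_set(rep("chr1", 3), c(100L, 100L, 500L), c(200L, 200L, 600L),
                 c(150L, 150L, 550L), c(1, 2, 3))
  bl <- interval_set("chr1", 150L, 160L, label = "blacklist")
  kept <- filter_blacklist(pk, bl)
  expect_equal(kept$score, 3)
  # adjacent interval shares no base
  bl2 <- interval_set("chr1", 200L, 300L, label = "blacklist")
  expect_equal(nrow(filter_blacklist(pk, bl2)), 3L)
  empty <- interval_set(character(0), integer(0), integer(0))
  expect_identical(filter_blacklist(pk, empty), pk)
})

test_that("summit-to-TSS assignment uses the summit and multi-assigns", {
  ann <- gene_annotation(c("tA", "tB"), c("gA", "gB"), "chr1", "+",
                         c(5000L, 6800L))
  mk <- function(summit) peak_set("chr1", summit - 100L, summit + 100L,
                                  summit, 1)
  expect_equal(assign_peaks_to_tss(mk(5400L), ann)$gene_id, "gA")
  # summit 6200 is 1200 bp from gA (excluded) and 600 bp from gB
  expect_equal(assign_peaks_to_tss(mk(6200L), ann)$gene_id, "gB")
  # equidistant 900 bp from both TSSs -> both
  both <- assign_peaks_to_tss(mk(5900L), ann)
  expect_setequal(both$gene_id, c("gA", "gB"))
  # window is half-open on the right: distance 1000 is out, -1000 is in
  annA <- tiny_ann(5000L, gene_id = "gA", transcript_id = "tA")
  expect_equal(nrow(assign_peaks_to_tss(mk(6000L), annA)), 0L)
  expect_equal(assign_peaks_to_tss(mk(4000L), annA)$gene_id, "gA")
  expect_error(assign_peaks_to_tss(mk(5000L), ann[0, ]), "empty")
})

test_that("assignment agrees with the brute-force all-pairs scan", {
  set.seed(31)
  for (rep in 1:15) {
    ann <- tiny_ann(sort(sample(0:20000, 8)),
                    chrom = sample(c("c1", "c2"), 8, TRUE))
    summit <- sample(0:20000, 25, TRUE)
    pk <- peak_set(sample(c("c1", "c2"), 25, TRUE), pmax(0L, summit - 50L),
                   summit + 50L, summit, 1)
    got <- assign_peaks_to_tss(pk, ann)
    want <- oracle_assign(pk, ann)
    o <- function(d) d[order(d$peak_row, d$transcript_id), ]
    expect_equal(unname(as.matrix(o(got))), unname(as.matrix(o(want))))
  }
})

test_that("promoter fraction covers the all-at-TSS and none cases", {
  ann <- tiny_ann(c(5000L, 9000L))
  at_tss <- peak_set("chr1", c(4900L, 8900L), c(5100L, 9100L),
                     c(5000L, 9000L), 1)
  expect_equal(promoter_fraction(at_tss, ann), 1.0)
  far <- peak_set("chr1", 20000L, 20200L, 20100L, 1)
  expect_equal(promoter_fraction(far, ann), 0.0)
  expect_error(promoter_fraction(at_tss[0, ], ann), "empty")
})

test_that("consensus calling applies the control filter before the replicate count", {
  flag <- list(c("gA", "gB", "gC"), c("gA", "gB"), c("gB", "gD"))
  calls <- call_bound_genes(flag, list(), min_replicates = 2)
  expect_setequal(calls$bound, c("gA", "gB"))
  # control hit in any replicate removes the gene even at 3/3 support
  calls2 <- call_bound_genes(flag, list("gB", character(0)), 2)
  expect_setequal(calls2$bound, "gA")
  row_b <- calls2$calls[calls2$calls$gene_id == "gB", ]
  expect_equal(row_b$n_flag_replicates_with_peak, 3L)
  expect_true(row_b$control_hit)
  # single-replicate gene is reported but not bound
  row_d <- calls$calls[calls$calls$gene_id == "gD", ]
  expect_false(row_d$bound)
  expect_equal(row_d$n_flag_replicates_with_peak, 1L)
  expect_error(call_bound_genes(flag, list(), min_replicates = 4),
               "exceeds")
})

test_that("consensus is monotone and collapses to union/intersection at the extremes", {
  set.seed(17)
  genes <- sprintf("g%02d", 1:30)
  for (rep in 1:10) {
    flag <- lapply(1:3, function(i) sample(genes, sample(5:20, 1)))
    ctrl <- list(sample(genes, 4))
    base <- call_bound_genes(flag, ctrl, 2)$bound
    # enlarging a FLAG replicate never shrinks the bound set
    flag2 <- flag; flag2[[1]] <- union(flag2[[1]], sample(genes, 5))
    expect_true(all(base %in% call_bound_genes(flag2, ctrl, 2)$bound))
    # enlarging the control never grows it
    ctrl2 <- list(union(ctrl[[1]], sample(genes, 5)))
    expect_true(all(call_bound_genes(flag, ctrl2, 2)$bound %in% base))
    filtered <- lapply(flag, setdiff, y = ctrl[[1]])
    expect_setequal(call_bound_genes(flag, ctrl, 1)$bound,
                    Reduce(union, filtered))
    expect_setequal(call_bound_genes(flag, ctrl, 3)$bound,
                    Reduce(intersect, filtered))
  }
})

test_that("promoter read density is input-subtracted rpm without clipping", {
  d <- promoter_read_density(c(g = 50), 1e6, c(g = 10), 1e6)
  expect_equal(d[["g"]], 40)
  expect_equal(promoter_read_density(c(g = 0), 1e6, c(g = 30), 1e6)[["g"]],
               -30)
  expect_equal(promoter_read_density(c(g = 100), 2e6, c(g = 25), 1e6)[["g"]],
               25)
  # transcript counts sum to gene level before normalization
  ann <- gene_annotation(c("t1", "t2"), c("g", "g"), "chr1", "+",
                         c(100L, 300L))
  d2 <- promoter_read_density(c(t1 = 30, t2 = 20), 1e6, c(t1 = 5, t2 = 5),
                              1e6, ann = ann)
  expect_equal(d2[["g"]], 40)
  expect_error(promoter_read_density(c(g = 1), 0, c(g = 1), 1e6), "positive")
  expect_error(promoter_read_density(c(g = -1), 1e6, c(g = 1), 1e6),
               "negative")
})

test_that("narrowPeak files round-trip, with midpoint fallback for absent summits", {
  pk <- peak_set("chr1", c(100L, 400L), c(300L, 700L), c(180L, 500L),
                 c(7.5, 2.25), replicate_id = 2L, condition = "FLAG")
  path <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, path)
  back <- read_narrowpeak(path, replicate_id = 2L)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$summit, pk$summit)
  expect_equal(back$score, pk$score)
  # summit column -1 means absent
  lines <- readLines(path)
  lines[1] <- sub("\t80$", "\t-1", lines[1])
  writeLines(lines, path)
  expect_warning(back2 <- read_narrowpeak(path), "midpoint")
  expect_equal(back2$summit[1], 200L)
  expect_error(peak_set("chr1", 100L, 200L, 250L, 1), "summit")
})
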