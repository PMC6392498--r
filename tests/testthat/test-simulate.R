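test_that("the generator is a pure function of config and seed", {
  cfg <- small_sim_config(seed = 5L)
  s1 <- make_genome(cfg)
  s2 <- make_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  s3 <- make_genome(small_sim_config(seed = 6L))
  expect_false(identical(s1$genome, s3$genome))
  p1 <- simulate_peaks(s1)
  p2 <- simulate_peaks(s1)
  expect_identical(p1, p2)
  e1 <- simulate_expression(s1)
  e2 <- simulate_expression(s1)
  expect_identical(e1$tpm, e2$tpm)
})

test_that("planted motif counts are verified by the naive oracle scanner", {
  pm3 <- c("0" = 0, "1" = 0, "2" = 0, "3" = 1, "4" = 0, "5" = 0, "6" = 0,
           "7" = 0, "8" = 0)
  cfg <- sim_config(n_genes = 50L, chrom_length = 2e5, frac_bound = 1,
                    n_downregulated = 0L,
                    motif_count_distribution = pm3, seed = 9L)
  sim <- make_genome(cfg)
  expect_true(all(sim$truth$motif_count == 3L))
  for (i in seq_len(nrow(sim$ann))) {
    tss <- sim$ann$tss[i]
    win <- substr(sim$genome[[1]], tss - 1000 + 1, tss + 1000)
    expect_gte(nrow(oracle_scan(win, "CNCCTCAG")), 3L)
  }
  # point mass at zero: nothing planted anywhere
  pm0 <- c("0" = 1, "1" = 0, "2" = 0, "3" = 0, "4" = 0, "5" = 0, "6" = 0,
           "7" = 0, "8" = 0)
  sim0 <- make_genome(sim_config(n_genes = 50L, chrom_length = 2e5,
                                 frac_bound = 1, n_downregulated = 0L,
                                 motif_count_distribution = pm0, seed = 9L))
  expect_true(all(sim0$truth$motif_count == 0L))
  expect_error(make_genome(sim_config(n_genes = 100L, chrom_length = 1e5)),
               "packing")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(frac_bound = 1.5), "\\[0, 1\\]")
  bad <- c("0" = 0.5, "1" = 0.4)
  expect_error(sim_config(motif_count_distribution = bad), "sum to 1")
})

test_that("noise-free peaks sit exactly at the TSS of every bound gene", {
  cfg <- small_sim_config(per_replicate_sensitivity = 1,
                          spurious_peak_rate = 0, summit_jitter_sd = 0,
                          seed = 3L)
  sim <- make_genome(cfg)
  pk <- simulate_peaks(sim)
  bound_tss <- sort(sim$ann$tss[sim$ann$gene_id %in% sim$truth$bound_genes])
  for (rep in pk$flag) {
    expect_equal(nrow(rep), length(sim$truth$bound_genes))
    expect_equal(sort(rep$summit), bound_tss)
  }
  for (rep in pk$control) expect_equal(nrow(rep), 0L)
})

test_that("spurious peaks never reach a promoter and scores track motif dose", {
  cfg <- small_sim_config(seed = 13L)
  sim <- make_genome(cfg)
  pk <- simulate_peaks(sim)
  for (rep in pk$control) {
    if (nrow(rep) == 0) next
    expect_equal(nrow(assign_peaks_to_tss(rep, sim$ann)), 0L)
  }
  pooled <- do.call(rbind, pk$flag)
  asg <- assign_peaks_to_tss(pooled, sim$ann)
  counts <- sim$truth$motif_count[asg$gene_id]
  expect_gt(stats::cor(counts, pooled$score[asg$peak_row],
                       method = "spearman"), 0)
})

test_that("expression columns are TPM-normalized and effects are exact without noise", {
  cfg <- small_sim_config(expr_noise_sd = 0, log2fc_per_motif = 1, seed = 21L)
  sim <- make_genome(cfg)
  expr <- simulate_expression(sim)
  expect_true(all(abs(colSums(expr$tpm) - 1e6) < 1e-6 * 1e6))
  counts <- sim$truth$motif_count
  g3 <- names(counts)[counts == 3 &
                        names(counts) %in% sim$truth$bound_genes][1]
  null_gene <- setdiff(names(counts)[counts == 0],
                       c(sim$truth$bound_genes,
                         sim$truth$downregulated_genes))[1]
  skip_if(is.na(g3), "no three-motif gene under this seed")
  # renormalization cancels in the double ratio against a null gene
  ratio <- (expr$tpm[g3, "high.1"] / expr$tpm[g3, "KO.1"]) /
    (expr$tpm[null_gene, "high.1"] / expr$tpm[null_gene, "KO.1"])
  expect_equal(ratio, 8, tolerance = 1e-9)
  # low samples carry half the log effect
  ratio_low <- (expr$tpm[g3, "low.1"] / expr$tpm[g3, "KO.1"]) /
    (expr$tpm[null_gene, "low.1"] / expr$tpm[null_gene, "KO.1"])
  expect_equal(ratio_low, 2^1.5, tolerance = 1e-9)
})

test_that("tissue panel plants exactly the requested biased genes", {
  cfg <- small_sim_config(seed = 31L)
  sim <- make_genome(cfg)
  p0 <- simulate_tissue_panel(sim, n_biased = 0)
  expect_equal(sum(testis_bias(p0$tpm)), 0L)
  p50 <- simulate_tissue_panel(sim, n_biased = 50)
  called <- names(which(testis_bias(p50$tpm)))
  expect_setequal(called, p50$biased_genes)
  expect_equal(length(called), 50L)
  expect_error(simulate_tissue_panel(sim, n_biased = 1e5), "exceeds")
})

test_that("simulated promoter counts support the read-density arithmetic", {
  cfg <- small_sim_config(seed = 41L)
  sim <- make_genome(cfg)
  pc <- simulate_promoter_counts(sim)
  dens <- promoter_read_density(pc$chip_counts, pc$chip_library_size,
                                pc$input_counts, pc$input_library_size)
  bound <- names(dens) %in% sim$truth$bound_genes
  expect_gt(mean(dens[bound]), mean(dens[!bound]))
})

test_that("a written simulation reloads through the file-facing entry points", {
  cfg <- small_sim_config(seed = 51L)
  sim <- make_genome(cfg)
  pk <- simulate_peaks(sim)
  expr <- simulate_expression(sim)
  dir <- file.path(tempdir(), "simout")
  paths <- write_simulation(sim, pk, expr, dir)
  ann2 <- load_annotation(paths$annotation)
  expect_equal(ann2$tss, sim$ann$tss)
  fa <- Biostrings::readDNAStringSet(paths$genome)
  expect_equal(as.character(fa[[1]]), unname(sim$genome[1]))
  flag_sets_files <- lapply(1:3, function(i) {
    promoter_genes(read_narrowpeak(paths[[sprintf("flag_rep%d", i)]], i),
                   ann2)
  })
  flag_sets_mem <- lapply(pk$flag, promoter_genes, ann = sim$ann)
  expect_identical(lapply(flag_sets_files, sort), lapply(flag_sets_mem, sort))
  cgi2 <- read_bed(paths$cgi, label = "CGI")
  expect_equal(nrow(cgi2), nrow(sim$cgi))
  unlink(dir, recursive = TRUE)
})
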