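# Seeded synthetic-data generator. Emits a random genome with promoters
# carrying planted CNCCTCAG motifs, replicated promoter-localized peak calls
# whose score tracks motif dose, and staged expression matrices in which
# bound genes are amplified in proportion to their motif count. Everything is
# a pure function of (config, seed).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Parameters of the synthetic regulon. The defaults are the package's
#' reference study conditions: 1000 genes on a 5 Mb chromosome, a quarter of
#' them bound, three tagged-ChIP and three control replicates at 0.9
#' per-replicate sensitivity, a motif-dose score and expression model, and the
#' study's 3 + 2 + 2 expression design (KO / low / high).
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp.
#' @param n_flag_reps,n_control_reps ChIP replicate counts.
#' @param frac_bound fraction of genes truly bound.
#' @param motif_count_distribution named probabilities over planted promoter
#'   motif counts 0..8. Bound genes draw their count from this distribution
#'   conditioned on being >= 1 (binding and motif dose are coupled, as in the
#'   biology the generator emulates); unbound genes carry no planted motifs.
#' @param per_replicate_sensitivity probability a truly bound promoter yields
#'   a peak in one tagged replicate.
#' @param spurious_peak_rate expected non-promoter peaks per replicate.
#' @param summit_jitter_sd SD (bp) of the summit around the TSS.
#' @param score_base,score_per_motif,score_noise_sd,score_floor peak score
#'   model: `base + per_motif * motif_count + Normal(0, sd)`, floored.
#' @param peak_halfwidth half-width of the emitted peak interval.
#' @param expr_baseline_log2_mean,expr_baseline_log2_sd baseline per-gene
#'   log2 TPM distribution.
#' @param log2fc_per_motif expression amplification per planted motif in
#'   high-STRA8 samples (low-STRA8 samples receive half the log effect).
#' @param n_downregulated number of (unbound) genes downregulated at
#'   initiation.
#' @param downregulation_log2fc their log2 fold change in high samples.
#' @param expr_noise_sd per-sample multiplicative noise, SD in log2 units.
#' @param groups named integer vector of sample counts per condition.
#' @param seed integer seed; the peak, expression and panel generators use
#'   fixed small offsets from it so each stage is reproducible in isolation.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 1000L, chrom_length = 5e6,
                       n_flag_reps = 3L, n_control_reps = 3L,
                       frac_bound = 0.25,
                       motif_count_distribution = c(
                         "0" = 0.40, "1" = 0.30, "2" = 0.15, "3" = 0.08,
                         "4" = 0.04, "5" = 0.02, "6" = 0.007, "7" = 0.002,
                         "8" = 0.001),
                       per_replicate_sensitivity = 0.9,
                       spurious_peak_rate = 50,
                       summit_jitter_sd = 100,
                       score_base = 5, score_per_motif = 2,
                       score_noise_sd = 1, score_floor = 0.5,
                       peak_halfwidth = 150L,
                       expr_baseline_log2_mean = 8,
                       expr_baseline_log2_sd = 2,
                       log2fc_per_motif = 1.0,
                       n_downregulated = 180L,
                       downregulation_log2fc = -1,
                       expr_noise_sd = 0.1,
                       groups = c(KO = 3L, low = 2L, high = 2L),
                       seed = 1L) {
  probs <- c(frac_bound, per_replicate_sensitivity)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (abs(sum(motif_count_distribution) - 1) > 1e-9)
    stop("motif_count_distribution must sum to 1")
  if (any(motif_count_distribution < 0))
    stop("motif_count_distribution must be non-negative")
  cfg <- list(n_genes = as.integer(n_genes), chrom_length = chrom_length,
              n_flag_reps = as.integer(n_flag_reps),
              n_control_reps = as.integer(n_control_reps),
              frac_bound = frac_bound,
              motif_count_distribution = motif_count_distribution,
              per_replicate_sensitivity = per_replicate_sensitivity,
              spurious_peak_rate = spurious_peak_rate,
              summit_jitter_sd = summit_jitter_sd,
              score_base = score_base, score_per_motif = score_per_motif,
              score_noise_sd = score_noise_sd, score_floor = score_floor,
              peak_halfwidth = as.integer(peak_halfwidth),
              expr_baseline_log2_mean = expr_baseline_log2_mean,
              expr_baseline_log2_sd = expr_baseline_log2_sd,
              log2fc_per_motif = log2fc_per_motif,
              n_downregulated = as.integer(n_downregulated),
              downregulation_log2fc = downregulation_log2fc,
              expr_noise_sd = expr_noise_sd,
              groups = groups, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

SIM_CHROM <- "chrS"
SIM_FLANK <- 1000L
MOTIF_LEN <- 8L

#' Simulate a genome, annotation and ground truth
#'
#' Generates a uniform-random A/C/G/T chromosome, places genes with
#' non-overlapping 2 kb promoter windows, plants the configured number of
#' CNCCTCAG instances (random N base, random strand, non-overlapping
#' positions) inside each bound gene's promoter window, and records the
#' ground truth. CpG-island-like intervals are attached over bound promoters
#' (and a tenth of unbound ones).
#'
#' @param cfg a `"sim_config"`.
#' @return List of class `"sim_regulon"`: `genome` (named character vector of
#'   chromosome sequence), `ann` (a `"gene_annotation"`), `truth` (list with
#'   `bound_genes`, `motif_count`, `true_log2fc`, `downregulated_genes`),
#'   `cgi` (an `"interval_set"`), `config`.
#' @export
make_genome <- function(cfg) {
  spacing <- floor(cfg$chrom_length / cfg$n_genes)
  if (spacing < 2 * SIM_FLANK + 200)
    stop("infeasible packing: need chrom_length >= n_genes * ",
         2 * SIM_FLANK + 200, " bp")
  with_seed(cfg$seed, {
    bases <- c("A", "C", "G", "T")
    seq_chars <- sample(bases, cfg$chrom_length, replace = TRUE)
    gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
    tss <- as.integer((seq_len(cfg$n_genes) - 1L) * spacing + spacing %/% 2L)
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    n_bound <- round(cfg$frac_bound * cfg$n_genes)
    bound <- sort(sample(gene_ids, n_bound))
    motif_count <- setNames(integer(cfg$n_genes), gene_ids)
    pd <- cfg$motif_count_distribution
    support <- as.integer(names(pd))
    pd_pos <- pd[support >= 1]
    if (n_bound > 0 && sum(pd_pos) > 0) {
      motif_count[bound] <- sample(support[support >= 1], n_bound,
                                   replace = TRUE, prob = pd_pos / sum(pd_pos))
    }
    # plant motifs at non-overlapping positions inside each promoter window
    for (g in bound) {
      k <- motif_count[[g]]
      if (k == 0) next
      win_lo <- tss[match(g, gene_ids)] - SIM_FLANK
      win_hi <- tss[match(g, gene_ids)] + SIM_FLANK - MOTIF_LEN
      placed <- integer(0)
      while (length(placed) < k) {
        cand <- sample(win_lo:win_hi, 1L)
        if (all(abs(cand - placed) >= MOTIF_LEN)) placed <- c(placed, cand)
      }
      for (pos in placed) {
        inst <- c("C", sample(bases, 1L), "C", "C", "T", "C", "A", "G")
        if (sample(c(TRUE, FALSE), 1L))
          inst <- rev(c(G = "C", C = "G", A = "T", T = "A")[inst])
        seq_chars[(pos + 1L):(pos + MOTIF_LEN)] <- inst
      }
    }
    unbound <- setdiff(gene_ids, bound)
    if (cfg$n_downregulated > length(unbound))
      stop("n_downregulated exceeds the number of unbound genes")
    downreg <- sort(sample(unbound, cfg$n_downregulated))
    true_log2fc <- setNames(numeric(cfg$n_genes), gene_ids)
    true_log2fc[bound] <- cfg$log2fc_per_motif * motif_count[bound]
    true_log2fc[downreg] <- cfg$downregulation_log2fc
    cgi_genes <- c(bound,
                   sample(unbound, max(0L, round(0.1 * length(unbound)))))
    cgi_tss <- tss[match(sort(cgi_genes), gene_ids)]
    ann <- gene_annotation(paste0(gene_ids, ".t1"), gene_ids,
                           SIM_CHROM, strand, tss,
                           seqlengths = setNames(as.integer(cfg$chrom_length),
                                                 SIM_CHROM))
    out <- list(
      genome = setNames(paste(seq_chars, collapse = ""), SIM_CHROM),
      ann = ann,
      truth = list(bound_genes = bound, motif_count = motif_count,
                   true_log2fc = true_log2fc, downregulated_genes = downreg),
      cgi = interval_set(SIM_CHROM, cgi_tss - 500L, cgi_tss + 500L,
                         label = "CGI"),
      config = cfg)
    class(out) <- "sim_regulon"
    out
  })
}

# uniform positions on the chromosome whose summit avoids every promoter
# window (rejection sampling keeps the ground truth clean); tss must be
# sorted
sample_nonpromoter <- function(n, cfg, tss) {
  if (n == 0) return(integer(0))
  out <- integer(0)
  while (length(out) < n) {
    cand <- as.integer(floor(runif(2L * (n - length(out)) + 10L,
                                   min = 0, max = cfg$chrom_length)))
    i <- findInterval(cand, tss)
    d_left <- ifelse(i >= 1L, cand - tss[pmax(i, 1L)], Inf)
    d_right <- ifelse(i < length(tss), tss[pmin(i + 1L, length(tss))] - cand,
                      Inf)
    ok <- pmin(d_left, d_right) > SIM_FLANK
    out <- c(out, cand[ok])
  }
  out[seq_len(n)]
}

#' Simulate replicated peak calls
#'
#' For each tagged replicate, every truly bound gene yields a peak with the
#' configured per-replicate sensitivity; the summit is the TSS plus Gaussian
#' jitter and the score follows the motif-dose score model. A Poisson number
#' of spurious peaks is placed uniformly outside all promoter windows.
#' Control replicates contain only spurious peaks.
#'
#' @param sim a `"sim_regulon"` from [make_genome()].
#' @param cfg a `"sim_config"` (defaults to the one inside `sim`).
#' @return List with elements `flag` and `control`, each a list of
#'   `"peak_set"` objects (one per replicate).
#' @export
simulate_peaks <- function(sim, cfg = sim$config) {
  ann <- sim$ann
  tss <- sort(ann$tss)
  with_seed(cfg$seed + 1L, {
    make_rep <- function(rep_id, condition) {
      if (condition == "FLAG") {
        bound <- sim$truth$bound_genes
        hit <- bound[runif(length(bound)) < cfg$per_replicate_sensitivity]
        g_tss <- ann$tss[match(hit, ann$gene_id)]
        summit <- as.integer(round(
          g_tss + rnorm(length(hit), 0, cfg$summit_jitter_sd)))
        summit <- pmax(0L, pmin(as.integer(cfg$chrom_length) - 1L, summit))
        count <- sim$truth$motif_count[hit]
        score <- pmax(cfg$score_floor,
                      cfg$score_base + cfg$score_per_motif * count +
                        rnorm(length(hit), 0, cfg$score_noise_sd))
      } else {
        summit <- integer(0); score <- numeric(0)
      }
      n_sp <- rpois(1L, cfg$spurious_peak_rate)
      sp <- sample_nonpromoter(n_sp, cfg, tss)
      sp_score <- pmax(cfg$score_floor,
                       cfg$score_base + rnorm(n_sp, 0, cfg$score_noise_sd))
      summit <- c(summit, sp)
      score <- c(score, sp_score)
      if (length(summit) == 0)
        return(peak_set(character(0), integer(0), integer(0), integer(0),
                        numeric(0), rep_id, condition))
      start <- pmax(0L, summit - cfg$peak_halfwidth)
      end <- pmin(as.integer(cfg$chrom_length), summit + cfg$peak_halfwidth)
      peak_set(SIM_CHROM, start, end, summit, score, rep_id, condition)
    }
    list(flag = lapply(seq_len(cfg$n_flag_reps), make_rep,
                       condition = "FLAG"),
         control = lapply(seq_len(cfg$n_control_reps), make_rep,
                          condition = "control"))
  })
}

#' Simulate staged expression
#'
#' Baseline per-gene log2 TPM is Gaussian; in high-STRA8 samples bound genes
#' are amplified by `2^(log2fc_per_motif * motif_count)` and downregulated
#' genes by `2^(downregulation_log2fc)`; low-STRA8 samples receive half of
#' every log effect; knockout samples none. Per-sample multiplicative
#' lognormal noise is added and columns are renormalized to TPM units
#' (sum 1e6).
#'
#' @param sim a `"sim_regulon"`.
#' @param cfg a `"sim_config"`.
#' @param groups named sample counts per condition (default from `cfg`).
#' @return List with `tpm` (gene x sample matrix, columns named
#'   `group.rep`), `groups` (named vector mapping column to condition) and
#'   `truth_de` (`data.frame` of per-gene true log2 fold changes).
#' @export
simulate_expression <- function(sim, cfg = sim$config, groups = cfg$groups) {
  ann <- sim$ann
  genes <- unique(ann$gene_id)
  n <- length(genes)
  effect <- sim$truth$true_log2fc[genes]
  with_seed(cfg$seed + 2L, {
    baseline <- rnorm(n, cfg$expr_baseline_log2_mean, cfg$expr_baseline_log2_sd)
    cols <- unlist(lapply(names(groups), function(g)
      paste(g, seq_len(groups[[g]]), sep = ".")))
    grp <- sub("\\..*$", "", cols)
    mult <- c(KO = 0, low = 0.5, high = 1)[grp]
    lg <- vapply(seq_along(cols), function(j) {
      baseline + mult[j] * effect + rnorm(n, 0, cfg$expr_noise_sd)
    }, numeric(n))
    dimnames(lg) <- list(genes, cols)
    tpm <- renormalize_tpm(2^lg)
    list(tpm = tpm, groups = setNames(grp, cols),
         truth_de = data.frame(gene_id = genes, true_log2fc = unname(effect),
                               downregulated =
                                 genes %in% sim$truth$downregulated_genes,
                               stringsAsFactors = FALSE))
  })
}

#' Simulate a nine-tissue expression panel
#'
#' Eight somatic tissues plus testis, each with replicate individuals. The
#' chosen testis-biased genes get testis expression exceeding the summed
#' expression of the other eight tissues; all other genes are balanced across
#' tissues.
#'
#' @param sim a `"sim_regulon"`.
#' @param n_biased number of planted testis-biased genes.
#' @param cfg a `"sim_config"`.
#' @param n_reps individuals per tissue (default 3).
#' @param noise_sd per-column lognormal noise in log2 units (default 0:
#'   noise off).
#' @return List with `tpm` (gene x sample matrix, columns `tissue.rep`) and
#'   `biased_genes`.
#' @export
simulate_tissue_panel <- function(sim, n_biased, cfg = sim$config,
                                  n_reps = 3L, noise_sd = 0) {
  genes <- unique(sim$ann$gene_id)
  if (n_biased > length(genes)) stop("n_biased exceeds n_genes")
  tissues <- c("brain", "colon", "heart", "kidney", "liver", "lung",
               "muscle", "spleen", "testis")
  with_seed(cfg$seed + 3L, {
    biased <- sort(sample(genes, n_biased))
    base <- 2^rnorm(length(genes), 5, 1.5)
    m <- matrix(base, nrow = length(genes), ncol = length(tissues) * n_reps)
    cols <- unlist(lapply(tissues, function(t)
      paste(t, seq_len(n_reps), sep = ".")))
    dimnames(m) <- list(genes, cols)
    testis_cols <- grepl("^testis\\.", cols)
    m[genes %in% biased, testis_cols] <-
      base[genes %in% biased] * 8 * runif(sum(genes %in% biased), 1.5, 3)
    if (noise_sd > 0)
      m <- m * 2^matrix(rnorm(length(m), 0, noise_sd), nrow = nrow(m))
    list(tpm = m, biased_genes = biased)
  })
}

#' Simulate promoter read-count tables
#'
#' Minimal model backing the input-subtraction arithmetic: per-gene ChIP
#' counts are Poisson with rate proportional to the gene's score under the
#' motif-dose score model (flat for unbound genes), and input-chromatin
#' counts are Poisson with a flat rate.
#'
#' @param sim a `"sim_regulon"`.
#' @param cfg a `"sim_config"`.
#' @param base_rate flat Poisson rate per gene (default 20).
#' @param rate_per_score additional rate per unit of peak score (default 10).
#' @return List with `chip_counts`, `input_counts` (named per gene),
#'   `chip_library_size`, `input_library_size`.
#' @export
simulate_promoter_counts <- function(sim, cfg = sim$config, base_rate = 20,
                                     rate_per_score = 10) {
  genes <- unique(sim$ann$gene_id)
  score <- ifelse(genes %in% sim$truth$bound_genes,
                  cfg$score_base +
                    cfg$score_per_motif * sim$truth$motif_count[genes], 0)
  with_seed(cfg$seed + 4L, {
    chip <- rpois(length(genes), base_rate + rate_per_score * score)
    input <- rpois(length(genes), base_rate)
    list(chip_counts = setNames(chip, genes),
         input_counts = setNames(input, genes),
         chip_library_size = 1e6, input_library_size = 1e6)
  })
}

#' Write a simulated dataset to files
#'
#' Exercises every file-facing entry point: FASTA genome, TSV annotation,
#' narrowPeak replicates, TSV expression matrix, BED CpG islands, and a JSON
#' ground-truth sidecar.
#'
#' @param sim a `"sim_regulon"`.
#' @param peaks output of [simulate_peaks()].
#' @param expr output of [simulate_expression()].
#' @param dir output directory (created if needed).
#' @return Named list of the paths written.
#' @export
write_simulation <- function(sim, peaks, expr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                annotation = file.path(dir, "annotation.tsv"),
                cgi = file.path(dir, "cgi.bed"),
                expression = file.path(dir, "expression.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  dna <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(dna, paths$genome)
  write_annotation(sim$ann, paths$annotation)
  write_bed(sim$cgi, paths$cgi)
  write.table(data.frame(gene_id = rownames(expr$tpm), expr$tpm,
                         check.names = FALSE),
              paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(peaks$flag)) {
    p <- file.path(dir, sprintf("flag_rep%d.narrowPeak", i))
    write_narrowpeak(peaks$flag[[i]], p)
    paths[[sprintf("flag_rep%d", i)]] <- p
  }
  for (i in seq_along(peaks$control)) {
    p <- file.path(dir, sprintf("control_rep%d.narrowPeak", i))
    write_narrowpeak(peaks$control[[i]], p)
    paths[[sprintf("control_rep%d", i)]] <- p
  }
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  paths
}
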