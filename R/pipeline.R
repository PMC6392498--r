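# End-to-end orchestration: simulate -> binding calls -> DE -> integration ->
# motif dose -> census, with every parameter echoed into the run report so a
# report can be regenerated bit-identically from its config and seed.

#' Pipeline configuration
#'
#' All analysis parameters with their reference defaults: 1 kb assignment
#' flank, consensus in >= 2 replicates, expressed at >= 1 TPM, FDR q < 0.05,
#' the CNCCTCAG motif, and 10^4 permutations for the motif-score correlation.
#'
#' @param flank promoter assignment half-width in bp.
#' @param min_replicates replicate-consensus threshold.
#' @param expressed_threshold,expressed_op expressed-gene rule (TPM).
#' @param de_alpha FDR threshold for differential expression.
#' @param motif IUPAC motif pattern.
#' @param n_permutations permutations for the motif-score correlation.
#' @param max_stratum top motif-count stratum for the dose-response summary.
#' @param seed integer master seed (also seeds the simulation).
#' @param sim a `"sim_config"`; defaults to `sim_config(seed = seed)`.
#' @param observed_2s_fraction observed 2S STRA8-positive preleptotene cell
#'   fraction fed to the census calculator.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(flank = 1000L, min_replicates = 2L,
                            expressed_threshold = 1, expressed_op = ">=",
                            de_alpha = 0.05, motif = "CNCCTCAG",
                            n_permutations = 10000L, max_stratum = 5L,
                            seed = 1L, sim = sim_config(seed = seed),
                            observed_2s_fraction = 0.44) {
  cfg <- list(flank = as.integer(flank),
              min_replicates = as.integer(min_replicates),
              expressed_threshold = expressed_threshold,
              expressed_op = expressed_op, de_alpha = de_alpha,
              motif = motif, n_permutations = as.integer(n_permutations),
              max_stratum = as.integer(max_stratum), seed = as.integer(seed),
              sim = sim, observed_2s_fraction = observed_2s_fraction)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [pipeline_config()] defaults
#'   (simulation keys under `sim:`).
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  cfg <- do.call(pipeline_config, y)
  if (!is.null(sim_args)) {
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    if (!is.null(sim_args$motif_count_distribution))
      sim_args$motif_count_distribution <-
        unlist(sim_args$motif_count_distribution)
    if (!is.null(sim_args$groups)) sim_args$groups <- unlist(sim_args$groups)
    cfg$sim <- do.call(sim_config, sim_args)
  }
  cfg
}

group_cols <- function(expr, group) {
  names(expr$groups)[expr$groups == group]
}

#' Run the full synthetic-data pipeline
#'
#' Simulates a regulon, calls consensus-bound genes from the replicated
#' peaks, tests differential expression between knockout and high-expression
#' samples, classifies bound-by-direction, runs the motif dose-response
#' analyses, compares every call against the simulation ground truth, and
#' appends the testis cell-census worked example. Deterministic given the
#' configuration (which contains the seed).
#'
#' @param config a `"pipeline_config"`.
#' @param outdir optional directory; when given, all stage outputs (gene
#'   lists, tables, the report JSON) are written there.
#' @param blacklist optional `"interval_set"` applied to every replicate's
#'   peaks before assignment.
#' @return A `"run_report"` (list) with components `counts`, `binding`,
#'   `expression`, `motif`, `recovery`, `census`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         blacklist = NULL) {
  sim <- make_genome(config$sim)
  peaks <- simulate_peaks(sim)
  expr <- simulate_expression(sim)

  if (is.null(blacklist))
    blacklist <- interval_set(character(0), integer(0), integer(0),
                              label = "blacklist")
  flag_peaks <- lapply(peaks$flag, filter_blacklist, blacklist = blacklist)
  control_peaks <- lapply(peaks$control, filter_blacklist,
                          blacklist = blacklist)
  flag_sets <- lapply(flag_peaks, promoter_genes, ann = sim$ann,
                      flank = config$flank)
  control_sets <- lapply(control_peaks, promoter_genes, ann = sim$ann,
                         flank = config$flank)
  calls <- call_bound_genes(flag_sets, control_sets,
                            min_replicates = config$min_replicates)

  frac_of <- function(ps) {
    if (nrow(ps) == 0) return(NA_real_)
    promoter_fraction(ps, sim$ann, config$flank)
  }
  flag_fraction <- mean(vapply(flag_peaks, frac_of, numeric(1)), na.rm = TRUE)
  control_fraction <- mean(vapply(control_peaks, frac_of, numeric(1)),
                           na.rm = TRUE)

  expressed <- expressed_genes(expr$tpm, config$expressed_threshold,
                               op = config$expressed_op)
  de_high <- simple_de_test(expr$tpm, group_cols(expr, "KO"),
                            group_cols(expr, "high"), alpha = config$de_alpha)
  de_low <- simple_de_test(expr$tpm, group_cols(expr, "KO"),
                           group_cols(expr, "low"), alpha = config$de_alpha)
  concordance_r <- fold_change_concordance(de_low, de_high)
  cls <- classify_and_tabulate(calls$bound, de_high, expressed)

  up <- cls$flags$gene_id[cls$flags$up]
  down <- cls$flags$gene_id[cls$flags$down]
  bound_expressed <- intersect(calls$bound, expressed)
  overlap_up <- hypergeom_overlap(length(expressed), length(bound_expressed),
                                  length(up),
                                  length(intersect(bound_expressed, up)))
  overlap_down <- hypergeom_overlap(length(expressed),
                                    length(bound_expressed), length(down),
                                    length(intersect(bound_expressed, down)))

  promoter_counts <- count_promoter_motifs(sim$ann, sim$genome,
                                           motif = config$motif,
                                           flank = config$flank)
  pooled <- do.call(rbind, flag_peaks)
  summit_counts <- count_summit_motifs(pooled, sim$genome,
                                       motif = config$motif)
  corr <- tryCatch(
    motif_score_correlation(summit_counts, pooled$score,
                            n_permutations = config$n_permutations,
                            seed = config$seed),
    error = function(e) list(rho = NA_real_, p = NA_real_,
                             n_peaks = nrow(pooled),
                             n_permutations = config$n_permutations))
  log2fc <- setNames(de_high$log2fc, de_high$gene_id)
  strata <- stratify_by_motif_count(log2fc, promoter_counts,
                                    max_stratum = config$max_stratum)
  cgi_bound <- if (length(calls$bound) > 0)
    mean(has_cgi_promoter(calls$bound, sim$ann, sim$cgi)) else NA_real_

  truth <- sim$truth
  genes <- unique(sim$ann$gene_id)
  truth_unbound <- setdiff(genes, truth$bound_genes)
  truth_activated <- truth$bound_genes[truth$true_log2fc[truth$bound_genes] > 0]
  called_act <- cls$activated
  recovery <- list(
    bound_sensitivity = if (length(truth$bound_genes) > 0)
      length(intersect(calls$bound, truth$bound_genes)) /
        length(truth$bound_genes) else NA_real_,
    bound_fpr = if (length(truth_unbound) > 0)
      length(setdiff(calls$bound, truth$bound_genes)) /
        length(truth_unbound) else NA_real_,
    activated_sensitivity = if (length(truth_activated) > 0)
      length(intersect(called_act, truth_activated)) /
        length(truth_activated) else NA_real_,
    activated_precision = if (length(called_act) > 0)
      length(intersect(called_act, truth_activated)) /
        length(called_act) else NA_real_)

  census <- census_report(cell_census(), stage_table(),
                          observed_2s_fraction = config$observed_2s_fraction,
                          rounding = "paper")

  report <- list(
    counts = list(genes = length(genes), expressed = length(expressed),
                  up = length(up), down = length(down),
                  bound = length(calls$bound),
                  activated = length(called_act)),
    binding = list(flag_promoter_fraction = flag_fraction,
                   control_promoter_fraction = control_fraction,
                   cgi_fraction_of_bound = cgi_bound),
    expression = list(
      fraction_activated_of_up = cls$fraction_activated_of_up,
      fraction_up_bound = unname(cls$fraction_up["bound"]),
      fraction_up_unbound = unname(cls$fraction_up["unbound"]),
      odds_ratio = if (!is.null(cls$fisher)) cls$fisher$odds_ratio
                   else NA_real_,
      fisher_log10_p = if (!is.null(cls$fisher)) cls$fisher$log10_p
                       else NA_real_,
      overlap_up_log10_p = overlap_up$log10_p_over,
      overlap_down_log10_p_depletion = overlap_down$log10_p_under,
      concordance_r = concordance_r),
    motif = list(spearman_rho = corr$rho, permutation_p = corr$p,
                 strata = strata$strata,
                 monotone_medians = strata$monotone_medians),
    recovery = recovery,
    census = unclass(census),
    provenance = list(seed = config$seed,
                      parameters = config[setdiff(names(config), "sim")],
                      sim_parameters = unclass(config$sim)))
  class(report) <- "run_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_simulation(sim, peaks, expr, file.path(outdir, "sim"))
    write_binding_calls(calls, file.path(outdir, "binding_calls.tsv"),
                        file.path(outdir, "bound_genes.txt"))
    write_de_table(de_high, file.path(outdir, "de_high_vs_ko.tsv"))
    write_de_table(de_low, file.path(outdir, "de_low_vs_ko.tsv"))
    write_classification(cls, file.path(outdir, "classification.tsv"))
    write.table(data.frame(gene_id = names(promoter_counts),
                           promoter_motifs = as.integer(promoter_counts)),
                file.path(outdir, "promoter_motif_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(called_act, file.path(outdir, "activated_genes.txt"))
    write_run_report(report, file.path(outdir, "report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  genes %d | expressed %d | up %d | down %d | bound %d | activated %d\n",
              x$counts$genes, x$counts$expressed, x$counts$up,
              x$counts$down, x$counts$bound, x$counts$activated))
  cat(sprintf("  promoter peak fraction: FLAG %.1f%%, control %.1f%%\n",
              100 * x$binding$flag_promoter_fraction,
              100 * x$binding$control_promoter_fraction))
  cat(sprintf("  activated/up = %.1f%%; OR = %.3g (Fisher log10 p %.1f)\n",
              100 * x$expression$fraction_activated_of_up,
              x$expression$odds_ratio, x$expression$fisher_log10_p))
  cat(sprintf("  motif-score Spearman rho = %.2f (permutation p %.2g)\n",
              x$motif$spearman_rho, x$motif$permutation_p))
  cat(sprintf("  recovery: bound sens %.3f, FPR %.4f; activated sens %.3f, precision %.3f\n",
              x$recovery$bound_sensitivity, x$recovery$bound_fpr,
              x$recovery$activated_sensitivity,
              x$recovery$activated_precision))
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report a `"run_report"`.
#' @param path output file.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
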