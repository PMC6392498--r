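# Closed-form estimate of the STRA8-expressing preleptotene fraction of the
# adult mouse testis, from published cell-type counts and stage timings of
# the cycle of the seminiferous epithelium.

#' Testis cell census
#'
#' Per-testis counts of the major testis cell classes, in cells. Defaults are
#' the published adult mouse values (in millions: 3 Sertoli, 2.8
#' spermatogonia, 25 spermatocytes, 99 spermatids, 3.5 interstitial).
#'
#' @param sertoli,spermatogonia,spermatocytes,spermatids,interstitial
#'   cell counts (cells per testis).
#' @return List of class `"cell_census"`.
#' @export
cell_census <- function(sertoli = 3e6, spermatogonia = 2.8e6,
                        spermatocytes = 25e6, spermatids = 99e6,
                        interstitial = 3.5e6) {
  counts <- c(sertoli = sertoli, spermatogonia = spermatogonia,
              spermatocytes = spermatocytes, spermatids = spermatids,
              interstitial = interstitial)
  if (any(counts < 0)) stop("cell counts must be >= 0")
  out <- as.list(counts)
  class(out) <- "cell_census"
  out
}

#' Seminiferous-epithelium stage table
#'
#' Durations of stages VI-VIII of the cycle of the seminiferous epithelium,
#' the fraction of each stage during which preleptotene cells are present
#' (later half of VI, all of VII, first half of VIII), the fraction of
#' tubules of each stage containing STRA8-positive spermatocytes, and the
#' total spermatocyte lifespan. Defaults are the published mouse values.
#'
#' @param duration_hr named numeric: stage durations in hours.
#' @param presence named numeric in \[0,1\]: preleptotene presence fraction
#'   per stage.
#' @param stra8_positive named numeric in \[0,1\]: fraction of tubules with
#'   STRA8-positive spermatocytes per stage. For stage VIII, where
#'   preleptotene cells occupy only the first half, the effective STRA8
#'   weight is `stra8_positive * presence`.
#' @param spermatocyte_lifespan_hr total spermatocyte lifespan in hours.
#' @return List of class `"stage_table"`.
#' @export
stage_table <- function(duration_hr = c(VI = 18.1, VII = 20.6, VIII = 20.8),
                        presence = c(VI = 0.5, VII = 1.0, VIII = 0.5),
                        stra8_positive = c(VI = 0, VII = 0.71, VIII = 1.0),
                        spermatocyte_lifespan_hr = 326) {
  stopifnot(all(duration_hr > 0),
            all(presence >= 0 & presence <= 1),
            all(stra8_positive >= 0 & stra8_positive <= 1),
            spermatocyte_lifespan_hr > 0)
  out <- list(duration_hr = duration_hr, presence = presence,
              stra8_positive = stra8_positive,
              spermatocyte_lifespan_hr = spermatocyte_lifespan_hr)
  class(out) <- "stage_table"
  out
}

#' Total cells per testis
#'
#' @param census a `"cell_census"`.
#' @return Sum of the five cell-class counts.
#' @export
total_cells <- function(census) {
  census$sertoli + census$spermatogonia + census$spermatocytes +
    census$spermatids + census$interstitial
}

#' Preleptotene lifespan
#'
#' Hours a cell spends as a preleptotene spermatocyte: the sum over stages of
#' stage duration times preleptotene presence fraction.
#'
#' @param stages a `"stage_table"`.
#' @return Hours.
#' @export
preleptotene_lifespan <- function(stages) {
  sum(stages$duration_hr * stages$presence[names(stages$duration_hr)])
}

#' Duration of STRA8 expression in preleptotene cells
#'
#' Hours of the preleptotene lifespan during which STRA8 is expressed: the
#' sum over stages of duration times the STRA8-positive tubule fraction
#' weighted by preleptotene presence where that presence is partial.
#'
#' @param stages a `"stage_table"`.
#' @return Hours.
#' @export
stra8_expression_duration <- function(stages) {
  w <- stages$stra8_positive[names(stages$duration_hr)] *
    ifelse(stages$presence[names(stages$duration_hr)] < 1,
           stages$presence[names(stages$duration_hr)], 1)
  sum(stages$duration_hr * w)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Full cell-census report
#'
#' Chains the census and stage arithmetic into the estimate of the
#' STRA8-expressing preleptotene fraction of the adult testis and the
#' enrichment fold achieved by spermatogenesis synchronization.
#'
#' In `rounding = "unrounded"` mode (the default) full precision is carried
#' through. `rounding = "paper"` reproduces the published worked example
#' digit-for-digit by rounding intermediates exactly as printed: the
#' preleptotene lifespan to 40 hr, the STRA8 expression duration to 25 hr,
#' and the preleptotene count truncated to 3.0e6 before the STRA8-positive
#' multiplication.
#'
#' @param census a `"cell_census"`.
#' @param stages a `"stage_table"`.
#' @param observed_2s_fraction fraction of all cells that are STRA8-positive
#'   preleptotene cells in a synchronized-and-staged testis (default 0.44).
#' @param rounding `"unrounded"` or `"paper"`.
#' @return List of class `"census_report"` with fields `total_cells`,
#'   `spermatocyte_fraction`, `preleptotene_lifespan_hr`,
#'   `preleptotene_fraction_of_spermatocytes`, `preleptotene_fraction_of_all`,
#'   `preleptotene_count`, `stra8_duration_hr`,
#'   `stra8_fraction_of_preleptotene`, `stra8_preleptotene_count`,
#'   `stra8_preleptotene_fraction_of_all`, `enrichment_fold`, `rounding`.
#' @export
census_report <- function(census, stages, observed_2s_fraction = 0.44,
                          rounding = c("unrounded", "paper")) {
  rounding <- match.arg(rounding)
  if (observed_2s_fraction <= 0 || observed_2s_fraction > 1)
    stop("observed_2s_fraction must be in (0, 1]")
  total <- total_cells(census)
  if (total == 0) stop("empty census")
  sperm_frac <- census$spermatocytes / total
  lifespan <- preleptotene_lifespan(stages)
  duration <- stra8_expression_duration(stages)
  if (rounding == "paper") {
    lifespan <- round_half_up(lifespan)       # ~40 hr as printed
    duration <- round_half_up(duration)       # ~25 hr as printed
  }
  if (lifespan == 0) stop("zero preleptotene lifespan")
  pl_frac_sperm <- lifespan / stages$spermatocyte_lifespan_hr
  pl_frac_all <- sperm_frac * pl_frac_sperm
  pl_count <- pl_frac_all * total
  stra8_frac_pl <- duration / lifespan
  if (rounding == "paper") {
    # the printed chain truncates ~3.07e6 preleptotene cells to 3.0e6 before
    # applying the 62.5% STRA8-positive fraction
    pl_count_used <- floor(pl_count / 1e5) / 10 * 1e6
  } else {
    pl_count_used <- pl_count
  }
  stra8_pl_count <- stra8_frac_pl * pl_count_used
  stra8_pl_frac_all <- stra8_pl_count / total
  out <- list(total_cells = total,
              spermatocyte_fraction = sperm_frac,
              preleptotene_lifespan_hr = lifespan,
              preleptotene_fraction_of_spermatocytes = pl_frac_sperm,
              preleptotene_fraction_of_all = pl_frac_all,
              preleptotene_count = pl_count,
              stra8_duration_hr = duration,
              stra8_fraction_of_preleptotene = stra8_frac_pl,
              stra8_preleptotene_count = stra8_pl_count,
              stra8_preleptotene_fraction_of_all = stra8_pl_frac_all,
              observed_2s_fraction = observed_2s_fraction,
              enrichment_fold = observed_2s_fraction / stra8_pl_frac_all,
              rounding = rounding)
  class(out) <- "census_report"
  out
}

#' @export
print.census_report <- function(x, ...) {
  cat(sprintf("Testis cell-census report (%s mode)\n", x$rounding))
  cat(sprintf("  total cells per testis:            %.1f x 10^6\n",
              x$total_cells / 1e6))
  cat(sprintf("  spermatocytes:                     %.1f%% of all cells\n",
              100 * x$spermatocyte_fraction))
  cat(sprintf("  preleptotene lifespan:             %.2f hr\n",
              x$preleptotene_lifespan_hr))
  cat(sprintf("  preleptotene / spermatocytes:      %.1f%%\n",
              100 * x$preleptotene_fraction_of_spermatocytes))
  cat(sprintf("  preleptotene / all cells:          %.1f%% (%.2f x 10^6)\n",
              100 * x$preleptotene_fraction_of_all,
              x$preleptotene_count / 1e6))
  cat(sprintf("  STRA8 expression duration:         %.2f hr\n",
              x$stra8_duration_hr))
  cat(sprintf("  STRA8+ / preleptotene:             %.1f%%\n",
              100 * x$stra8_fraction_of_preleptotene))
  cat(sprintf("  STRA8+ preleptotene per testis:    %.2f x 10^6\n",
              x$stra8_preleptotene_count / 1e6))
  cat(sprintf("  STRA8+ preleptotene / all cells:   %.1f%%\n",
              100 * x$stra8_preleptotene_fraction_of_all))
  cat(sprintf("  enrichment at observed %.0f%% 2S:    %.1f-fold\n",
              100 * x$observed_2s_fraction, x$enrichment_fold))
  invisible(x)
}

#' Write a census report as JSON
#'
#' @param report a `"census_report"`.
#' @param path output file.
#' @export
write_census_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
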