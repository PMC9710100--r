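#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' two-strain brainstem microarray design: two groups of 4 samples
#' (treatment = seizure-susceptible DBA/1-like, control = C57BL/6-like),
#' log-normal intensities, planted fold changes of at least 2 in both
#' directions, and a toy genome in which all six lncRNA positional
#' categories plus lincRNA--neighbor pairs with a known direction
#' concordance are planted.
#'
#' @param n_coding number of coding transcripts on the array.
#' @param n_lncrna number of lncRNA transcripts on the array.
#' @param n_samples_per_group samples per group (study design: 4).
#' @param planted_de_fraction fraction of free (non-genome-planted)
#'   transcripts that carry a planted expression shift.
#' @param planted_log2fc planted shift in log2 units (>= 1 so planted
#'   effects exceed the fold-change >= 2 filter in expectation).
#' @param noise_sd residual SD of log2 intensity within a group.
#' @param baseline_log2_mean mean log2 baseline intensity.
#' @param baseline_log2_sd between-transcript SD of the log2 baseline.
#' @param chrom_sizes named integer vector, chromosome name -> length (bp).
#' @param category_counts named vector over [LNC_CATEGORIES]: how many
#'   lncRNAs to plant per positional category. Intergenic plants are placed
#'   > 300 kb from every coding gene and therefore yield no neighbor pairs.
#' @param n_linc_pairs number of intergenic lncRNAs planted with exactly one
#'   differentially expressed coding neighbor inside the 300 kb window.
#' @param concordant_fraction fraction of planted lincRNA--neighbor pairs
#'   whose two members share a regulation direction (planted as an exact
#'   count, `round(concordant_fraction * n_linc_pairs)`).
#' @param pair_direction_split length-4 numeric (up_up, down_down, up_down,
#'   down_up) giving the relative frequencies of the four direction
#'   categories among planted pairs; renormalized so the concordant and
#'   discordant halves each sum to 1. The default follows the printed
#'   direction split of the study this design emulates.
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical across calls.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_coding = 800L,
                       n_lncrna = 1200L,
                       n_samples_per_group = 4L,
                       planted_de_fraction = 0.1,
                       planted_log2fc = 2,
                       noise_sd = 0.25,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       chrom_sizes = NULL,
                       category_counts = NULL,
                       n_linc_pairs = 40L,
                       concordant_fraction = 0.685,
                       pair_direction_split = c(up_up = 12.9, down_down = 55.6,
                                                up_down = 8.0, down_up = 22.5),
                       seed = 1L) {
  if (is.null(chrom_sizes)) {
    chrom_sizes <- stats::setNames(rep(120e6, 20), paste0("chr", c(1:19, "X")))
  }
  if (is.null(category_counts)) {
    category_counts <- c(sense_overlapping = 12L, intronic = 6L,
                         natural_antisense = 6L, nonoverlapping_antisense = 4L,
                         bidirectional = 4L, intergenic = 20L)
  }
  chrom_sizes <- unlist(chrom_sizes)          # YAML configs arrive as lists
  category_counts <- unlist(category_counts)
  if (length(category_counts) > 0 &&
      (is.null(names(category_counts)) || any(!nzchar(names(category_counts))))) {
    stop("configuration error: category_counts must be fully named ",
         "(use a named mapping in YAML configs)", call. = FALSE)
  }
  missing_cat <- setdiff(LNC_CATEGORIES, names(category_counts))
  category_counts[missing_cat] <- 0L
  cfg <- list(
    n_coding = as.integer(n_coding),
    n_lncrna = as.integer(n_lncrna),
    n_samples_per_group = as.integer(n_samples_per_group),
    planted_de_fraction = planted_de_fraction,
    planted_log2fc = planted_log2fc,
    noise_sd = noise_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    chrom_sizes = chrom_sizes,
    category_counts = as.integer(category_counts[LNC_CATEGORIES]) |>
      stats::setNames(LNC_CATEGORIES),
    n_linc_pairs = as.integer(n_linc_pairs),
    concordant_fraction = concordant_fraction,
    pair_direction_split = pair_direction_split,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_coding, cfg$n_lncrna, cfg$n_samples_per_group,
              cfg$n_linc_pairs, cfg$category_counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("configuration error: all counts must be non-negative", call. = FALSE)
  }
  if (cfg$n_samples_per_group < 1) {
    stop("configuration error: need at least one sample per group", call. = FALSE)
  }
  fracs <- c(cfg$planted_de_fraction, cfg$concordant_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("configuration error: fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$planted_log2fc < 1) {
    stop("configuration error: planted_log2fc must be >= 1 so planted ",
         "effects exceed the fold-change >= 2 threshold", call. = FALSE)
  }
  if (cfg$noise_sd < 0) {
    stop("configuration error: noise_sd must be non-negative", call. = FALSE)
  }
  if (length(cfg$chrom_sizes) < 1 || is.null(names(cfg$chrom_sizes))) {
    stop("configuration error: chrom_sizes must be a named vector", call. = FALSE)
  }
  if (length(cfg$pair_direction_split) != 4 || any(cfg$pair_direction_split < 0)) {
    stop("configuration error: pair_direction_split must be 4 non-negative values",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_coding, "coding +", x$n_lncrna, "lncRNA transcripts,",
      2L * x$n_samples_per_group, "samples\n")
  cat("  planted log2FC ", x$planted_log2fc, ", noise SD ", x$noise_sd,
      " (log2), DE fraction ", x$planted_de_fraction, "\n", sep = "")
  cat("  planted categories:",
      paste(names(x$category_counts), x$category_counts, sep = "=", collapse = " "),
      "\n")
  cat("  lincRNA pairs:", x$n_linc_pairs,
      sprintf("(concordant fraction %.3f), seed %d\n",
              x$concordant_fraction, x$seed))
  invisible(x)
}
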