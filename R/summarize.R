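# Descriptive summaries over the primary-filter DE set: transcript length
# histogram (fixed nt bins so the 1000-2000 bin is directly comparable
# across runs), chromosome distribution, positional category fractions,
# volcano coordinates and hierarchical-clustering leaf orders.

.LENGTH_BREAKS <- c(0, 500, 1000, 2000, 3000, Inf)
.LENGTH_LABELS <- c("<500", "500-1000", "1000-2000", "2000-3000", ">=3000")

frac_table <- function(x, levels = NULL) {
  if (length(x) == 0) return(stats::setNames(numeric(), character()))
  tab <- if (is.null(levels)) table(x) else table(factor(x, levels = levels))
  stats::setNames(as.numeric(tab) / length(x), names(tab))
}

length_bins <- function(lengths) {
  cut(lengths, breaks = .LENGTH_BREAKS, labels = .LENGTH_LABELS, right = FALSE)
}

#' Descriptive summary bundle over DE transcripts
#'
#' Computed over primary-filter passes, reported for the up set, the down
#' set and their union: lncRNA length histogram (bins <500, 500-1000,
#' 1000-2000, 2000-3000, >=3000 nt), chromosome distribution, positional
#' category fractions, plus a volcano table (signed log2 fold change,
#' -log10 P) over every tested transcript.
#'
#' @param de `de_result` data.frame from [de_test()].
#' @param classes optional classification data.frame from [classify_all()].
#' @param annotation optional [transcript_set()] (required for the length
#'   and chromosome summaries).
#' @return list of class `summary_bundle` with elements `length_histogram`,
#'   `chrom_distribution`, `category_fractions` (each a list all/up/down of
#'   fraction vectors summing to 1) and `volcano_table`.
#' @export
summarize_de <- function(de, classes = NULL, annotation = NULL) {
  pass <- de[de$passes_primary, , drop = FALSE]
  if (nrow(pass) == 0) warning("empty summary: no transcripts pass the primary filter")
  lnc_pass <- pass[!is.na(pass$biotype) & pass$biotype == "lncRNA", , drop = FALSE]
  arms <- list(all = lnc_pass$transcript_id,
               up = lnc_pass$transcript_id[lnc_pass$regulation == "up"],
               down = lnc_pass$transcript_id[lnc_pass$regulation == "down"])

  len_hist <- chrom_dist <- cat_frac <- NULL
  if (!is.null(annotation)) {
    tx <- annotation$transcripts
    len_hist <- lapply(arms, function(ids) {
      ids <- intersect(ids, tx$transcript_id)
      frac_table(as.character(length_bins(tx$length[match(ids, tx$transcript_id)])),
                 levels = .LENGTH_LABELS)
    })
    chrom_dist <- lapply(arms, function(ids) {
      ids <- intersect(ids, tx$transcript_id)
      frac_table(tx$chrom[match(ids, tx$transcript_id)])
    })
  }
  if (!is.null(classes)) {
    cat_frac <- lapply(arms, function(ids) {
      frac_table(classes$category[match(intersect(ids, classes$lncrna_id),
                                        classes$lncrna_id)],
                 levels = LNC_CATEGORIES)
    })
  }
  volcano <- data.frame(
    transcript_id = de$transcript_id,
    log2_fold_change = ifelse(de$regulation == "up", 1, -1) * log2(de$fold_change),
    neg_log10_p = -log10(pmax(de$p_value, .Machine$double.xmin)),
    stringsAsFactors = FALSE
  )
  structure(list(length_histogram = len_hist, chrom_distribution = chrom_dist,
                 category_fractions = cat_frac, volcano_table = volcano),
            class = "summary_bundle")
}

#' Hierarchical-clustering leaf orders for a DE expression heatmap
#'
#' Average-linkage agglomerative clustering on Euclidean distance of
#' row-z-scored log2 intensities; rows with zero variance cannot be
#' z-scored and are dropped with a warning. Deterministic for fixed input.
#'
#' @param mat intensity matrix restricted to the transcripts of interest
#'   (>= 2 rows and >= 2 columns).
#' @return list(transcript_order, sample_order): ids in leaf order.
#' @export
cluster_order <- function(mat) {
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need >= 2 transcripts and >= 2 samples", call. = FALSE)
  }
  lg <- log2(mat)
  sds <- apply(lg, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance row(s)")
    lg <- lg[sds > 0, , drop = FALSE]
    if (nrow(lg) < 2) stop("fewer than 2 rows left after the zero-variance guard",
                           call. = FALSE)
  }
  z <- t(scale(t(lg)))
  hr <- stats::hclust(stats::dist(z), method = "average")
  hc <- stats::hclust(stats::dist(t(z)), method = "average")
  list(transcript_order = rownames(z)[hr$order],
       sample_order = colnames(z)[hc$order])
}
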