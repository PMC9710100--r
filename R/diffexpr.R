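#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")` (step-up,
#' monotone, capped at 1), kept as a named operation so the FDR family used
#' by [de_test()] is explicit and swappable.
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("data error: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Fold change and regulation direction for one transcript
#'
#' Ratio of group arithmetic means of (normalized) linear intensities,
#' reported >= 1 with an up/down label: up if the treatment mean is at
#' least the control mean (equal means tie-break to up), down otherwise.
#'
#' @param mat numeric matrix, transcripts x samples.
#' @param groups named vector sample -> `treatment`/`control`, covering the
#'   matrix columns.
#' @param transcript_id row to measure.
#' @return list(fold_change, regulation).
#' @export
fold_change <- function(mat, groups, transcript_id) {
  x <- mat[transcript_id, , drop = TRUE]
  g <- groups[colnames(mat)]
  mt <- mean(x[g == "treatment"])
  mc <- mean(x[g == "control"])
  if (mt == 0 && mc == 0) stop("undefined-ratio error: both group means zero",
                               call. = FALSE)
  if (mt >= mc) list(fold_change = mt / mc, regulation = "up")
  else list(fold_change = mc / mt, regulation = "down")
}

# Vectorized two-sample Welch t-test on the rows of log2(mat).
# Returns p-values; rows with zero pooled variance get p = 1 when the group
# means are equal and p = 0 otherwise (the zero-noise degenerate case).
row_welch_p <- function(log2mat, is_treat) {
  x <- log2mat[, is_treat, drop = FALSE]
  y <- log2mat[, !is_treat, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) {
    stop("statistics error: each group needs >= 2 samples for a variance estimate",
         call. = FALSE)
  }
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  unname(p)
}

#' Two-group differential expression with the study's two filter regimes
#'
#' Per transcript: linear fold change with up/down direction (treatment vs
#' control), a Welch unequal-variance two-sample t-test on log2 normalized
#' intensities, and BH-FDR correction. The primary filter is fold change
#' >= `fc_min` and P < `p_max`; the sensitivity filter is fold change >=
#' `fc_min` and FDR < `fdr_max`. lncRNAs and mRNAs are corrected as
#' separate families by default (they are reported as separate result
#' sets); set `fdr_family = "joint"` for a single family.
#'
#' @param mat normalized intensity matrix, transcripts x samples.
#' @param groups named vector sample -> `treatment`/`control`.
#' @param biotype optional named vector transcript -> `coding`/`lncRNA`;
#'   required for `fdr_family = "biotype"` (transcripts missing from it are
#'   treated as one extra family).
#' @param fc_min,p_max,fdr_max filter thresholds (defaults 2, 0.05, 0.05).
#' @param fdr_family `"biotype"` (default) or `"joint"`.
#' @return data.frame of class `de_result`: transcript_id, biotype,
#'   fold_change, regulation, p_value, fdr, passes_primary,
#'   passes_sensitivity.
#' @export
de_test <- function(mat, groups, biotype = NULL, fc_min = 2, p_max = 0.05,
                    fdr_max = 0.05, fdr_family = c("biotype", "joint")) {
  fdr_family <- match.arg(fdr_family)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("row_%d", seq_len(nrow(mat)))
  g <- groups[colnames(mat)]
  if (anyNA(g)) stop("every sample needs a group label", call. = FALSE)
  is_treat <- g == "treatment"
  if (any(mat <= 0)) stop("data error: intensities must be positive", call. = FALSE)

  mt <- rowMeans(mat[, is_treat, drop = FALSE])
  mc <- rowMeans(mat[, !is_treat, drop = FALSE])
  up <- mt >= mc
  fc <- ifelse(up, mt / mc, mc / mt)
  p <- row_welch_p(log2(mat), is_treat)

  ids <- rownames(mat)
  bt <- if (is.null(biotype)) rep(NA_character_, length(ids)) else
    unname(biotype[ids])
  if (fdr_family == "biotype" && !is.null(biotype)) {
    fam <- ifelse(is.na(bt), "other", bt)
    fdr <- stats::ave(p, fam, FUN = bh_fdr)
  } else {
    fdr <- bh_fdr(p)
  }
  res <- data.frame(
    transcript_id = ids,
    biotype = bt,
    fold_change = unname(fc),
    regulation = ifelse(up, "up", "down"),
    p_value = p,
    fdr = fdr,
    stringsAsFactors = FALSE
  )
  res$passes_primary <- res$fold_change >= fc_min & res$p_value < p_max
  res$passes_sensitivity <- res$fold_change >= fc_min & res$fdr < fdr_max
  class(res) <- c("de_result", "data.frame")
  res
}

#' Write a DE result table (Seqname/GeneSymbol/FoldChange/Regulation/P/FDR)
#' @param de a `de_result` data.frame.
#' @param path output TSV path.
#' @param symbols optional named vector transcript_id -> gene symbol.
#' @export
write_de_table <- function(de, path, symbols = NULL) {
  out <- data.frame(
    Seqname = de$transcript_id,
    GeneSymbol = if (is.null(symbols)) de$transcript_id else
      unname(symbols[de$transcript_id]),
    FoldChange = de$fold_change,
    Regulation = de$regulation,
    P = de$p_value,
    FDR = de$fdr,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
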