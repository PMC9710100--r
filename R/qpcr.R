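# Relative quantification of qPCR Ct tables by the 2^-ddCt method:
# per-sample dCt against the reference gene (GAPDH in the emulated study),
# centred on the control-group mean dCt so the control group's mean
# relative expression is 1, as in the study's reporting convention.

#' Read a Ct table from CSV
#'
#' Expected columns: sample_id, group (treatment/control), gene_id, ct.
#' @param path CSV path.
#' @param reference_gene reference gene id (default `Gapdh`).
#' @return a `ct_table` data.frame with a `reference_gene` attribute.
#' @export
read_ct_table <- function(path, reference_gene = "Gapdh") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene_id", "ct")
  if (!all(need %in% names(tab))) {
    stop("data error: Ct table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  attr(tab, "reference_gene") <- reference_gene
  class(tab) <- c("ct_table", "data.frame")
  tab
}

#' Write a Ct table to CSV
#' @param tab a `ct_table`.
#' @param path output path.
#' @export
write_ct_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab)[, c("sample_id", "group", "gene_id", "ct")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Relative expression of one gene by 2^-ddCt
#'
#' Technical replicates are averaged per sample first; then per sample
#' dCt = Ct(gene) - Ct(reference), and the relative value is
#' 2^-(dCt - mean control dCt). The reported fold vs control is the
#' treatment-group mean of relative values (control-group mean is 1 by
#' construction); direction is up when the fold is >= 1.
#'
#' @param tab a `ct_table`.
#' @param gene_id target gene.
#' @param reference_gene overrides the table's reference-gene attribute.
#' @return list of class `relative_expression`: gene_id, fold_vs_control,
#'   direction, per_sample (data.frame sample_id, group, relative).
#' @export
ddct <- function(tab, gene_id, reference_gene = NULL) {
  if (is.null(reference_gene)) reference_gene <- attr(tab, "reference_gene")
  if (is.null(reference_gene)) stop("data error: no reference gene", call. = FALSE)
  d <- as.data.frame(tab)
  ct_of <- function(g) {
    sub <- d[d$gene_id == g, , drop = FALSE]
    agg <- stats::aggregate(ct ~ sample_id + group, data = sub, FUN = mean)
    agg
  }
  tg <- ct_of(gene_id)
  if (nrow(tg) == 0) stop("gene ", gene_id, " absent from Ct table", call. = FALSE)
  rf <- ct_of(reference_gene)
  ref_ct <- stats::setNames(rf$ct, rf$sample_id)
  if (!all(tg$sample_id %in% names(ref_ct))) {
    stop("data error: reference gene Ct missing in some sample(s)", call. = FALSE)
  }
  if (!all(c("treatment", "control") %in% tg$group)) {
    stop("gene ", gene_id, " needs Ct values in both groups", call. = FALSE)
  }
  dct <- tg$ct - ref_ct[tg$sample_id]
  ddct_val <- dct - mean(dct[tg$group == "control"])
  rel <- 2^(-ddct_val)
  fold <- mean(rel[tg$group == "treatment"])
  structure(list(
    gene_id = gene_id,
    fold_vs_control = fold,
    direction = if (fold >= 1) "up" else "down",
    per_sample = data.frame(sample_id = tg$sample_id, group = tg$group,
                            relative = unname(rel), stringsAsFactors = FALSE)
  ), class = "relative_expression")
}

#' Relative expression for every target gene in a Ct table
#' @param tab a `ct_table`.
#' @param genes gene ids (default: all non-reference genes present).
#' @return data.frame: gene_id, fold_vs_control, direction.
#' @export
ddct_all <- function(tab, genes = NULL) {
  ref <- attr(tab, "reference_gene")
  if (is.null(genes)) genes <- setdiff(unique(tab$gene_id), ref)
  rows <- lapply(genes, function(g) {
    r <- ddct(tab, g)
    data.frame(gene_id = g, fold_vs_control = r$fold_vs_control,
               direction = r$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Direction concordance between qPCR and array results
#'
#' @param rel data.frame from [ddct_all()] (or a list of
#'   `relative_expression` objects).
#' @param de `de_result` data.frame from [de_test()].
#' @return named logical: TRUE where the qPCR direction equals the array
#'   regulation; genes absent from either input are excluded with a
#'   message.
#' @export
concordance_with_array <- function(rel, de) {
  if (!is.data.frame(rel)) {
    rel <- do.call(rbind, lapply(rel, function(r) {
      data.frame(gene_id = r$gene_id, fold_vs_control = r$fold_vs_control,
                 direction = r$direction, stringsAsFactors = FALSE)
    }))
  }
  ix <- match(rel$gene_id, de$transcript_id)
  if (anyNA(ix)) {
    message("excluding ", sum(is.na(ix)), " gene(s) absent from the array results")
  }
  keep <- !is.na(ix)
  stats::setNames(rel$direction[keep] == de$regulation[ix[keep]],
                  rel$gene_id[keep])
}
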