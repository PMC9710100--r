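# Cis-pairing of differentially expressed lncRNAs with coding genes:
# antisense lncRNA -- sense mRNA pairs (overlap-based) and intergenic
# lincRNA -- nearest-neighbor pairs (< 300 kb boundary gap), plus
# direction-concordance statistics over the resulting pairs.

pair_frame <- function(lncrna_id = character(), mrna_id = character(),
                       relationship = character(), distance = numeric(),
                       lnc_regulation = character(),
                       mrna_regulation = character()) {
  data.frame(lncrna_id = lncrna_id, mrna_id = mrna_id,
             relationship = relationship, distance = distance,
             lnc_regulation = lnc_regulation,
             mrna_regulation = mrna_regulation,
             concordant = lnc_regulation == mrna_regulation,
             stringsAsFactors = FALSE)
}

#' Antisense lncRNA -- sense mRNA pairs among DE transcripts
#'
#' Pairs every lncRNA classified into an antisense category
#' (natural or nonoverlapping antisense) and passing the primary DE filter
#' with its classified partner mRNA, provided the partner also passes the
#' primary filter. A nonoverlapping-antisense lncRNA lying wholly within
#' one intron of its partner is labelled `intronic_antisense`. Distance is
#' 0 for all (overlapping) antisense relationships. Partners without a DE
#' record are skipped with a warning.
#'
#' @param classes classification data.frame from [classify_all()].
#' @param de `de_result` data.frame from [de_test()].
#' @param annotation optional [transcript_set()], used only to refine the
#'   `intronic_antisense` label.
#' @return data.frame of pairs: lncrna_id, mrna_id, relationship, distance,
#'   lnc_regulation, mrna_regulation, concordant.
#' @export
antisense_pairs <- function(classes, de, annotation = NULL) {
  as_cat <- c("natural_antisense", "nonoverlapping_antisense")
  cl <- classes[classes$category %in% as_cat, , drop = FALSE]
  de_ix <- match(cl$lncrna_id, de$transcript_id)
  keep <- !is.na(de_ix) & de$passes_primary[de_ix]
  cl <- cl[keep, , drop = FALSE]
  if (nrow(cl) == 0) return(pair_frame())

  p_ix <- match(cl$partner_id, de$transcript_id)
  if (anyNA(p_ix)) {
    warning("skipping ", sum(is.na(p_ix)),
            " antisense pair(s) whose partner mRNA has no DE record")
    cl <- cl[!is.na(p_ix), , drop = FALSE]
    p_ix <- p_ix[!is.na(p_ix)]
  }
  keep <- de$passes_primary[p_ix]
  cl <- cl[keep, , drop = FALSE]
  p_ix <- p_ix[keep]
  if (nrow(cl) == 0) return(pair_frame())

  rel <- cl$category
  if (!is.null(annotation)) {
    for (i in which(rel == "nonoverlapping_antisense")) {
      if (within_one_intron(cl$lncrna_id[i], cl$partner_id[i], annotation)) {
        rel[i] <- "intronic_antisense"
      }
    }
  }
  l_ix <- match(cl$lncrna_id, de$transcript_id)
  pair_frame(cl$lncrna_id, cl$partner_id, rel, rep(0, nrow(cl)),
             de$regulation[l_ix], de$regulation[p_ix])
}

within_one_intron <- function(lnc_id, cod_id, annotation) {
  tx <- annotation$transcripts
  l <- tx[tx$transcript_id == lnc_id, ]
  c_tx <- tx[tx$transcript_id == cod_id, ]
  if (nrow(l) == 0 || nrow(c_tx) == 0) return(FALSE)
  ce <- annotation$exons[annotation$exons$transcript_id == cod_id, ]
  introns <- IRanges::setdiff(IRanges::IRanges(c_tx$start + 1L, c_tx$end),
                              IRanges::IRanges(ce$start + 1L, ce$end))
  any(IRanges::start(introns) <= l$start + 1L & IRanges::end(introns) >= l$end)
}

#' lincRNA -- nearest coding neighbor pairs within a window
#'
#' For each differentially expressed intergenic lncRNA, emits a pair with
#' the nearest differentially expressed coding gene upstream AND the
#' nearest one downstream within `window` bp (so one lincRNA can yield up
#' to two pairs). Distance is the gap between nearest transcript
#' boundaries; the upstream/downstream label is taken from the lincRNA's
#' perspective in its own strand orientation.
#'
#' @param annotation a [transcript_set()].
#' @param classes classification data.frame from [classify_all()].
#' @param de `de_result` data.frame from [de_test()].
#' @param window neighbor window, bp (default 300 kb).
#' @return data.frame of pairs (see [antisense_pairs()] for columns).
#' @export
lincrna_neighbors <- function(annotation, classes, de, window = 300000) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  tx <- annotation$transcripts
  linc_ids <- classes$lncrna_id[classes$category == "intergenic"]
  de_pass <- de$transcript_id[de$passes_primary]
  linc_ids <- intersect(linc_ids, de_pass)
  coding <- tx[tx$biotype == "coding" & tx$transcript_id %in% de_pass, ,
               drop = FALSE]
  if (length(linc_ids) == 0 || nrow(coding) == 0) return(pair_frame())

  reg <- stats::setNames(de$regulation, de$transcript_id)
  rows <- list()
  for (lid in linc_ids) {
    l <- tx[tx$transcript_id == lid, ]
    cand <- coding[coding$chrom == l$chrom, , drop = FALSE]
    if (nrow(cand) == 0) next
    left <- cand[cand$end <= l$start, , drop = FALSE]
    right <- cand[cand$start >= l$end, , drop = FALSE]
    sides <- list()
    if (nrow(left) > 0) {
      gap <- l$start - left$end
      j <- which(gap == min(gap))
      j <- j[order(left$transcript_id[j])][1]
      if (gap[j] < window) {
        sides$left <- list(id = left$transcript_id[j], gap = gap[j])
      }
    }
    if (nrow(right) > 0) {
      gap <- right$start - l$end
      j <- which(gap == min(gap))
      j <- j[order(right$transcript_id[j])][1]
      if (gap[j] < window) {
        sides$right <- list(id = right$transcript_id[j], gap = gap[j])
      }
    }
    for (side in names(sides)) {
      s <- sides[[side]]
      rel <- if (l$strand == "+") {
        if (side == "left") "upstream" else "downstream"
      } else {
        if (side == "left") "downstream" else "upstream"
      }
      rows[[length(rows) + 1L]] <- pair_frame(lid, s$id, rel, s$gap,
                                              unname(reg[lid]), unname(reg[s$id]))
    }
  }
  if (length(rows) == 0) return(pair_frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Direction-concordance summary over coexpression pairs
#'
#' Fractions of the four direction categories (up/up, down/down, up/down,
#' down/up, lncRNA direction first) computed as exact counts over the pair
#' total; the concordant fraction is the up/up + down/down sum.
#'
#' @param pairs data.frame from [antisense_pairs()] or
#'   [lincrna_neighbors()].
#' @return list of class `concordance_summary`: n_pairs, frac_up_up,
#'   frac_down_down, frac_up_down, frac_down_up, frac_concordant.
#' @export
concordance_summary <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("empty-input error: no pairs to summarize", call. = FALSE)
  }
  n <- nrow(pairs)
  n_uu <- sum(pairs$lnc_regulation == "up" & pairs$mrna_regulation == "up")
  n_dd <- sum(pairs$lnc_regulation == "down" & pairs$mrna_regulation == "down")
  n_ud <- sum(pairs$lnc_regulation == "up" & pairs$mrna_regulation == "down")
  n_du <- sum(pairs$lnc_regulation == "down" & pairs$mrna_regulation == "up")
  structure(list(
    n_pairs = n,
    frac_up_up = n_uu / n,
    frac_down_down = n_dd / n,
    frac_up_down = n_ud / n,
    frac_down_up = n_du / n,
    frac_concordant = (n_uu + n_dd) / n
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(paste0("concordance over %d pairs: %.1f%% concordant ",
                     "(up/up %.1f%%, down/down %.1f%%; up/down %.1f%%, ",
                     "down/up %.1f%%)\n"),
              x$n_pairs, 100 * x$frac_concordant, 100 * x$frac_up_up,
              100 * x$frac_down_down, 100 * x$frac_up_down,
              100 * x$frac_down_up))
  invisible(x)
}

#' Write a pair table mirroring the published result-table layout
#' @param pairs pair data.frame.
#' @param de `de_result` data.frame (for fold changes).
#' @param path output TSV path.
#' @param symbols optional named vector transcript_id -> gene symbol.
#' @export
write_pairs_tsv <- function(pairs, de, path, symbols = NULL) {
  sym <- function(id) if (is.null(symbols)) id else unname(symbols[id])
  ix_l <- match(pairs$lncrna_id, de$transcript_id)
  ix_m <- match(pairs$mrna_id, de$transcript_id)
  out <- data.frame(
    lncRNA_seqname = pairs$lncrna_id,
    lncRNA_symbol = sym(pairs$lncrna_id),
    lncRNA_fold_change = de$fold_change[ix_l],
    lncRNA_regulation = pairs$lnc_regulation,
    genome_relationship = pairs$relationship,
    gene_seqname = pairs$mrna_id,
    gene_symbol = sym(pairs$mrna_id),
    gene_fold_change = de$fold_change[ix_m],
    gene_regulation = pairs$mrna_regulation,
    distance_bp = pairs$distance,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
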