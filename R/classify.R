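# Six-way positional classification of lncRNAs relative to coding
# transcripts. Category definitions (in precedence order, strongest
# physical overlap first):
#   sense_overlapping        same strand, exon-exon overlap
#   intronic                 same strand, no exon-exon overlap, lncRNA exon
#                            overlaps an intron of the coding transcript
#   natural_antisense        opposite strand, exon-exon overlap
#   nonoverlapping_antisense opposite strand, gene-body overlap, no
#                            exon-exon overlap
#   bidirectional            opposite strand, no overlap, head-to-head
#                            (divergent 5' ends) within `window` bp
#   intergenic               none of the above
# Among multiple qualifying partners the largest overlap (or smallest 5'
# gap) wins; ties break by lexicographic transcript id.

.CATEGORY_RANK <- stats::setNames(seq_along(LNC_CATEGORIES), LNC_CATEGORIES)

# per-(lnc, coding) relation: category + evidence, or NULL
pair_relation <- function(lnc_tx, lnc_ex, cod_tx, cod_ex, window) {
  if (lnc_tx$chrom != cod_tx$chrom) return(NULL)
  same <- lnc_tx$strand == cod_tx$strand
  body_ov <- min(lnc_tx$end, cod_tx$end) - max(lnc_tx$start, cod_tx$start)
  if (body_ov > 0) {
    exon_ov <- sum(IRanges::width(IRanges::intersect(lnc_ex, cod_ex)))
    if (same) {
      if (exon_ov > 0) return(list(category = "sense_overlapping", evidence = exon_ov))
      introns <- IRanges::setdiff(
        IRanges::IRanges(cod_tx$start + 1L, cod_tx$end), cod_ex)
      intron_ov <- sum(IRanges::width(IRanges::intersect(lnc_ex, introns)))
      if (intron_ov > 0) return(list(category = "intronic", evidence = intron_ov))
      return(NULL)
    } else {
      if (exon_ov > 0) return(list(category = "natural_antisense", evidence = exon_ov))
      return(list(category = "nonoverlapping_antisense", evidence = body_ov))
    }
  }
  if (!same) {
    # head-to-head: the + strand 5' end (its start) lies at or beyond the
    # - strand 5' end (its end), i.e. transcription is divergent
    if (lnc_tx$strand == "+") { plus <- lnc_tx; minus <- cod_tx }
    else { plus <- cod_tx; minus <- lnc_tx }
    if (plus$start >= minus$end) {
      gap <- plus$start - minus$end
      if (gap < window) return(list(category = "bidirectional", evidence = gap))
    }
  }
  NULL
}

#' Classify one lncRNA into its positional category
#'
#' @param lnc_id lncRNA transcript id (biotype must be `lncRNA`).
#' @param annotation a [transcript_set()] containing the lncRNA and the
#'   coding transcripts to classify against.
#' @param window head-to-head promoter window, bp (default 1000).
#' @return one-row data.frame: lncrna_id, category, partner_id (NA iff
#'   intergenic), evidence_bp (overlap bp, or 5' gap bp for bidirectional;
#'   NA for intergenic).
#' @export
classify_lncrna <- function(lnc_id, annotation, window = 1000) {
  classify_all(annotation, lnc_ids = lnc_id, window = window)
}

#' Classify every lncRNA in an annotation
#'
#' @param annotation a [transcript_set()].
#' @param lnc_ids lncRNA transcript ids to classify (default: all
#'   transcripts with biotype `lncRNA`).
#' @param window head-to-head promoter window, bp (default 1000).
#' @return data.frame with one row per lncRNA: lncrna_id, category,
#'   partner_id, evidence_bp.
#' @export
classify_all <- function(annotation, lnc_ids = NULL, window = 1000) {
  tx <- annotation$transcripts
  if (is.null(lnc_ids)) {
    lnc_ids <- tx$transcript_id[tx$biotype == "lncRNA"]
  } else {
    bt <- tx$biotype[match(lnc_ids, tx$transcript_id)]
    if (anyNA(bt)) stop("unknown transcript id", call. = FALSE)
    if (any(bt != "lncRNA")) {
      stop("usage error: classify_lncrna applies to lncRNA transcripts only",
           call. = FALSE)
    }
  }
  empty <- data.frame(lncrna_id = character(), category = character(),
                      partner_id = character(), evidence_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lnc_ids) == 0) return(empty)

  coding <- tx[tx$biotype == "coding", , drop = FALSE]
  exons_by_tx <- split(annotation$exons[, c("start", "end")],
                       annotation$exons$transcript_id)
  ir_of <- function(tid) {
    e <- exons_by_tx[[tid]]
    IRanges::IRanges(e$start + 1L, e$end)
  }

  # candidate coding partners via interval overlap with a `window` margin
  lnc_tab <- tx[match(lnc_ids, tx$transcript_id), , drop = FALSE]
  if (nrow(coding) > 0) {
    chroms <- union(lnc_tab$chrom, coding$chrom)
    lnc_gr <- GenomicRanges::GRanges(factor(lnc_tab$chrom, chroms),
                                     IRanges::IRanges(lnc_tab$start + 1L, lnc_tab$end))
    cod_gr <- GenomicRanges::GRanges(factor(coding$chrom, chroms),
                                     IRanges::IRanges(coding$start + 1L, coding$end))
    hits <- GenomicRanges::findOverlaps(lnc_gr, cod_gr, maxgap = window,
                                        ignore.strand = TRUE)
    cand <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  } else {
    cand <- list()
  }

  rows <- vector("list", length(lnc_ids))
  for (i in seq_along(lnc_ids)) {
    lid <- lnc_ids[i]
    lnc_tx <- lnc_tab[i, ]
    lnc_ex <- ir_of(lid)
    best <- NULL
    for (j in cand[[as.character(i)]]) {
      cod_tx <- coding[j, ]
      rel <- pair_relation(lnc_tx, lnc_ex, cod_tx, ir_of(cod_tx$transcript_id),
                           window)
      if (is.null(rel)) next
      rel$partner <- cod_tx$transcript_id
      if (is.null(best) || better_relation(rel, best)) best <- rel
    }
    rows[[i]] <- if (is.null(best)) {
      data.frame(lncrna_id = lid, category = "intergenic",
                 partner_id = NA_character_, evidence_bp = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(lncrna_id = lid, category = best$category,
                 partner_id = best$partner, evidence_bp = best$evidence,
                 stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# precedence ladder, then evidence (max overlap / min gap), then id
better_relation <- function(a, b) {
  ra <- .CATEGORY_RANK[[a$category]]; rb <- .CATEGORY_RANK[[b$category]]
  if (ra != rb) return(ra < rb)
  if (a$category == "bidirectional") {
    if (a$evidence != b$evidence) return(a$evidence < b$evidence)
  } else if (a$evidence != b$evidence) {
    return(a$evidence > b$evidence)
  }
  a$partner < b$partner
}

#' Write classification results as TSV
#' @param classes data.frame from [classify_all()].
#' @param path output path.
#' @export
write_classification <- function(classes, path) {
  utils::write.table(classes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
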