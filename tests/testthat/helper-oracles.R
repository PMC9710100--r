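# Independent oracles, coded from first principles and kept deliberately
# naive (loops, integer position sets, exhaustive enumeration) so they do
# not share a code path with the package implementation.

# Literal transcription of the quantile-normalization procedure: sort each
# column ascending, average across columns at each rank, substitute, then
# restore the input order (assumes no ties in any column).
qn_literal <- function(mat) {
  sorted <- matrix(0, nrow(mat), ncol(mat))
  for (j in seq_len(ncol(mat))) sorted[, j] <- sort(mat[, j])
  rank_mean <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) rank_mean[i] <- mean(sorted[i, ])
  out <- mat
  for (j in seq_len(ncol(mat))) {
    rk <- rank(mat[, j], ties.method = "first")
    for (i in seq_len(nrow(mat))) out[i, j] <- rank_mean[rk[i]]
  }
  out
}

# Hand-coded BH step-up: adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper tail: over all draws of size n from a
# universe of N genes of which the first K form the set, the fraction with
# at least k hits.
hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# ---- brute-force positional classifier -------------------------------------
# Literal all-pairs rule checker over integer base-position sets.
brute_positions <- function(ex) {
  unlist(Map(function(s, e) seq.int(s + 1L, e), ex$start, ex$end))
}

brute_classify_one <- function(lid, ts, window = 1000) {
  tx <- ts$transcripts
  l <- tx[tx$transcript_id == lid, ]
  lex <- ts$exons[ts$exons$transcript_id == lid, ]
  lpos <- brute_positions(lex)
  lbody <- seq.int(l$start + 1L, l$end)
  coding <- tx[tx$biotype == "coding", , drop = FALSE]
  rank_of <- c(sense_overlapping = 1, intronic = 2, natural_antisense = 3,
               nonoverlapping_antisense = 4, bidirectional = 5)
  best <- NULL
  for (j in seq_len(nrow(coding))) {
    cc <- coding[j, ]
    if (cc$chrom != l$chrom) next
    cex <- ts$exons[ts$exons$transcript_id == cc$transcript_id, ]
    cpos <- brute_positions(cex)
    cbody <- seq.int(cc$start + 1L, cc$end)
    same <- cc$strand == l$strand
    exon_ov <- length(intersect(lpos, cpos))
    body_ov <- length(intersect(lbody, cbody))
    cat_ev <- NULL
    if (body_ov > 0) {
      if (same && exon_ov > 0) cat_ev <- c("sense_overlapping", exon_ov)
      else if (same) {
        intron_ov <- length(intersect(lpos, setdiff(cbody, cpos)))
        if (intron_ov > 0) cat_ev <- c("intronic", intron_ov)
      } else if (exon_ov > 0) cat_ev <- c("natural_antisense", exon_ov)
      else cat_ev <- c("nonoverlapping_antisense", body_ov)
    } else if (!same) {
      plus <- if (l$strand == "+") l else cc
      minus <- if (l$strand == "+") cc else l
      if (plus$start >= minus$end && plus$start - minus$end < window) {
        cat_ev <- c("bidirectional", plus$start - minus$end)
      }
    }
    if (is.null(cat_ev)) next
    cand <- list(category = cat_ev[1], evidence = as.numeric(cat_ev[2]),
                 partner = cc$transcript_id)
    if (is.null(best)) { best <- cand; next }
    rb <- rank_of[[best$category]]; rc <- rank_of[[cand$category]]
    take <- if (rc != rb) rc < rb
    else if (cand$category == "bidirectional" && cand$evidence != best$evidence)
      cand$evidence < best$evidence
    else if (cand$category != "bidirectional" && cand$evidence != best$evidence)
      cand$evidence > best$evidence
    else cand$partner < best$partner
    if (take) best <- cand
  }
  if (is.null(best)) {
    data.frame(lncrna_id = lid, category = "intergenic",
               partner_id = NA_character_, evidence_bp = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(lncrna_id = lid, category = best$category,
               partner_id = best$partner, evidence_bp = best$evidence,
               stringsAsFactors = FALSE)
  }
}

brute_classify_all <- function(ts, window = 1000) {
  ids <- ts$transcripts$transcript_id[ts$transcripts$biotype == "lncRNA"]
  do.call(rbind, lapply(ids, brute_classify_one, ts = ts, window = window))
}

# ---- random toy genome -----------------------------------------------------
# Small random annotation: coding transcripts with 1-3 exons and single-exon
# lncRNAs scattered over a 20 kb toy chromosome so every relation type
# arises by chance.
random_toy_genome <- function(n_coding = 12, n_lnc = 12, seed = 1,
                              chrom_span = 20000L) {
  set.seed(seed)
  tx <- list(); ex <- list()
  for (i in seq_len(n_coding)) {
    tid <- sprintf("tc%02d", i)
    n_ex <- sample(1:3, 1)
    s <- sample.int(chrom_span - 5000L, 1)
    starts <- s
    ends <- s + sample(200:1200, 1)
    while (length(starts) < n_ex) {
      gap <- sample(100:800, 1)
      w <- sample(200:1200, 1)
      starts <- c(starts, ends[length(ends)] + gap)
      ends <- c(ends, ends[length(ends)] + gap + w)
    }
    tx[[length(tx) + 1]] <- data.frame(
      transcript_id = tid, gene_id = tid, chrom = "toy",
      strand = sample(c("+", "-"), 1), start = starts[1], end = ends[n_ex],
      biotype = "coding", stringsAsFactors = FALSE)
    ex[[length(ex) + 1]] <- data.frame(transcript_id = tid, start = starts,
                                       end = ends, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_lnc)) {
    tid <- sprintf("tl%02d", i)
    s <- sample.int(chrom_span - 4000L, 1)
    e <- s + sample(150:3000, 1)
    tx[[length(tx) + 1]] <- data.frame(
      transcript_id = tid, gene_id = tid, chrom = "toy",
      strand = sample(c("+", "-"), 1), start = s, end = e,
      biotype = "lncRNA", stringsAsFactors = FALSE)
    ex[[length(ex) + 1]] <- data.frame(transcript_id = tid, start = s, end = e,
                                       stringsAsFactors = FALSE)
  }
  transcript_set(do.call(rbind, tx), do.call(rbind, ex))
}

# small annotation builder for hand-constructed cases
toy_annotation <- function(tx_rows, exon_rows) {
  transcript_set(
    do.call(rbind, lapply(tx_rows, function(r)
      data.frame(transcript_id = r[[1]], gene_id = r[[1]], chrom = r[[2]],
                 strand = r[[3]], start = as.integer(r[[4]]),
                 end = as.integer(r[[5]]), biotype = r[[6]],
                 stringsAsFactors = FALSE))),
    do.call(rbind, lapply(exon_rows, function(r)
      data.frame(transcript_id = r[[1]], start = as.integer(r[[2]]),
                 end = as.integer(r[[3]]), stringsAsFactors = FALSE)))
  )
}

# minimal hand-made DE result frame
toy_de <- function(ids, fc, reg, p = NULL, fdr = NULL, biotype = NULL) {
  p <- if (is.null(p)) rep(0.01, length(ids)) else p
  fdr <- if (is.null(fdr)) p else fdr
  d <- data.frame(transcript_id = ids,
                  biotype = if (is.null(biotype)) NA_character_ else biotype,
                  fold_change = fc, regulation = reg, p_value = p, fdr = fdr,
                  stringsAsFactors = FALSE)
  d$passes_primary <- d$fold_change >= 2 & d$p_value < 0.05
  d$passes_sensitivity <- d$fold_change >= 2 & d$fdr < 0.05
  class(d) <- c("de_result", "data.frame")
  d
}
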