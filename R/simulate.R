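# Synthetic-data generators with planted ground truth.
#
# Geometry constants for the toy genome. Every planted structure lives in
# its own 2 Mb block so that planted categories cannot interfere with each
# other: features occupy at most ~270 kb at the block start, leaving > 1.7 Mb
# (>> the 300 kb neighbor window) to the next block's features.
.BLOCK_WIDTH <- 2e6
.CODING_SPAN <- 9000L          # coding gene template: 3 exons over 9 kb
.CODING_EXONS <- rbind(c(0L, 2000L), c(4000L, 6000L), c(8000L, 9000L))

#' Simulate a two-group expression matrix with planted fold changes
#'
#' Null transcripts share a log-normal intensity model (Gaussian on log2,
#' then exponentiated); planted differentially expressed transcripts are
#' shifted by `planted_log2fc` log2 units up or down in the treatment group.
#'
#' @param config a [sim_config()].
#' @param truth optional ground truth from [simulate_genome()]; when given,
#'   its transcripts (with their planted DE status and directions) occupy
#'   the first rows and the matrix is padded with array-only probes up to
#'   `n_coding + n_lncrna` rows.
#' @return list with `matrix` (positive intensities, rows = transcripts,
#'   columns = samples), `groups` (named vector sample -> treatment/control),
#'   `biotype` (named vector transcript -> coding/lncRNA) and `truth`
#'   (a `ground_truth` with `de_status` and signed `log2fc` for every row).
#' @export
simulate_expression <- function(config, truth = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  if (is.null(truth)) {
    coding_ids <- sprintf("NM_A%05d", seq_len(config$n_coding))
    lnc_ids <- if (config$n_lncrna > 0) sprintf("NR_A%05d", seq_len(config$n_lncrna)) else character()
    de_status <- stats::setNames(rep("null", length(coding_ids) + length(lnc_ids)),
                                 c(coding_ids, lnc_ids))
  } else {
    planted_coding <- names(truth$biotype)[truth$biotype == "coding"]
    planted_lnc <- names(truth$biotype)[truth$biotype == "lncRNA"]
    if (length(planted_coding) > config$n_coding ||
        length(planted_lnc) > config$n_lncrna) {
      stop("configuration error: n_coding/n_lncrna smaller than the number ",
           "of genome-planted transcripts", call. = FALSE)
    }
    coding_ids <- c(planted_coding,
                    sprintf("NM_A%05d", seq_len(config$n_coding - length(planted_coding))))
    extra_lnc <- config$n_lncrna - length(planted_lnc)
    lnc_ids <- c(planted_lnc,
                 if (extra_lnc > 0) sprintf("NR_A%05d", seq_len(extra_lnc)) else character())
    de_status <- stats::setNames(rep("null", length(coding_ids) + length(lnc_ids)),
                                 c(coding_ids, lnc_ids))
    de_status[names(truth$de_status)] <- truth$de_status
  }
  ids <- c(coding_ids, lnc_ids)
  biotype <- stats::setNames(rep(c("coding", "lncRNA"),
                                 c(length(coding_ids), length(lnc_ids))), ids)

  # free (non-planted) transcripts pick up planted_de_fraction DE, with the
  # study's down-skewed direction split
  free <- names(de_status)[de_status == "null"]
  if (is.null(truth)) {
    n_free_de <- round(config$planted_de_fraction * length(free))
  } else {
    n_free_de <- round(config$planted_de_fraction * length(free))
  }
  if (n_free_de > 0) {
    chosen <- sample(free, n_free_de)
    de_status[chosen] <- ifelse(stats::runif(n_free_de) < 0.7, "down", "up")
  }

  log2fc <- ifelse(de_status == "up", config$planted_log2fc,
                   ifelse(de_status == "down", -config$planted_log2fc, 0))
  names(log2fc) <- ids

  n <- config$n_samples_per_group
  samples <- c(paste0("DBA1_", seq_len(n)), paste0("C57BL6_", seq_len(n)))
  groups <- stats::setNames(rep(c("treatment", "control"), each = n), samples)

  baseline <- stats::rnorm(length(ids), config$baseline_log2_mean,
                           config$baseline_log2_sd)
  shift <- outer(log2fc, as.numeric(groups == "treatment"))
  noise <- matrix(stats::rnorm(length(ids) * length(samples), 0, config$noise_sd),
                  nrow = length(ids))
  log2val <- baseline + shift + noise
  mat <- 2^log2val
  dimnames(mat) <- list(ids, samples)

  out_truth <- structure(list(de_status = de_status, log2fc = log2fc,
                              biotype = biotype,
                              true_category = if (!is.null(truth)) truth$true_category else
                                stats::setNames(character(), character()),
                              true_pairs = if (!is.null(truth)) truth$true_pairs else
                                empty_true_pairs()),
                         class = "ground_truth")
  list(matrix = mat, groups = groups, biotype = biotype, truth = out_truth)
}

empty_true_pairs <- function() {
  data.frame(lncrna_id = character(), mrna_id = character(),
             relationship = character(), lnc_regulation = character(),
             mrna_regulation = character(), concordant = logical(),
             stringsAsFactors = FALSE)
}

#' Simulate a toy genome annotation with planted positional categories
#'
#' Plants, per six-way positional category, the requested number of lncRNAs
#' in geometries that force the classifier's decision rules to recover that
#' category, plus `n_linc_pairs` intergenic lncRNAs each with exactly one
#' differentially expressed coding neighbor < 300 kb away (the planted
#' lincRNA--neighbor pairs carrying `concordant_fraction`). Intergenic
#' category plants are > 300 kb (and > 1000 bp) from every coding gene.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (a [transcript_set()]) and `truth`
#'   (`ground_truth` with `true_category`, `true_pairs`, `de_status`,
#'   signed `log2fc` and `biotype` for every planted transcript).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  counts <- config$category_counts
  bad <- setdiff(names(counts), LNC_CATEGORIES)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)

  n_partner <- sum(counts[c("sense_overlapping", "intronic", "natural_antisense",
                            "nonoverlapping_antisense", "bidirectional")]) +
    config$n_linc_pairs
  if (config$n_coding < n_partner) {
    stop("configuration error: n_coding must cover the ", n_partner,
         " planted partner genes", call. = FALSE)
  }
  # every coding transcript is annotated: partner genes live in the planted
  # blocks, the rest get isolated blocks of their own
  specs <- c(rep(names(counts), counts), rep("linc_pair", config$n_linc_pairs),
             rep("free_coding", config$n_coding - n_partner))
  # blocks per chromosome; shuffle block order so categories spread over chroms
  capacity <- floor(config$chrom_sizes / .BLOCK_WIDTH)
  if (sum(capacity) < length(specs)) {
    stop("placement error: chromosomes too short to place ", length(specs),
         " structures (capacity ", sum(capacity), ")", call. = FALSE)
  }
  if (length(specs) == 0) {
    return(list(annotation = empty_transcript_set(),
                truth = structure(list(de_status = stats::setNames(character(), character()),
                                       log2fc = stats::setNames(numeric(), character()),
                                       biotype = stats::setNames(character(), character()),
                                       true_category = stats::setNames(character(), character()),
                                       true_pairs = empty_true_pairs()),
                                  class = "ground_truth")))
  }
  specs <- sample(specs)
  block_chrom <- rep(names(capacity), capacity)
  block_off <- unlist(lapply(capacity, function(k) (seq_len(k) - 1) * .BLOCK_WIDTH),
                      use.names = FALSE)
  # draw block slots over the whole genome so features spread across chroms
  slots <- sample(sum(capacity), length(specs))
  block_chrom <- block_chrom[slots]
  block_off <- block_off[slots]
  idx <- seq_along(specs)

  tx <- list(); ex <- list()
  lnc_n <- 0L; cod_n <- 0L
  true_category <- character(); de_status <- character()
  pair_rows <- list()

  add_coding <- function(chrom, B, strand = "+") {
    cod_n <<- cod_n + 1L
    tid <- sprintf("NM_%06d", cod_n)
    tx[[length(tx) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = sprintf("Gene%04d", cod_n),
      chrom = chrom, strand = strand, start = B, end = B + .CODING_SPAN,
      biotype = "coding", stringsAsFactors = FALSE)
    ex[[length(ex) + 1L]] <<- data.frame(
      transcript_id = tid, start = B + .CODING_EXONS[, 1],
      end = B + .CODING_EXONS[, 2], stringsAsFactors = FALSE)
    tid
  }
  add_lnc <- function(chrom, strand, start, end) {
    lnc_n <<- lnc_n + 1L
    tid <- sprintf("NR_%06d", lnc_n)
    tx[[length(tx) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = sprintf("Lnc%04d", lnc_n),
      chrom = chrom, strand = strand, start = start, end = end,
      biotype = "lncRNA", stringsAsFactors = FALSE)
    ex[[length(ex) + 1L]] <<- data.frame(transcript_id = tid, start = start,
                                         end = end, stringsAsFactors = FALSE)
    tid
  }
  draw_dir <- function() if (stats::runif(1) < 0.7) "down" else "up"

  # planted pair direction table: exact counts from concordant_fraction and
  # the four-way direction split, shuffled over pair slots
  np <- config$n_linc_pairs
  if (np > 0) {
    w <- config$pair_direction_split
    n_conc <- round(config$concordant_fraction * np)
    n_dd <- if (n_conc > 0) round(n_conc * w[["down_down"]] /
                                    (w[["up_up"]] + w[["down_down"]])) else 0L
    n_disc <- np - n_conc
    n_du <- if (n_disc > 0) round(n_disc * w[["down_up"]] /
                                    (w[["up_down"]] + w[["down_up"]])) else 0L
    pair_dirs <- rbind(
      if (n_conc - n_dd > 0) matrix(rep(c("up", "up"), n_conc - n_dd), ncol = 2, byrow = TRUE),
      if (n_dd > 0) matrix(rep(c("down", "down"), n_dd), ncol = 2, byrow = TRUE),
      if (n_disc - n_du > 0) matrix(rep(c("up", "down"), n_disc - n_du), ncol = 2, byrow = TRUE),
      if (n_du > 0) matrix(rep(c("down", "up"), n_du), ncol = 2, byrow = TRUE))
    pair_dirs <- pair_dirs[sample(nrow(pair_dirs)), , drop = FALSE]
  }
  pair_i <- 0L

  for (i in idx) {
    chrom <- block_chrom[i]
    B <- block_off[i] + 5e5   # margin inside the block
    spec <- specs[i]
    L <- sample(400:3500, 1)
    if (spec == "sense_overlapping") {
      cid <- add_coding(chrom, B)
      lid <- add_lnc(chrom, "+", B + 1000L, B + 1000L + L)
      true_category[lid] <- "sense_overlapping"
      de_status[lid] <- draw_dir()
      de_status[cid] <- draw_dir()
    } else if (spec == "intronic") {
      Li <- sample(300:1800, 1)
      cid <- add_coding(chrom, B)
      lid <- add_lnc(chrom, "+", B + 2100L, B + 2100L + Li)
      true_category[lid] <- "intronic"
      de_status[lid] <- draw_dir()
      de_status[cid] <- draw_dir()
    } else if (spec == "natural_antisense") {
      cid <- add_coding(chrom, B)
      lid <- add_lnc(chrom, "-", B + 1000L, B + 1000L + L)
      true_category[lid] <- "natural_antisense"
      d <- draw_dir()
      de_status[lid] <- d
      de_status[cid] <- if (stats::runif(1) < config$concordant_fraction) d else
        setdiff(c("up", "down"), d)
    } else if (spec == "nonoverlapping_antisense") {
      Li <- sample(300:1800, 1)
      cid <- add_coding(chrom, B)
      lid <- add_lnc(chrom, "-", B + 2100L, B + 2100L + Li)
      true_category[lid] <- "nonoverlapping_antisense"
      d <- draw_dir()
      de_status[lid] <- d
      de_status[cid] <- if (stats::runif(1) < config$concordant_fraction) d else
        setdiff(c("up", "down"), d)
    } else if (spec == "bidirectional") {
      gap <- sample(100:900, 1)
      lid <- add_lnc(chrom, "-", B, B + L)              # 5' end at B + L
      cid <- add_coding(chrom, B + L + gap, "+")        # 5' end at its start
      true_category[lid] <- "bidirectional"
      de_status[lid] <- draw_dir()
      de_status[cid] <- draw_dir()
    } else if (spec == "intergenic") {
      lid <- add_lnc(chrom, sample(c("+", "-"), 1), B, B + L)
      true_category[lid] <- "intergenic"
      de_status[lid] <- draw_dir()
    } else if (spec == "free_coding") {
      cid <- add_coding(chrom, B)
      de_status[cid] <- "null"
    } else { # linc_pair: coding gene, then the lincRNA 20-250 kb downstream of it
      pair_i <- pair_i + 1L
      d <- sample(20000:250000, 1)
      s <- sample(c("+", "-"), 1)
      cid <- add_coding(chrom, B)
      lid <- add_lnc(chrom, s, B + .CODING_SPAN + d, B + .CODING_SPAN + d + L)
      true_category[lid] <- "intergenic"
      de_status[lid] <- pair_dirs[pair_i, 1]
      de_status[cid] <- pair_dirs[pair_i, 2]
      # relationship from the lincRNA's perspective, in its own orientation:
      # the coding gene sits on its lower-coordinate side
      rel <- if (s == "+") "upstream" else "downstream"
      pair_rows[[pair_i]] <- data.frame(
        lncrna_id = lid, mrna_id = cid, relationship = rel,
        lnc_regulation = pair_dirs[pair_i, 1],
        mrna_regulation = pair_dirs[pair_i, 2],
        concordant = pair_dirs[pair_i, 1] == pair_dirs[pair_i, 2],
        stringsAsFactors = FALSE)
    }
  }

  annotation <- transcript_set(do.call(rbind, tx), do.call(rbind, ex))
  log2fc <- ifelse(de_status == "up", config$planted_log2fc,
                   ifelse(de_status == "down", -config$planted_log2fc, 0))
  names(log2fc) <- names(de_status)
  biotype <- stats::setNames(annotation$transcripts$biotype,
                             annotation$transcripts$transcript_id)
  truth <- structure(list(
    de_status = de_status,
    log2fc = log2fc,
    biotype = biotype,
    true_category = true_category,
    true_pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else empty_true_pairs()
  ), class = "ground_truth")
  list(annotation = annotation, truth = truth)
}

#' Simulate the full study (genome + coupled expression matrix)
#'
#' Convenience wrapper: [simulate_genome()] then [simulate_expression()]
#' with the genome's ground truth, so planted positional categories, pair
#' directions and expression shifts are mutually consistent.
#' @param config a [sim_config()].
#' @return list with `annotation`, `matrix`, `groups`, `biotype`, `truth`.
#' @export
simulate_study <- function(config) {
  g <- simulate_genome(config)
  e <- simulate_expression(config, truth = g$truth)
  list(annotation = g$annotation, matrix = e$matrix, groups = e$groups,
       biotype = e$biotype, truth = e$truth)
}

#' Simulate a qPCR Ct table from planted ground truth
#'
#' Ct is defined as `sample_offset + gene_offset - log2(abundance) + noise`,
#' so at zero noise the 2^-ddCt identity recovers planted linear folds
#' exactly; the reference gene is included in every sample and per-sample
#' offsets emulate global efficiency shifts that reference-gene
#' normalization must remove.
#'
#' @param de_truth a `ground_truth` (from [simulate_expression()] /
#'   [simulate_genome()]) providing `de_status` and signed `log2fc`.
#' @param genes target gene ids (default: up to 9 planted DE transcripts).
#' @param n_replicates biological replicates per group (study design: 4).
#' @param noise_sd SD of Ct noise, cycles.
#' @param seed RNG seed.
#' @param reference_gene reference gene id added to every sample.
#' @return a `ct_table` data.frame (sample_id, group, gene_id, ct) with a
#'   `reference_gene` attribute.
#' @export
simulate_qpcr <- function(de_truth, genes = NULL, n_replicates = 4L,
                          noise_sd = 0.1, seed = 1L,
                          reference_gene = "Gapdh") {
  if (n_replicates < 1) stop("configuration error: n_replicates must be >= 1",
                             call. = FALSE)
  if (is.null(reference_gene) || !nzchar(reference_gene)) {
    stop("configuration error: a reference gene is required", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(genes)) {
    de <- names(de_truth$de_status)[de_truth$de_status != "null"]
    if (length(de) == 0) stop("no DE transcripts to assay", call. = FALSE)
    genes <- utils::head(de, 9L)
  }
  log2fc <- de_truth$log2fc[genes]
  log2fc[is.na(log2fc)] <- 0
  names(log2fc) <- genes

  samples <- data.frame(
    sample_id = c(paste0("DBA1_q", seq_len(n_replicates)),
                  paste0("C57BL6_q", seq_len(n_replicates))),
    group = rep(c("treatment", "control"), each = n_replicates),
    stringsAsFactors = FALSE)
  sample_off <- stats::setNames(stats::rnorm(nrow(samples), 20, 0.5),
                                samples$sample_id)
  all_genes <- c(genes, reference_gene)
  gene_off <- stats::setNames(c(stats::rnorm(length(genes), 4, 1), -2),
                              all_genes)

  rows <- expand.grid(sample_id = samples$sample_id, gene_id = all_genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$group <- samples$group[match(rows$sample_id, samples$sample_id)]
  abund_log2 <- ifelse(rows$gene_id == reference_gene, 0,
                       ifelse(rows$group == "treatment",
                              log2fc[rows$gene_id], 0))
  rows$ct <- sample_off[rows$sample_id] + gene_off[rows$gene_id] -
    abund_log2 + stats::rnorm(nrow(rows), 0, noise_sd)
  tab <- rows[, c("sample_id", "group", "gene_id", "ct")]
  attr(tab, "reference_gene") <- reference_gene
  class(tab) <- c("ct_table", "data.frame")
  tab
}

#' Simulate gene-set collections with planted enrichment
#'
#' Builds GO/KEGG-like stand-in sets over a transcript universe; the first
#' `n_enriched` sets are preferentially sampled from a supplied gene list so
#' over-representation is detectable by construction.
#'
#' @param universe character vector of gene ids.
#' @param enriched_in ids the enriched sets should over-sample (e.g. the
#'   upregulated DE list); may be empty.
#' @param n_sets total number of sets.
#' @param n_enriched number of planted enriched sets.
#' @param set_size_range integer range of set sizes.
#' @param seed RNG seed.
#' @return a `gene_set_collection`: list(sets = named list, universe).
#' @export
simulate_gene_sets <- function(universe, enriched_in = character(),
                               n_sets = 20L, n_enriched = 3L,
                               set_size_range = c(10L, 50L), seed = 1L) {
  set.seed(seed)
  enriched_in <- intersect(enriched_in, universe)
  sets <- list()
  for (i in seq_len(n_sets)) {
    sz <- sample(set_size_range[1]:set_size_range[2], 1)
    sz <- min(sz, length(universe))
    if (i <= n_enriched && length(enriched_in) > 0) {
      n_hit <- min(length(enriched_in), ceiling(sz * 0.6))
      members <- c(sample(enriched_in, n_hit),
                   sample(setdiff(universe, enriched_in), sz - n_hit))
    } else {
      members <- sample(universe, sz)
    }
    sets[[sprintf("SET_%03d", i)]] <- sort(unique(members))
  }
  gene_set_collection(sets, universe)
}
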