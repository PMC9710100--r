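#' Run the full profiling pipeline from a declarative config
#'
#' Orchestrates every stage: simulate (or load) the expression matrix and
#' annotation, quantile-normalize, test differential expression under the
#' primary (FC >= 2, P < 0.05) and sensitivity (FC >= 2, FDR < 0.05)
#' regimes, classify lncRNAs into the six positional categories, build
#' antisense and lincRNA-neighbor pairs with a concordance summary, run
#' gene-set over-representation on the up and down mRNA lists, quantify
#' the simulated (or supplied) qPCR Ct table, and write the descriptive
#' summary bundle. All outputs are plain-text tables; for a fixed config
#' and seed the run is byte-identical across repeats.
#'
#' @param config path to a YAML config, or an equivalent named list. Top
#'   keys: `simulate` (a [sim_config()] argument list) OR `inputs`
#'   (`expression`, `groups`, `annotation`, optional `gene_sets`,
#'   `ct_table` paths); optional `thresholds` (`fc_min`, `p_max`,
#'   `fdr_max`, `bidirectional_window`, `neighbor_window`), `de_regime`
#'   (`primary`/`sensitivity`, controls the filtered DE tables), `qpcr`
#'   (`n_replicates`, `noise_sd`), `enrich` (`n_sets`), `seed`,
#'   `output_dir`.
#' @param output_dir overrides the config's output directory.
#' @param seed overrides the config's seed.
#' @return (invisibly) a list with every stage's in-memory result and
#'   `output_dir`.
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  out <- output_dir %||% cfg$output_dir %||% "lncarray_output"
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  th <- utils::modifyList(list(fc_min = 2, p_max = 0.05, fdr_max = 0.05,
                               bidirectional_window = 1000,
                               neighbor_window = 300000),
                          cfg$thresholds %||% list())
  regime <- cfg$de_regime %||% "primary"
  if (!regime %in% c("primary", "sensitivity")) {
    stop("stage config: de_regime must be 'primary' or 'sensitivity'", call. = FALSE)
  }
  log_lines <- c("lncarray pipeline run",
                 paste0("package_version: ", as.character(utils::packageVersion("lncarray"))),
                 paste0("seed: ", cfg$seed),
                 paste0("de_regime: ", regime),
                 paste0("thresholds: ", paste(names(th), unlist(th), sep = "=",
                                              collapse = " ")))

  # --- stage: inputs -------------------------------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, utils::modifyList(cfg$simulate %||% list(),
                                                  list(seed = cfg$seed)))
      simulate_study(sc)
    })
    mat <- sim$matrix; groups <- sim$groups; annotation <- sim$annotation
    biotype <- sim$biotype; truth <- sim$truth
    log_lines <- c(log_lines, paste0("simulated: ", nrow(mat), " transcripts x ",
                                     ncol(mat), " samples"))
  } else {
    inp <- cfg$inputs
    if (is.null(inp$expression) || is.null(inp$groups) || is.null(inp$annotation)) {
      stop("stage 'inputs' failed: config needs inputs$expression, inputs$groups ",
           "and inputs$annotation (or a simulate block)", call. = FALSE)
    }
    mat <- stage("inputs", read_expression_tsv(inp$expression))
    groups <- stage("inputs", read_groups_tsv(inp$groups))
    annotation <- stage("inputs", read_gtf(inp$annotation))
    biotype <- stats::setNames(annotation$transcripts$biotype,
                               annotation$transcripts$transcript_id)[rownames(mat)]
    names(biotype) <- rownames(mat)
  }
  write_expression_tsv(mat, file.path(out, "expression_raw.tsv"))
  write_groups_tsv(groups, file.path(out, "groups.tsv"))
  write_gtf(annotation, file.path(out, "annotation.gtf"))

  # --- stage: normalize ----------------------------------------------------
  norm <- stage("normalize", quantile_normalize(mat))
  write_expression_tsv(norm, file.path(out, "expression_normalized.tsv"))

  # --- stage: differential expression --------------------------------------
  de <- stage("diffexpr", de_test(norm, groups, biotype = biotype,
                                  fc_min = th$fc_min, p_max = th$p_max,
                                  fdr_max = th$fdr_max))
  for (bt in c("lncRNA", "coding")) {
    sub <- de[!is.na(de$biotype) & de$biotype == bt, , drop = FALSE]
    lab <- if (bt == "coding") "mrna" else "lncrna"
    write_de_table(sub[sub$passes_primary, ],
                   file.path(out, paste0("de_", lab, "_primary.tsv")))
    write_de_table(sub[sub$passes_sensitivity, ],
                   file.path(out, paste0("de_", lab, "_sensitivity.tsv")))
  }
  filtered <- if (regime == "primary") de[de$passes_primary, ] else
    de[de$passes_sensitivity, ]
  write_de_table(filtered, file.path(out, "de_filtered.tsv"))
  log_lines <- c(log_lines,
                 sprintf("de: %d/%d lncRNA, %d/%d mRNA pass primary filter",
                         sum(de$passes_primary & de$biotype == "lncRNA", na.rm = TRUE),
                         sum(de$biotype == "lncRNA", na.rm = TRUE),
                         sum(de$passes_primary & de$biotype == "coding", na.rm = TRUE),
                         sum(de$biotype == "coding", na.rm = TRUE)))

  # --- stage: classify -----------------------------------------------------
  classes <- stage("classify", classify_all(annotation,
                                            window = th$bidirectional_window))
  write_classification(classes, file.path(out, "classification.tsv"))

  # --- stage: pairs --------------------------------------------------------
  as_pairs <- stage("pairs", antisense_pairs(classes, de, annotation))
  linc_pairs <- stage("pairs", lincrna_neighbors(annotation, classes, de,
                                                 window = th$neighbor_window))
  write_pairs_tsv(as_pairs, de, file.path(out, "antisense_pairs.tsv"))
  write_pairs_tsv(linc_pairs, de, file.path(out, "lincrna_pairs.tsv"))
  conc <- if (nrow(linc_pairs) > 0) concordance_summary(linc_pairs) else NULL
  if (!is.null(conc)) {
    utils::write.table(data.frame(statistic = names(unclass(conc)),
                                  value = unlist(unclass(conc))),
                       file.path(out, "lincrna_concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines, sprintf("lincRNA pairs: %d, concordant %.3f",
                                      conc$n_pairs, conc$frac_concordant))
  }

  # --- stage: enrichment ---------------------------------------------------
  arms <- split_by_regulation(de[!is.na(de$biotype) & de$biotype == "coding", ])
  universe <- de$transcript_id[!is.na(de$biotype) & de$biotype == "coding"]
  collection <- if (!is.null(cfg$inputs$gene_sets)) {
    stage("enrich", read_gmt(cfg$inputs$gene_sets, universe = universe))
  } else {
    n_sets <- (cfg$enrich %||% list())$n_sets %||% 20L
    simulate_gene_sets(universe, enriched_in = arms$up, n_sets = n_sets,
                       seed = cfg$seed + 3L)
  }
  write_gmt(collection, file.path(out, "gene_sets.gmt"))
  for (arm in c("up", "down")) {
    if (length(arms[[arm]]) == 0) next
    enr <- stage("enrich", hypergeom_enrich(arms[[arm]], collection))
    utils::write.table(enr, file.path(out, paste0("enrichment_", arm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: qpcr ---------------------------------------------------------
  qp <- cfg$qpcr %||% list()
  ct <- if (!is.null(cfg$inputs$ct_table)) {
    stage("qpcr", read_ct_table(cfg$inputs$ct_table,
                                reference_gene = qp$reference_gene %||% "Gapdh"))
  } else if (!is.null(truth) && any(truth$de_status != "null")) {
    stage("qpcr", simulate_qpcr(truth,
                                n_replicates = qp$n_replicates %||% 4L,
                                noise_sd = qp$noise_sd %||% 0.1,
                                seed = cfg$seed + 4L))
  } else NULL
  qpcr_rel <- NULL
  if (!is.null(ct)) {
    write_ct_table(ct, file.path(out, "qpcr_ct.csv"))
    qpcr_rel <- stage("qpcr", ddct_all(ct))
    qpcr_rel$array_concordant <-
      unname(concordance_with_array(qpcr_rel, de)[qpcr_rel$gene_id])
    utils::write.table(qpcr_rel, file.path(out, "qpcr_relative_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: summaries ----------------------------------------------------
  bundle <- stage("summarize", summarize_de(de, classes, annotation))
  for (comp in c("length_histogram", "chrom_distribution", "category_fractions")) {
    b <- bundle[[comp]]
    if (is.null(b)) next
    rows <- do.call(rbind, lapply(names(b), function(arm) {
      if (length(b[[arm]]) == 0) return(NULL)
      data.frame(arm = arm, bin = names(b[[arm]]), fraction = unname(b[[arm]]),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(rows)) {
      utils::write.table(rows, file.path(out, paste0("summary_", comp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  utils::write.table(bundle$volcano_table, file.path(out, "volcano.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  de_ids <- filtered$transcript_id
  clust <- NULL
  if (length(de_ids) >= 2) {
    clust <- stage("summarize", suppressWarnings(
      cluster_order(norm[de_ids, , drop = FALSE])))
    writeLines(clust$transcript_order, file.path(out, "cluster_transcript_order.txt"))
    writeLines(clust$sample_order, file.path(out, "cluster_sample_order.txt"))
  }

  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(list(output_dir = out, matrix = mat, normalized = norm,
                 groups = groups, annotation = annotation, de = de,
                 classes = classes, antisense_pairs = as_pairs,
                 lincrna_pairs = linc_pairs, concordance = conc,
                 gene_sets = collection, qpcr = qpcr_rel, summary = bundle,
                 cluster = clust, truth = truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
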