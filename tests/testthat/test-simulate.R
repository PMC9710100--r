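test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_coding = -1), "counts")
  expect_error(sim_config(planted_de_fraction = 1.5), "fractions")
  expect_error(sim_config(planted_log2fc = 0.5), "planted_log2fc")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
})

test_that("a fixed seed makes every generator byte-identical across calls", {
  cfg <- sim_config(n_coding = 40, n_lncrna = 50, n_linc_pairs = 4, seed = 1,
                    category_counts = stats::setNames(rep(1L, 6), LNC_CATEGORIES))
  e1 <- simulate_expression(cfg); e2 <- simulate_expression(cfg)
  expect_identical(e1$matrix, e2$matrix)
  expect_identical(e1$truth$de_status, e2$truth$de_status)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1$annotation, g2$annotation)
  expect_identical(g1$truth$true_pairs, g2$truth$true_pairs)
  q1 <- simulate_qpcr(e1$truth, n_replicates = 3, noise_sd = 0.2, seed = 5)
  q2 <- simulate_qpcr(e1$truth, n_replicates = 3, noise_sd = 0.2, seed = 5)
  expect_identical(q1, q2)
})

test_that("zero noise forces the exact planted linear fold change", {
  cfg <- sim_config(n_coding = 5, n_lncrna = 5, planted_de_fraction = 0,
                    planted_log2fc = 2, noise_sd = 0, seed = 2)
  truth <- structure(list(
    de_status = c(NM_A00001 = "up"),
    log2fc = c(NM_A00001 = 2),
    biotype = stats::setNames(rep(c("coding", "lncRNA"), each = 5),
                              c(sprintf("NM_A%05d", 1:5), sprintf("NR_A%05d", 1:5))),
    true_category = stats::setNames(character(), character()),
    true_pairs = NULL), class = "ground_truth")
  e <- simulate_expression(cfg, truth = truth)
  g <- e$groups
  ratio <- mean(e$matrix["NM_A00001", g == "treatment"]) /
    mean(e$matrix["NM_A00001", g == "control"])
  expect_identical(ratio, 4)
  null_id <- "NM_A00002"
  expect_identical(mean(e$matrix[null_id, g == "treatment"]) /
                     mean(e$matrix[null_id, g == "control"]), 1)
  expect_true(all(e$matrix > 0))
})

test_that("planted_de_fraction = 0 leaves every transcript null", {
  cfg <- sim_config(n_coding = 30, n_lncrna = 30, planted_de_fraction = 0, seed = 3)
  e <- simulate_expression(cfg)
  expect_true(all(e$truth$de_status == "null"))
  expect_equal(dim(e$matrix), c(60L, 8L))
})

test_that("all-zero category counts give a coding-only annotation", {
  cfg <- sim_config(n_coding = 10, n_lncrna = 10, n_linc_pairs = 0,
                    category_counts = stats::setNames(rep(0L, 6), LNC_CATEGORIES),
                    seed = 5)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$annotation$transcripts), 10)
  expect_true(all(g$annotation$transcripts$biotype == "coding"))
})

test_that("intergenic plants sit over 300 kb from every coding gene (brute scan)", {
  cfg <- sim_config(n_coding = 20, n_lncrna = 20, n_linc_pairs = 0,
                    category_counts = c(intergenic = 5L), seed = 6)
  g <- simulate_genome(cfg)
  tx <- g$annotation$transcripts
  lnc <- tx[tx$biotype == "lncRNA", ]
  cod <- tx[tx$biotype == "coding", ]
  for (i in seq_len(nrow(lnc))) {
    same <- cod[cod$chrom == lnc$chrom[i], ]
    if (nrow(same) == 0) next
    gaps <- pmax(same$start - lnc$end[i], lnc$start[i] - same$end)
    expect_true(all(gaps > 300000))
  }
})

test_that("placement fails loudly when the toy genome is too small", {
  expect_error(sim_config(n_coding = 50, n_lncrna = 60, n_linc_pairs = 10,
                          chrom_sizes = c(chr1 = 5e6)) |> simulate_genome(),
               "placement error")
})

test_that("the Ct model encodes abundance as -log2 with the reference in every sample", {
  truth <- structure(list(de_status = c(gA = "up", gB = "null"),
                          log2fc = c(gA = 2, gB = 0)),
                     class = "ground_truth")
  ct <- simulate_qpcr(truth, genes = c("gA", "gB"), n_replicates = 4,
                      noise_sd = 0, seed = 8)
  expect_true(all(table(ct$sample_id[ct$gene_id == "Gapdh"]) == 1))
  r <- ddct(ct, "gA")
  expect_equal(r$fold_vs_control, 4, tolerance = 1e-12)   # ddCt = -2 exactly
  expect_equal(ddct(ct, "gB")$fold_vs_control, 1, tolerance = 1e-12)
  expect_error(simulate_qpcr(truth, reference_gene = ""), "configuration error")
})

test_that("planted pair directions honor the exact concordant count", {
  cfg <- sim_config(n_coding = 40, n_lncrna = 40, n_linc_pairs = 30,
                    concordant_fraction = 0.7,
                    category_counts = stats::setNames(rep(0L, 6), LNC_CATEGORIES),
                    seed = 10)
  g <- simulate_genome(cfg)
  tp <- g$truth$true_pairs
  expect_equal(nrow(tp), 30)
  expect_equal(sum(tp$concordant), round(0.7 * 30))
  expect_true(all(tp$lncrna_id %in% g$annotation$transcripts$transcript_id))
  expect_true(all(tp$mrna_id %in% g$annotation$transcripts$transcript_id))
})
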