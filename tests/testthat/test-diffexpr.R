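make_groups <- function(n) {
  stats::setNames(rep(c("treatment", "control"), each = n),
                  c(paste0("T", 1:n), paste0("C", 1:n)))
}

test_that("fold change is the >= 1 group-mean ratio with an up/down label", {
  g <- make_groups(2)
  m <- rbind(a = c(8, 8, 2, 2), b = c(2, 2, 8, 8), c = c(5, 5, 5, 5))
  colnames(m) <- names(g)
  expect_equal(fold_change(m, g, "a"), list(fold_change = 4, regulation = "up"))
  expect_equal(fold_change(m, g, "b"), list(fold_change = 4, regulation = "down"))
  # equal means tie-break to up
  expect_equal(fold_change(m, g, "c"), list(fold_change = 1, regulation = "up"))
})

test_that("bh_fdr reproduces hand-applied step-up values and the BH oracle", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.001, 1.0)), c(0.002, 1.0))
  set.seed(3)
  for (rep in 1:5) {
    p <- runif(20)
    expect_equal(bh_fdr(p), bh_hand(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("row-wise Welch p-values agree with stats::t.test", {
  set.seed(5)
  g <- make_groups(4)
  m <- matrix(2^rnorm(20 * 8, 8, 0.5), nrow = 20, dimnames = list(NULL, names(g)))
  de <- de_test(m, g)
  for (i in c(1, 7, 20)) {
    ref <- t.test(log2(m[i, g == "treatment"]), log2(m[i, g == "control"]))
    expect_equal(de$p_value[i], unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("planted fold-change-4 transcripts pass the primary filter with correct direction", {
  set.seed(9)
  cfg <- sim_config(n_coding = 300, n_lncrna = 300, planted_de_fraction = 0.05,
                    planted_log2fc = 2, noise_sd = 0.1, seed = 9)
  e <- simulate_expression(cfg)
  de <- de_test(quantile_normalize(e$matrix), e$groups, biotype = e$biotype)
  planted <- names(e$truth$de_status)[e$truth$de_status != "null"]
  got <- de[match(planted, de$transcript_id), ]
  # normalization can pin planted effects sitting at the extreme low-
  # intensity tail to the shared rank-means, so demand high but not
  # perfect recovery, with the direction always correct among passes
  expect_gte(mean(got$passes_primary), 0.9)
  pass <- got$passes_primary
  expect_equal(got$regulation[pass], unname(e$truth$de_status[planted])[pass])
})

test_that("an all-null matrix with tiny noise yields essentially no primary passes", {
  set.seed(13)
  cfg <- sim_config(n_coding = 300, n_lncrna = 300, planted_de_fraction = 0,
                    noise_sd = 0.05, seed = 13)
  e <- simulate_expression(cfg)
  de <- de_test(quantile_normalize(e$matrix), e$groups, biotype = e$biotype)
  expect_lt(mean(de$passes_primary), 0.01)
})

test_that("sensitivity passes are nested in primary passes when fdr >= p", {
  set.seed(17)
  cfg <- sim_config(n_coding = 200, n_lncrna = 200, planted_de_fraction = 0.1,
                    noise_sd = 0.3, seed = 17)
  e <- simulate_expression(cfg)
  de <- de_test(quantile_normalize(e$matrix), e$groups, biotype = e$biotype)
  nested <- de$fdr >= de$p_value
  expect_true(all(!de$passes_sensitivity[nested] | de$passes_primary[nested]))
})

test_that("biotype families are corrected separately by default", {
  set.seed(21)
  g <- make_groups(3)
  m <- matrix(2^rnorm(40 * 6, 8, 0.4), nrow = 40, dimnames = list(
    sprintf("t%02d", 1:40), names(g)))
  bt <- stats::setNames(rep(c("coding", "lncRNA"), each = 20), rownames(m))
  de_split <- de_test(m, g, biotype = bt, fdr_family = "biotype")
  de_joint <- de_test(m, g, biotype = bt, fdr_family = "joint")
  cod <- de_split$biotype == "coding"
  expect_equal(de_split$fdr[cod], bh_fdr(de_split$p_value[cod]))
  expect_equal(de_joint$fdr, bh_fdr(de_joint$p_value))
})

test_that("groups of fewer than two samples are a statistics error", {
  g <- stats::setNames(c("treatment", "control", "control"), c("T1", "C1", "C2"))
  m <- matrix(2^rnorm(9, 8, 1), nrow = 3, dimnames = list(NULL, names(g)))
  expect_error(de_test(m, g), "statistics error")
})
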