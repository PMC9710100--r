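# one coding transcript spanning [100, 500) with exons [100,200) and
# [400,500), used by several cases below
coding_rows <- function() list(list("cod1", "chr1", "+", 100, 500, "coding"))
coding_exons <- function() list(list("cod1", 100, 200), list("cod1", 400, 500))

test_that("each of the six categories is recovered from its defining geometry", {
  cases <- list(
    # same strand, exon-exon overlap of 50 bp
    list(lnc = list("l1", "chr1", "+", 150, 250), exons = list(list("l1", 150, 250)),
         category = "sense_overlapping", evidence = 50),
    # same strand, single exon inside the intron [200, 400)
    list(lnc = list("l2", "chr1", "+", 300, 350), exons = list(list("l2", 300, 350)),
         category = "intronic", evidence = 50),
    # opposite strand, exon-exon overlap
    list(lnc = list("l3", "chr1", "-", 150, 250), exons = list(list("l3", 150, 250)),
         category = "natural_antisense", evidence = 50),
    # opposite strand, body overlap but no exon overlap
    list(lnc = list("l4", "chr1", "-", 250, 350), exons = list(list("l4", 250, 350)),
         category = "nonoverlapping_antisense", evidence = 100),
    # far away on the other strand, no divergent partner
    list(lnc = list("l6", "chr1", "-", 5000, 5400), exons = list(list("l6", 5000, 5400)),
         category = "intergenic", evidence = NA_real_)
  )
  for (cs in cases) {
    ts <- toy_annotation(c(coding_rows(), list(c(cs$lnc, "lncRNA"))),
                         c(coding_exons(), cs$exons))
    got <- classify_lncrna(cs$lnc[[1]], ts)
    expect_equal(got$category, cs$category, label = cs$lnc[[1]])
    expect_equal(got$evidence_bp, cs$evidence, label = cs$lnc[[1]])
    # the brute-force rule checker agrees
    expect_equal(brute_classify_all(ts)$category, cs$category)
  }
})

test_that("head-to-head lncRNA within 1000 bp is bidirectional with the 5' gap as evidence", {
  ts <- toy_annotation(
    list(list("lb", "chr1", "-", 1500, 2000, "lncRNA"),
         list("codb", "chr1", "+", 2400, 3000, "coding")),
    list(list("lb", 1500, 2000), list("codb", 2400, 3000))
  )
  got <- classify_lncrna("lb", ts)
  expect_equal(got$category, "bidirectional")
  expect_equal(got$evidence_bp, 400)
  expect_equal(got$partner_id, "codb")
  # convergent (tail-to-tail) neighbors are NOT bidirectional
  ts2 <- toy_annotation(
    list(list("lb", "chr1", "+", 1500, 2000, "lncRNA"),
         list("codb", "chr1", "-", 2400, 3000, "coding")),
    list(list("lb", 1500, 2000), list("codb", 2400, 3000))
  )
  expect_equal(classify_lncrna("lb", ts2)$category, "intergenic")
})

test_that("classification agrees with the brute-force oracle on random toy genomes", {
  for (seed in 1:20) {
    ts <- random_toy_genome(n_coding = 10, n_lnc = 10, seed = seed)
    got <- classify_all(ts)
    ref <- brute_classify_all(ts)
    expect_identical(got$category, ref$category, label = paste("seed", seed))
    expect_identical(got$partner_id, ref$partner_id, label = paste("seed", seed))
    expect_equal(got$evidence_bp, ref$evidence_bp, label = paste("seed", seed))
  }
})

test_that("flipping every strand preserves all overlap-based category assignments", {
  # sense/antisense relations depend only on relative strand and so survive
  # a global strand flip; head-to-head (bidirectional) is orientation-
  # sensitive by definition (a flip turns divergent into convergent), so
  # only assignments not involving the promoter-geometry rule must agree
  for (seed in c(2, 5, 8)) {
    ts <- random_toy_genome(seed = seed)
    flipped <- ts
    flipped$transcripts$strand <- ifelse(ts$transcripts$strand == "+", "-", "+")
    a <- classify_all(ts)$category
    b <- classify_all(flipped)$category
    keep <- a != "bidirectional" & b != "bidirectional" &
      !(a == "intergenic" | b == "intergenic")
    expect_identical(a[keep], b[keep])
    overlap_cats <- c("sense_overlapping", "intronic", "natural_antisense",
                      "nonoverlapping_antisense")
    expect_identical(a %in% overlap_cats, b %in% overlap_cats)
  }
})

test_that("same-strand exon overlap always outranks antisense and bidirectional", {
  for (seed in 1:10) {
    ts <- random_toy_genome(seed = seed)
    got <- classify_all(ts)
    for (i in seq_len(nrow(got))) {
      lid <- got$lncrna_id[i]
      l <- ts$transcripts[ts$transcripts$transcript_id == lid, ]
      lex <- ts$exons[ts$exons$transcript_id == lid, ]
      lpos <- brute_positions(lex)
      coding <- ts$transcripts[ts$transcripts$biotype == "coding" &
                                 ts$transcripts$strand == l$strand, ]
      has_sense_ov <- any(vapply(coding$transcript_id, function(cid) {
        length(intersect(lpos, brute_positions(
          ts$exons[ts$exons$transcript_id == cid, ]))) > 0
      }, TRUE))
      if (has_sense_ov) {
        expect_false(got$category[i] %in%
                       c("natural_antisense", "nonoverlapping_antisense",
                         "bidirectional"))
      }
    }
  }
})

test_that("planted categories are recovered exactly from the generator", {
  cfg <- sim_config(n_coding = 30, n_lncrna = 40, n_linc_pairs = 5,
                    category_counts = stats::setNames(rep(2L, 6), LNC_CATEGORIES),
                    seed = 4)
  g <- simulate_genome(cfg)
  got <- classify_all(g$annotation)
  truth <- g$truth$true_category
  expect_equal(stats::setNames(got$category[match(names(truth), got$lncrna_id)],
                               names(truth)), truth)
})

test_that("classifying a coding transcript is a usage error", {
  ts <- toy_annotation(coding_rows(), coding_exons())
  expect_error(classify_lncrna("cod1", ts), "usage error")
  expect_equal(nrow(classify_all(ts)), 0)
})
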