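test_that("antisense pairs require both members to pass the primary filter", {
  classes <- data.frame(lncrna_id = c("l1", "l2", "l3"),
                        category = c("natural_antisense", "natural_antisense",
                                     "nonoverlapping_antisense"),
                        partner_id = c("m1", "m2", "m3"),
                        evidence_bp = c(50, 60, 70), stringsAsFactors = FALSE)
  de <- toy_de(c("l1", "l2", "l3", "m1", "m2", "m3"),
               fc = c(6, 5, 4, 2.04, 1.5, 3),
               reg = c("down", "up", "up", "down", "up", "up"))
  pairs <- antisense_pairs(classes, de)
  # m2 fails the fold-change filter, so l2 yields no pair
  expect_equal(sort(pairs$lncrna_id), c("l1", "l3"))
  expect_equal(pairs$distance, c(0, 0))
  p1 <- pairs[pairs$lncrna_id == "l1", ]
  expect_true(p1$concordant)       # down/down, the published pattern
  expect_equal(p1$relationship, "natural_antisense")
})

test_that("a partner without a DE record is skipped with a warning", {
  classes <- data.frame(lncrna_id = "l1", category = "natural_antisense",
                        partner_id = "missing", evidence_bp = 10,
                        stringsAsFactors = FALSE)
  de <- toy_de("l1", fc = 4, reg = "up")
  expect_warning(pairs <- antisense_pairs(classes, de), "no DE record")
  expect_equal(nrow(pairs), 0)
})

test_that("antisense lncRNA inside one intron of its partner is labelled intronic_antisense", {
  ts <- toy_annotation(
    list(list("cod1", "chr1", "+", 100, 500, "coding"),
         list("l1", "chr1", "-", 250, 350, "lncRNA")),
    list(list("cod1", 100, 200), list("cod1", 400, 500), list("l1", 250, 350))
  )
  classes <- classify_all(ts)
  de <- toy_de(c("l1", "cod1"), fc = c(4, 3), reg = c("down", "down"))
  pairs <- antisense_pairs(classes, de, annotation = ts)
  expect_equal(pairs$relationship, "intronic_antisense")
})

neighbor_fixture <- function(gaps, lnc_strand = "+", lnc_start = 1e6) {
  # lincRNA of 2 kb with coding genes placed at the given boundary gaps
  # (negative = left of the lincRNA, positive = right)
  lnc_end <- lnc_start + 2000
  tx <- list(list("linc", "chr1", lnc_strand, lnc_start, lnc_end, "lncRNA"))
  ex <- list(list("linc", lnc_start, lnc_end))
  for (i in seq_along(gaps)) {
    id <- sprintf("cod%d", i)
    if (gaps[i] < 0) { s <- lnc_start + gaps[i] - 9000; e <- lnc_start + gaps[i] }
    else { s <- lnc_end + gaps[i]; e <- lnc_end + gaps[i] + 9000 }
    tx <- c(tx, list(list(id, "chr1", "+", s, e, "coding")))
    ex <- c(ex, list(list(id, s, e)))
  }
  toy_annotation(tx, ex)
}

test_that("one DE coding gene 50 kb away yields one pair at that distance", {
  ts <- neighbor_fixture(gaps = 50000)
  classes <- classify_all(ts)
  de <- toy_de(c("linc", "cod1"), fc = c(4, 3), reg = c("down", "up"))
  pairs <- lincrna_neighbors(ts, classes, de)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$distance, 50000)
  expect_equal(pairs$relationship, "downstream")  # + strand lincRNA, right side
  expect_false(pairs$concordant)
})

test_that("nearest DE neighbors on both sides each yield a pair", {
  ts <- neighbor_fixture(gaps = c(-100000, 200000, -250000))
  classes <- classify_all(ts)
  de <- toy_de(c("linc", "cod1", "cod2", "cod3"), fc = c(4, 3, 3, 3),
               reg = c("down", "down", "down", "down"))
  pairs <- lincrna_neighbors(ts, classes, de)
  expect_equal(nrow(pairs), 2)
  # nearest on the left is cod1 (100 kb), not cod3 (250 kb)
  expect_setequal(pairs$mrna_id, c("cod1", "cod2"))
  expect_equal(sort(pairs$distance), c(100000, 200000))
  expect_setequal(pairs$relationship, c("upstream", "downstream"))
})

test_that("neighbors at or beyond the window yield no pair; enlarging the window never removes one", {
  ts <- neighbor_fixture(gaps = 350000)
  classes <- classify_all(ts)
  de <- toy_de(c("linc", "cod1"), fc = c(4, 3), reg = c("down", "up"))
  expect_equal(nrow(lincrna_neighbors(ts, classes, de)), 0)
  wide <- lincrna_neighbors(ts, classes, de, window = 500000)
  expect_equal(nrow(wide), 1)
  # monotonicity on a multi-gene fixture
  ts2 <- neighbor_fixture(gaps = c(-40000, 120000))
  classes2 <- classify_all(ts2)
  de2 <- toy_de(c("linc", "cod1", "cod2"), fc = c(4, 3, 3),
                reg = c("up", "up", "down"))
  narrow <- lincrna_neighbors(ts2, classes2, de2, window = 150000)
  wide2 <- lincrna_neighbors(ts2, classes2, de2, window = 400000)
  expect_true(all(paste(narrow$lncrna_id, narrow$mrna_id) %in%
                    paste(wide2$lncrna_id, wide2$mrna_id)))
})

test_that("strand-relative upstream/downstream labels flip with the lincRNA strand", {
  for (s in c("+", "-")) {
    ts <- neighbor_fixture(gaps = -50000, lnc_strand = s)
    classes <- classify_all(ts)
    de <- toy_de(c("linc", "cod1"), fc = c(4, 3), reg = c("up", "up"))
    pairs <- lincrna_neighbors(ts, classes, de)
    expect_equal(pairs$relationship, if (s == "+") "upstream" else "downstream")
  }
})

test_that("concordance summary computes the four direction fractions exactly", {
  pairs <- toy_pairs <- data.frame(
    lncrna_id = c("a", "b"), mrna_id = c("x", "y"),
    relationship = "downstream", distance = c(1, 2),
    lnc_regulation = c("down", "down"), mrna_regulation = c("down", "up"),
    concordant = c(TRUE, FALSE), stringsAsFactors = FALSE)
  s <- concordance_summary(pairs)
  expect_equal(s$frac_down_down, 0.5)
  expect_equal(s$frac_down_up, 0.5)
  expect_equal(s$frac_concordant, 0.5)
  all_up <- transform(pairs, lnc_regulation = "up", mrna_regulation = "up")
  expect_equal(concordance_summary(all_up)$frac_concordant, 1)
  expect_error(concordance_summary(pairs[0, ]), "empty-input error")
})

test_that("the four fractions close to 1 and concordant = up_up + down_down", {
  set.seed(31)
  regs <- expand.grid(l = c("up", "down"), m = c("up", "down"),
                      stringsAsFactors = FALSE)
  idx <- sample(1:4, 37, replace = TRUE)
  pairs <- data.frame(lncrna_id = sprintf("l%02d", 1:37),
                      mrna_id = sprintf("m%02d", 1:37),
                      relationship = "upstream", distance = 0,
                      lnc_regulation = regs$l[idx], mrna_regulation = regs$m[idx],
                      concordant = regs$l[idx] == regs$m[idx],
                      stringsAsFactors = FALSE)
  s <- concordance_summary(pairs)
  expect_identical(s$frac_up_up + s$frac_down_down + s$frac_up_down + s$frac_down_up, 1)
  expect_identical(s$frac_concordant, s$frac_up_up + s$frac_down_down)
})

test_that("planted pair relationships and concordance survive the full round trip", {
  # planted pairs embedded in a mostly-null background so normalization
  # leaves the planted fold changes essentially intact
  cfg <- sim_config(n_coding = 250, n_lncrna = 800, n_linc_pairs = 30,
                    concordant_fraction = 0.7, noise_sd = 0.2,
                    planted_de_fraction = 0,
                    category_counts = stats::setNames(rep(0L, 6), LNC_CATEGORIES),
                    seed = 12)
  s <- simulate_study(cfg)
  de <- de_test(quantile_normalize(s$matrix), s$groups, biotype = s$biotype)
  classes <- classify_all(s$annotation)
  pairs <- lincrna_neighbors(s$annotation, classes, de)
  tp <- s$truth$true_pairs
  # a planted pair drops out only if one member sits at the intensity tail
  # where normalization pins it below the filters; recovery stays >= 90%
  expect_gte(nrow(pairs), 0.9 * nrow(tp))
  key <- paste(pairs$lncrna_id, pairs$mrna_id)
  expect_true(all(key %in% paste(tp$lncrna_id, tp$mrna_id)))
  ix <- match(key, paste(tp$lncrna_id, tp$mrna_id))
  expect_equal(pairs$relationship, tp$relationship[ix])
  expect_equal(pairs$concordant, tp$concordant[ix])
})
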