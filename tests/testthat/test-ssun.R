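test_that("window counting matches exhaustive per-read enumeration", {
  # 7 hand-placed reads against window [101,140] (0-based [100,140))
  reads <- makeReads(list(
    rbind(c(90, 105)),                  # 5 nt overlap -> in
    rbind(c(140, 160)),                 # 1 nt overlap -> in
    rbind(c(141, 160)),                 # adjacent, 0 overlap -> out
    rbind(c(80, 100), c(141, 200)),     # gap spans the window -> out
    rbind(c(95, 110), c(130, 150)),     # two overlapping blocks -> once
    rbind(c(10, 50)),                   # far away -> out
    rbind(c(101, 140))))                # contained -> in
  win <- GRanges("chrT", IRanges(101, 140))
  expect_equal(countWindowReads(reads, win), 4L)
  expect_equal(countWindowReads(reads, win),
               bruteWindowCount(reads, "chrT", 101L, 140L))
  # stricter overlap rule drops the 1-nt read
  expect_equal(countWindowReads(reads, win, minOverlap = 5L), 3L)
  expect_equal(countWindowReads(reads, win, minOverlap = 5L),
               bruteWindowCount(reads, "chrT", 101L, 140L, minOverlap = 5L))
  # no reads -> 0
  expect_equal(countWindowReads(AlignedReadSet(readBlocks(reads)[0]), win), 0L)
})

test_that("a spliced read whose gap covers the window contributes nothing", {
  reads <- makeReads(list(rbind(c(150, 200), c(301, 350))))
  expect_equal(countWindowReads(reads, GRanges("chrT", IRanges(201, 300))), 0L)
})

test_that("SSun is intronic over exonic with threshold-gated evaluability", {
  win <- boundaryWindows(toyGene("+"), w = 40)
  # 12 exonic reads in [161,200] and 0 intronic -> perfect splicing, ssun 0
  ex_reads <- lapply(1:12, function(i) rbind(c(161, 200)))
  rec <- computeSSun(makeReads(ex_reads), win)
  r5 <- as.data.frame(rec[rec$site_kind == "five_prime", ])
  expect_equal(r5$exonic_count, 12L)
  expect_equal(r5$intronic_count, 0L)
  expect_equal(r5$ssun, 0)
  expect_true(r5$evaluable)
  # three prime exonic window had no reads -> undefined ratio, flagged
  r3 <- as.data.frame(rec[rec$site_kind == "three_prime", ])
  expect_false(r3$evaluable)
  expect_true(is.na(r3$ssun))

  # 3 exonic + 2 intronic hand-placed reads, threshold relaxed -> 2/3,
  # cross-checked against the brute-force window counter
  mix <- makeReads(c(lapply(1:3, function(i) rbind(c(161, 200))),
                     lapply(1:2, function(i) rbind(c(205, 240)))))
  rec2 <- computeSSun(mix, win, minExonicReads = 1L)
  v <- as.data.frame(rec2[rec2$site_kind == "five_prime", ])
  expect_equal(v$ssun, 2 / 3)
  expect_equal(v$exonic_count,
               bruteWindowCount(mix, "chrT", 161L, 200L))
  expect_equal(v$intronic_count,
               bruteWindowCount(mix, "chrT", 201L, 240L))
})

test_that("orientation switch exposes the literal inverse ratio", {
  win <- boundaryWindows(toyGene("+"), w = 40)
  mix <- makeReads(c(lapply(1:4, function(i) rbind(c(161, 200))),
                     lapply(1:2, function(i) rbind(c(205, 240)))))
  a <- computeSSun(mix, win, minExonicReads = 1L)
  b <- computeSSun(mix, win, minExonicReads = 1L,
                   orientation = "exonic_over_intronic")
  i5 <- which(a$site_kind == "five_prime")
  expect_equal(a$ssun[i5], 0.5)
  expect_equal(b$ssun[i5], 2)
})

test_that("boundary-crossing unspliced reads count in both windows", {
  win <- boundaryWindows(toyGene("+"), w = 40)
  cross <- makeReads(list(rbind(c(181, 220))))  # 20 nt each side
  rec <- computeSSun(cross, win, minExonicReads = 1L)
  v <- as.data.frame(rec[rec$site_kind == "five_prime", ])
  expect_equal(v$exonic_count, 1L)
  expect_equal(v$intronic_count, 1L)
})

test_that("group comparison reduces to the textbook pooled-variance t-test", {
  # identical groups: degenerate but defined
  expect_equal(pooledTTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(pooledTTest(c(0.2, 0.2), c(0.2, 0.2))$t, 0)
  # hand-evaluated pooled formula as the oracle
  x <- c(0.10, 0.12, 0.11); y <- c(0.50, 0.55, 0.45)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  p_hand <- 2 * pt(-abs(t_hand), 4)
  tt <- pooledTTest(x, y)
  expect_equal(tt$t, t_hand)
  expect_equal(tt$p, p_hand)
  # and against stats::t.test with pooled variance
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$p, ref$p.value)
})

test_that("compareSSun flags sites only when every contrast passes", {
  win <- boundaryWindows(toyGene("+"), w = 40)
  cfg <- spliceSimConfig(seed = 21, depth = 2000L,
                         retention = data.frame(
                           genotype = c("mut", "wt", "het", "rescue"),
                           gene_id = "toy", r = c(0.5, 0.02, 0.02, 0.02)))
  sim <- simulateReads(cfg, GeneModelList(toyGene()))
  rec <- computeSSun(sim$reads, win)
  cmp <- compareSSun(rec, sim$design, mutant = "mut")
  df <- as.data.frame(cmp)
  expect_equal(nrow(df), 6L)  # 2 sites x 3 contrasts
  expect_true(all(df$tested))
  expect_true(all(df$p < 0.05))
  expect_true(all(df$site_significant))
  expect_true(all(df$mean_mut > df$mean_comp))
  # q is the BH adjustment within each contrast
  for (ct in unique(df$contrast)) {
    k <- df$contrast == ct
    expect_equal(df$q[k], p.adjust(df$p[k], method = "BH"))
  }
})

test_that("sites without enough evaluable replicates are reported untested", {
  rec <- DataFrame(gene_id = "g", intron_index = 1L, intron_class = "minor",
                   site_kind = rep("five_prime", 6L),
                   sample = sprintf("s%d", 1:6),
                   exonic_count = c(50L, 3L, 4L, 60L, 55L, 58L),
                   intronic_count = 0L,
                   ssun = c(0.1, NA, NA, 0.0, 0.01, 0.0),
                   evaluable = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
                   truncated = FALSE)
  design <- data.frame(sample = sprintf("s%d", 1:6),
                       genotype = rep(c("mut", "wt"), each = 3L))
  cmp <- compareSSun(rec, design, mutant = "mut")
  expect_false(cmp$tested[1])
  expect_match(cmp$reason[1], "evaluable")
  expect_false(cmp$site_significant[1])
})
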