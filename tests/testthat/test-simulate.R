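cfg2 <- function(seed = 1, r = 0.5, depth = 1000L, ...) {
  spliceSimConfig(seed = seed, depth = depth,
                  genotypes = data.frame(genotype = "g", replicates = 2L),
                  mutant = "g",
                  retention = data.frame(genotype = "g", gene_id = "toy",
                                         r = r), ...)
}

test_that("configuration contract rejects invalid fractions and designs", {
  expect_error(cfg2(r = 1.2), "fractions")
  expect_error(spliceSimConfig(dispersion = -1), "dispersion")
  expect_error(spliceSimConfig(
    genotypes = data.frame(genotype = "g", replicates = 1L), mutant = "g"),
    "replicates")
  expect_error(spliceSimConfig(mutant = "nope"), "mutant")
})

test_that("simulation is deterministic under a fixed seed", {
  m <- GeneModelList(toyGene())
  a <- simulateReads(cfg2(seed = 42), m)
  b <- simulateReads(cfg2(seed = 42), m)
  expect_identical(as.data.frame(readBlocks(a$reads)),
                   as.data.frame(readBlocks(b$reads)))
  expect_identical(a$truth, b$truth)
  c <- simulateReads(cfg2(seed = 43), m)
  expect_false(identical(as.data.frame(readBlocks(a$reads)),
                         as.data.frame(readBlocks(c$reads))))
})

test_that("full retention leaves no junction-spanning reads", {
  m <- GeneModelList(toyGene())
  sim <- simulateReads(cfg2(r = 1), m)
  b <- readBlocks(sim$reads)
  expect_true(all(table(mcols(b)$read_id) == 1L))  # no gaps at all
  expect_equal(countJunctionReads(sim$reads,
                                  junctionDef("chrT", 201, 300)), 0L)
  expect_true(all(sim$truth$jr_normal == 0L))
})

test_that("zero depth gives an empty stream and all-zero ground truth", {
  sim <- simulateReads(cfg2(depth = 0L), GeneModelList(toyGene()))
  expect_equal(length(sim$reads), 0L)
  expect_true(all(sim$truth[, c("n_spliced", "n_cryptic", "n_retained")] == 0L))
})

test_that("template counts conserve depth", {
  m <- GeneModelList(toyGene())
  sim <- simulateReads(cfg2(r = 0.3, depth = 500L), m)
  expect_true(all(rowSums(sim$truth[, c("n_spliced", "n_cryptic",
                                        "n_retained")]) == 500L))
})

test_that("reads land in the intronic window at the closed-form rate", {
  # toy gene, r = 0.5, L = 100: the retained template spans [101,400]
  # (300 nt), starts 0..200; a start s overlaps window [201,240] iff
  # 1 <= s <= 139, so E[count | n_retained] = n_retained * 139/201
  m <- GeneModelList(toyGene())
  sim <- simulateReads(cfg2(seed = 5, r = 0.5, depth = 10000L), m)
  s1 <- subsetBySample(sim$reads, "g_rep1")
  win <- GRanges("chrT", IRanges(201, 240))
  obs <- countWindowReads(s1, win)
  nret <- sim$truth$n_retained[sim$truth$sample == "g_rep1"]
  p <- 139 / 201
  expect_lt(abs(obs - nret * p), 3 * sqrt(nret * p * (1 - p)))
})

test_that("readLength must stay below every template", {
  m <- GeneModelList(toyGene())
  expect_error(simulateReads(cfg2(readLength = 200L), m), "readLength")
})

test_that("SAM output parses and agrees block-for-block with BED12", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  m <- GeneModelList(toyGene())
  sim <- simulateReads(cfg2(seed = 9, depth = 200L), m)
  sam <- tempfile(fileext = ".sam")
  bed <- tempfile(fileext = ".bed")
  writeSam(sim$reads, sam)
  writeReadsBed12(sim$reads, bed)
  from_sam <- readAlignments(sam)
  from_bed <- readAlignments(bed)
  canon <- function(x) {
    b <- readBlocks(x)
    df <- data.frame(read = mcols(b)$read_id,
                     start = start(b), end = end(b))
    df[order(df$read, df$start), ]
  }
  a <- canon(from_sam); b <- canon(from_bed)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_equal(sort(unique(a$read)),
               sort(unique(mcols(readBlocks(sim$reads))$read_id)))
})

test_that("count-table simulation is deterministic and shaped by the design", {
  cfg <- spliceSimConfig(seed = 2, enrichment = c(U11_like = 16))
  a <- simulateCountTable(cfg, "rip", nFeatures = 20L)
  b <- simulateCountTable(cfg, "rip", nFeatures = 20L)
  expect_identical(a$counts, b$counts)
  expect_equal(dim(a$counts), c(21L, 6L))  # planted feature prepended
  expect_equal(a$design$arm, rep(c("IP", "control"), each = 3L))
  expect_equal(a$truth$enrichment[a$truth$feature == "U11_like"], 16)

  r <- simulateCountTable(cfg, "rnaseq", nFeatures = 10L,
                          planted = data.frame(feature = "feature001",
                                               log2fc = 1))
  expect_equal(ncol(r$counts), 12L)
  expect_equal(sum(r$truth$log2fc != 0), 1L)
})

test_that("noise-free abundance tables reproduce planted fold-changes exactly", {
  cfg <- spliceSimConfig(seed = 4, sigmaLog = 0, libFactorRange = c(1, 1))
  ab <- simulateAbundanceTable(cfg, nFeatures = 5L,
                               planted = data.frame(feature = "protein002",
                                                    fc = 0.5))
  mut <- ab$design$sample[ab$design$genotype == "mut"][1]
  wt <- ab$design$sample[ab$design$genotype == "wt"][1]
  expect_equal(ab$abundance["protein002", mut] /
                 ab$abundance["protein002", wt], 0.5)
  expect_equal(ab$abundance["protein001", mut] /
                 ab$abundance["protein001", wt], 1)
  expect_error(simulateAbundanceTable(cfg, nFeatures = 0L), "nFeatures")
})
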