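test_that("GeneModel validity rejects malformed exon chains", {
  expect_error(geneModel("g", "t", "chr1", "+", c(100, 50), c(120, 80)),
               "sorted")
  expect_error(geneModel("g", "t", "chr1", "+", c(100, 110), c(120, 130)),
               "non-overlapping")
  # zero-length gap (adjacent exons) leaves no room for an intron
  expect_error(geneModel("g", "t", "chr1", "+", c(100, 121), c(120, 140)),
               "separated")
  expect_error(geneModel("g", "t", "chr1", "*", 100, 120), "strand")
})

test_that("introns are the inter-exon gaps, indexed in transcription order", {
  # 3-exon toy transcript; expected gaps enumerated by hand from the bounds
  gm <- geneModel("g", "t", "chr1", "+", c(101, 301, 601), c(200, 400, 700),
                  intronClass = c("minor", "major"))
  ir <- introns(gm)
  expect_equal(start(ir), c(201L, 401L))
  expect_equal(end(ir), c(300L, 600L))
  expect_equal(mcols(ir)$intron_index, c(1L, 2L))
  expect_equal(mcols(ir)$intron_class, c("minor", "major"))

  # same exon chain on '-' strand: genomic-last intron is the 5'-most one
  gmm <- geneModel("g", "t", "chr1", "-", c(101, 301, 601), c(200, 400, 700))
  irm <- introns(gmm)
  expect_equal(mcols(irm)$intron_index, c(2L, 1L))

  # single exon -> no introns
  expect_length(introns(geneModel("g", "t", "chr1", "+", 100, 200)), 0L)
})

test_that("splice-site kinds follow transcript orientation", {
  ss <- spliceSites(toyGene("+"))
  d <- ss[mcols(ss)$site_kind == "five_prime"]
  a <- ss[mcols(ss)$site_kind == "three_prime"]
  expect_equal(start(d), 201L)  # first intronic base
  expect_equal(start(a), 300L)
  # minus strand: the donor sits at the high-coordinate end of the intron
  ssm <- spliceSites(toyGene("-"))
  expect_equal(start(ssm[mcols(ssm)$site_kind == "five_prime"]), 300L)
  expect_equal(start(ssm[mcols(ssm)$site_kind == "three_prime"]), 201L)
})

test_that("boundary windows match the definitional plus-strand layout", {
  # intron [201,300] 1-based closed == [200,300) 0-based; w = 40
  win <- boundaryWindows(toyGene("+"), w = 40)
  getw <- function(sk, wk) {
    g <- win[mcols(win)$site_kind == sk & mcols(win)$window_kind == wk]
    c(start(g), end(g))
  }
  expect_equal(getw("five_prime", "exonic"), c(161L, 200L))
  expect_equal(getw("five_prime", "intronic"), c(201L, 240L))
  expect_equal(getw("three_prime", "intronic"), c(261L, 300L))
  expect_equal(getw("three_prime", "exonic"), c(301L, 340L))
  expect_true(all(width(win) == 40L))
  expect_false(any(mcols(win)$truncated))
})

test_that("minus-strand windows equal the mirrored plus-strand derivation", {
  # mirror the toy gene around the contig midpoint M: pos -> M - pos + 1,
  # derive on '+', and mirror back; labels must line up with direct '-' call
  M <- 1000L
  mirror <- function(s, e) c(M - e + 1L, M - s + 1L)
  ex_m <- rbind(mirror(101L, 200L), mirror(301L, 400L))
  gm_plus <- geneModel("toy", "toy.t1", "chrT", "+",
                       sort(ex_m[, 1L]), sort(ex_m[, 2L]),
                       intronClass = "minor", seqlength = M)
  win_direct <- boundaryWindows(toyGene("-"), w = 40)
  win_mirror <- boundaryWindows(gm_plus, w = 40)
  for (sk in c("five_prime", "three_prime")) {
    for (wk in c("exonic", "intronic")) {
      d <- win_direct[mcols(win_direct)$site_kind == sk &
                        mcols(win_direct)$window_kind == wk]
      m <- win_mirror[mcols(win_mirror)$site_kind == sk &
                        mcols(win_mirror)$window_kind == wk]
      expect_equal(c(start(d), end(d)),
                   c(M - end(m) + 1L, M - start(m) + 1L),
                   info = paste(sk, wk))
    }
  }
})

test_that("short introns and exons truncate windows with a flag", {
  gm <- geneModel("g", "t", "chr1", "+", c(101, 231), c(200, 320))  # intron 30 nt
  win <- boundaryWindows(gm, w = 40)
  intr <- win[mcols(win)$window_kind == "intronic"]
  expect_true(all(width(intr) == 30L))
  expect_true(all(mcols(intr)$truncated))
  # exon of 20 nt truncates the exonic window too
  gm2 <- geneModel("g", "t", "chr1", "+", c(181, 301), c(200, 400))
  w2 <- boundaryWindows(gm2, w = 40)
  ex5 <- w2[mcols(w2)$site_kind == "five_prime" &
              mcols(w2)$window_kind == "exonic"]
  expect_equal(width(ex5), 20L)
  expect_true(mcols(ex5)$truncated)
})

test_that("untruncated windows cover exactly 2w intronic and 2w exonic nt", {
  set.seed(11)
  models <- simulateGeneModels(nGenes = 6L, nExons = 5L)
  win <- boundaryWindows(models, w = 40)
  df <- as.data.frame(mcols(win))
  key <- paste(df$gene_id, df$intron_index)
  for (k in unique(key)) {
    sel <- key == k
    if (any(df$truncated[sel])) next
    expect_equal(sum(width(win[sel & df$window_kind == "intronic"])), 80L)
    expect_equal(sum(width(win[sel & df$window_kind == "exonic"])), 80L)
    # intronic windows lie inside the intron, exonic ones outside it
    ir <- introns(models)
    intr <- ir[paste(mcols(ir)$gene_id, mcols(ir)$intron_index) == k]
    ww <- win[sel]
    inside <- start(ww) >= start(intr) & end(ww) <= end(intr)
    expect_equal(inside, df$window_kind[sel] == "intronic")
  }
})

test_that("GTF and BED12 load into identical internal coordinates", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\texon\t101\t160\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\ttoy\texon\t201\t260\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";'),
    gtf)
  m <- loadGeneModels(gtf, "GTF")
  expect_length(m, 1L)
  ex <- exons(m[["gA.t1"]])
  expect_equal(start(ex), c(101L, 201L))
  expect_equal(end(ex), c(160L, 260L))

  # the same transcript as BED12 (0-based half-open): chromStart 100
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t260\tgA.t1\t0\t+\t100\t260\t0\t2\t60,60\t0,100", bed)
  mb <- loadGeneModels(bed, "BED12")
  expect_equal(start(exons(mb[["gA.t1"]])), start(ex))
  expect_equal(end(exons(mb[["gA.t1"]])), end(ex))

  # single-exon BED12 line, blockCount = 1 -> one exon, no introns
  bed1 <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tsolo\t0\t+\t100\t200\t0\t1\t100\t0", bed1)
  solo <- loadGeneModels(bed1, "BED12")[["solo"]]
  expect_length(exons(solo), 1L)
  expect_length(introns(solo), 0L)
})

test_that("gene models round-trip through BED12", {
  models <- simulateGeneModels(nGenes = 4L, nExons = 3L)
  bed <- tempfile(fileext = ".bed")
  writeGeneModelsBed(models, bed)
  back <- loadGeneModels(bed, "BED12")
  expect_setequal(names(back), names(models))
  for (nm in names(models)) {
    expect_equal(start(exons(back[[nm]])), start(exons(models[[nm]])))
    expect_equal(end(exons(back[[nm]])), end(exons(models[[nm]])))
    expect_equal(as.character(strand(exons(back[[nm]]))[1]),
                 as.character(strand(exons(models[[nm]]))[1]))
  }
})

test_that("malformed annotation input fails loudly, bad records are rejected", {
  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\tnot_a_number\t200\tx", bad)
  expect_error(loadGeneModels(bad, "BED12"), "failed to parse")
})

test_that("registries serve the packaged censuses and lengths", {
  expect_equal(minorIntronCensus("Dmel"), 19L)
  expect_error(minorIntronCensus("Xlae"), "unknown species")
  # census equals a brute-force iteration over the shipped registry file
  reg <- read.delim(system.file("extdata", "minor_introns.tsv",
                                package = "minorsplice"))
  expect_equal(minorIntronCensus("Dmel"),
               sum(reg$species == "Dmel" & reg$intron_class == "minor"))

  snr <- snRNARegistry()
  expect_true(all(c("U1", "U2", "U4", "U5", "U6", "U11", "U12",
                    "U4atac", "U6atac") %in%
                    snr$snrna[snr$species == "Dmel"]))
  expect_true(all(snr$length_nt > 0))
  expect_equal(snRNALength("Dmel", "U11"), 275L)
  expect_equal(snRNALength("Hsap", "U12"), 150L)
  expect_error(snRNALength("Dmel", "U99"), "no snRNA")
})
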