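suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# two-exon toy gene: exons [101,200] and [301,400], minor intron [201,300]
toyGene <- function(strand = "+") {
  geneModel("toy", "toy.t1", "chrT", strand,
            exonStarts = c(101L, 301L), exonEnds = c(200L, 400L),
            intronClass = "minor", seqlength = 1000L)
}

# build an AlignedReadSet from a list of block matrices (start, end) per read
makeReads <- function(blockList, chrom = "chrT", sample = "s1",
                      strand = "+") {
  grs <- lapply(seq_along(blockList), function(i) {
    m <- blockList[[i]]
    gr <- GRanges(chrom, IRanges(m[, 1L], m[, 2L]), strand = strand)
    mcols(gr) <- DataFrame(read_id = sprintf("%s:read%03d", sample, i),
                           sample = sample)
    gr
  })
  AlignedReadSet(suppressWarnings(do.call(c, grs)))
}

# independent brute-force window counter: plain per-read arithmetic (blocks
# grouped once up front; the overlap test itself is bare min/max algebra)
bruteWindowCount <- function(reads, chrom, wstart, wend, minOverlap = 1L) {
  b <- readBlocks(reads)
  bs <- start(b); be <- end(b)
  bc <- as.character(seqnames(b))
  idx <- split(seq_along(bs), mcols(b)$read_id)
  n <- 0L
  for (i in idx) {
    hit <- FALSE
    for (j in i) {
      if (bc[j] != chrom) next
      ov <- min(be[j], wend) - max(bs[j], wstart) + 1L
      if (ov >= minOverlap) { hit <- TRUE; break }
    }
    if (hit) n <- n + 1L
  }
  n
}

# independent brute-force junction counter: exact gap equality per read
bruteJunctionCount <- function(reads, chrom, jstart, jend) {
  b <- readBlocks(reads)
  bs <- start(b); be <- end(b)
  bc <- as.character(seqnames(b))
  idx <- split(seq_along(bs), mcols(b)$read_id)
  n <- 0L
  for (i in idx) {
    if (length(i) < 2L) next
    i <- i[order(bs[i])]
    for (k in seq_len(length(i) - 1L)) {
      gs <- be[i[k]] + 1L; ge <- bs[i[k + 1L]] - 1L
      if (bc[i[k]] == chrom && gs == jstart && ge == jend) { n <- n + 1L; break }
    }
  }
  n
}

# study-shaped simulation: nMinor genes perturbed in the mutant, nBackground
# genes at the baseline retention everywhere
studyConfig <- function(seed, nMinor = 14L, nBackground = 30L,
                        rMutant = 0.4, rBase = 0.02, depth = 5000L) {
  genes <- c(sprintf("mig%02d", seq_len(nMinor)),
             sprintf("bg%02d", seq_len(nBackground)))
  ret <- do.call(rbind, lapply(c("mut", "wt", "het", "rescue"), function(g)
    data.frame(genotype = g, gene_id = genes,
               r = ifelse(g == "mut" & grepl("^mig", genes), rMutant, rBase))))
  spliceSimConfig(seed = seed, depth = depth, retention = ret)
}

studyModels <- function(nMinor = 14L, nBackground = 30L) {
  GeneModelList(c(
    as.list(simulateGeneModels(nMinor, prefix = "mig")),
    as.list(simulateGeneModels(nBackground, prefix = "bg"))))
}
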