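#' @include AllClasses.R AllGenerics.R simulate.R stats-utils.R
NULL

#' Define splice junctions under test
#'
#' A junction is the genomic interval spliced out between a donor and an
#' acceptor, stored 1-based closed like every interval in the package.
#' Competing junctions (e.g. the normal acceptor of an intron versus a
#' cryptic acceptor inside the downstream exon, activated when minor
#' splicing is impaired) share a label column distinguishing
#' `"normal"`/`"cryptic"`.
#'
#' @param chrom chromosome.
#' @param start,end intron bounds, 1-based closed (first and last intronic
#'   base).
#' @param strand `"+"`/`"-"`.
#' @param label junction label, typically `"normal"` or `"cryptic"`.
#' @return `GRanges` with a `label` metadata column.
#' @export
junctionDef <- function(chrom, start, end, strand = "+", label = "normal") {
  stopifnot(all(end >= start))
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)),
                strand = strand)
  mcols(gr)$label <- label
  gr
}

#' Normal/cryptic junction pair of a gene's designated intron
#'
#' Builds the two competing junction definitions for the minor intron of a
#' simulated gene model: the normal junction is the intron itself; the
#' cryptic junction extends `crypticOffset` nt into the downstream exon
#' (strand-aware), matching the simulator's cryptic-splicing geometry.
#'
#' @param model a [GeneModel-class] with one `"minor"` intron.
#' @param crypticOffset nt between normal and cryptic acceptor.
#' @return `GRanges` of length 2 with labels `"normal"`, `"cryptic"`.
#' @export
normalCrypticPair <- function(model, crypticOffset = 30L) {
  k <- .designatedIntron(model)
  if (is.na(k)) stop("gene ", model@geneId, " has no minor intron")
  ex <- model@exons
  a <- end(ex)[k] + 1L; b <- start(ex)[k + 1L] - 1L
  minus <- as.character(strand(ex)[1L]) == "-"
  chrom <- as.character(seqnames(ex)[1L])
  strand <- as.character(strand(ex)[1L])
  if (minus)
    cr <- c(a - as.integer(crypticOffset), b)
  else
    cr <- c(a, b + as.integer(crypticOffset))
  c(junctionDef(chrom, a, b, strand, "normal"),
    junctionDef(chrom, cr[1L], cr[2L], strand, "cryptic"))
}

# per-read alignment gaps (spliced-out segments) with read/sample labels
.readGaps <- function(reads) {
  b <- readBlocks(reads)
  if (length(b) < 2L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), read_id = character(),
                      sample = character()))
  o <- order(match(mcols(b)$read_id, unique(mcols(b)$read_id)), start(b))
  b <- b[o]
  n <- length(b)
  same <- mcols(b)$read_id[-1L] == mcols(b)$read_id[-n]
  data.frame(chrom = as.character(seqnames(b))[-n][same],
             start = (end(b)[-n] + 1L)[same],
             end = (start(b)[-1L] - 1L)[same],
             read_id = mcols(b)$read_id[-n][same],
             sample = mcols(b)$sample[-n][same])
}

#' Count junction-spanning reads
#'
#' A read supports a junction when two of its consecutive blocks are
#' separated by a gap exactly equal to the junction interval (donor and
#' acceptor both matching). Matching is exact by default because aligners
#' report precise splice gaps and any tolerance would conflate neighbouring
#' cryptic sites; `tolerance` (nt, applied to each end independently) is
#' available for noisy input.
#'
#' @param reads an [AlignedReadSet-class].
#' @param junctions `GRanges` of junction intervals (see [junctionDef()]).
#' @param tolerance max per-end coordinate deviation in nt (default 0).
#' @param bySample return a junctions x samples matrix instead of totals.
#' @return integer vector (or matrix with `bySample = TRUE`) of read counts.
#' @export
countJunctionReads <- function(reads, junctions, tolerance = 0L,
                               bySample = FALSE) {
  g <- .readGaps(reads)
  samples <- unique(mcols(readBlocks(reads))$sample)
  if (!length(samples)) samples <- "none"
  m <- matrix(0L, length(junctions), length(samples),
              dimnames = list(mcols(junctions)$label, samples))
  if (nrow(g)) {
    if (tolerance == 0L) {
      jkey <- paste(as.character(seqnames(junctions)), start(junctions),
                    end(junctions), sep = "\1")
      gkey <- paste(g$chrom, g$start, g$end, sep = "\1")
      hit <- match(gkey, jkey)
      ok <- !is.na(hit)
      if (any(ok)) {
        tab <- table(factor(hit[ok], levels = seq_along(junctions)),
                     factor(g$sample[ok], levels = samples))
        m[] <- m + as.integer(tab)
      }
    } else {
      for (j in seq_along(junctions)) {
        ok <- g$chrom == as.character(seqnames(junctions))[j] &
          abs(g$start - start(junctions)[j]) <= tolerance &
          abs(g$end - end(junctions)[j]) <= tolerance
        if (any(ok)) {
          tb <- table(factor(g$sample[ok], levels = samples))
          m[j, ] <- m[j, ] + as.integer(tb)
        }
      }
    }
  }
  if (bySample) m else as.integer(rowSums(m))
}

#' Per-replicate usage of a normal/cryptic junction pair
#'
#' Usage is the fraction of junction-spanning reads choosing the cryptic
#' site: `cryptic / (cryptic + normal)` per sample. A replicate with zero
#' junction reads in total is flagged unevaluable rather than given a
#' usage of 0/0.
#'
#' @param reads an [AlignedReadSet-class].
#' @param pair `GRanges` of length 2 labelled `"normal"` and `"cryptic"`
#'   (see [normalCrypticPair()]).
#' @param design data.frame `sample`, `genotype`.
#' @param tolerance passed to [countJunctionReads()].
#' @return data.frame per sample: counts, `usage`, `evaluable`.
#' @export
junctionUsage <- function(reads, pair, design, tolerance = 0L) {
  stopifnot(length(pair) == 2L,
            setequal(mcols(pair)$label, c("normal", "cryptic")))
  m <- countJunctionReads(reads, pair, tolerance, bySample = TRUE)
  norm <- m[match("normal", mcols(pair)$label), ]
  cry <- m[match("cryptic", mcols(pair)$label), ]
  smp <- colnames(m)
  tot <- norm + cry
  data.frame(sample = smp,
             genotype = design$genotype[match(smp, design$sample)],
             normal_count = as.integer(norm),
             cryptic_count = as.integer(cry),
             usage = ifelse(tot > 0, cry / tot, NA_real_),
             evaluable = tot > 0,
             row.names = NULL)
}

#' Test a shift in cryptic junction usage across genotypes
#'
#' Unpaired two-tailed Student's t-tests (pooled variance) on per-replicate
#' usage fractions, mutant versus each comparator; the shift is flagged
#' significant only when every contrast passes `p < alpha`.
#'
#' @param usage output of [junctionUsage()].
#' @param mutant genotype under test.
#' @param comparators default: all other genotypes in `usage`.
#' @param alpha significance level.
#' @return data.frame, one row per contrast, plus an attribute-free
#'   `all_significant` column (same value in every row).
#' @export
junctionUsageShift <- function(usage, mutant = "mut", comparators = NULL,
                               alpha = 0.05) {
  if (is.null(comparators))
    comparators <- setdiff(unique(usage$genotype), mutant)
  mutv <- usage$usage[usage$genotype == mutant & usage$evaluable]
  out <- list()
  for (cmp in comparators) {
    cmpv <- usage$usage[usage$genotype == cmp & usage$evaluable]
    row <- data.frame(contrast = paste0(mutant, "_vs_", cmp),
                      n_mut = length(mutv), n_comp = length(cmpv),
                      mean_mut = NA_real_, mean_comp = NA_real_,
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      tested = FALSE, reason = "")
    if (length(mutv) >= 2L && length(cmpv) >= 2L) {
      tt <- pooledTTest(mutv, cmpv)
      row$mean_mut <- tt$mean_x; row$mean_comp <- tt$mean_y
      row$t <- tt$t; row$df <- tt$df; row$p <- tt$p; row$tested <- TRUE
    } else {
      row$reason <- "fewer than 2 evaluable replicates in a group"
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  res$all_significant <- all(res$tested) && all(res$p < alpha)
  res
}
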