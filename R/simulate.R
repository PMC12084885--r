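#' @include AllClasses.R AllGenerics.R annotation.R
NULL

#' Build a simulation configuration
#'
#' @param seed master RNG seed (integer). Identical configurations produce
#'   byte-identical outputs.
#' @param readLength single-end read length in nt.
#' @param depth reads per transcript per sample.
#' @param genotypes data.frame with columns `genotype`, `replicates`. The
#'   default design mirrors a four-genotype study: homozygous mutant
#'   (`"mut"`), wild type (`"wt"`), heterozygote (`"het"`), and transgenic
#'   rescue (`"rescue"`), three replicates each.
#' @param mutant the perturbed genotype; all others act as comparators.
#' @param retention data.frame `genotype`, `gene_id`, `r`: fraction of
#'   molecules retaining the gene's minor intron (intron-retention level).
#' @param crypticFraction data.frame `genotype`, `gene_id`, `fraction`:
#'   among spliced molecules, fraction spliced to the cryptic acceptor.
#' @param crypticOffset nt between the normal and the cryptic acceptor
#'   (the cryptic 3' splice site lies this far inside the downstream exon).
#' @param enrichment named numeric: planted IP/control ratios for RIP count
#'   simulation.
#' @param dispersion negative-binomial dispersion for simulated counts.
#' @param libFactorRange range of per-sample library-size factors.
#' @param sigmaLog log-normal noise sd (natural log) for protein abundances.
#' @return A validated [SpliceSimConfig-class].
#' @examples
#' cfg <- spliceSimConfig(seed = 7, retention = data.frame(
#'   genotype = "mut", gene_id = "g1", r = 0.4))
#' @export
spliceSimConfig <- function(seed = 1L, readLength = 100L, depth = 5000L,
                            genotypes = data.frame(
                              genotype = c("mut", "wt", "het", "rescue"),
                              replicates = 3L),
                            mutant = "mut",
                            retention = data.frame(genotype = character(),
                                                   gene_id = character(),
                                                   r = numeric()),
                            crypticFraction = data.frame(
                              genotype = character(), gene_id = character(),
                              fraction = numeric()),
                            crypticOffset = 30L,
                            enrichment = setNames(numeric(), character()),
                            dispersion = 0.05,
                            libFactorRange = c(0.8, 1.2),
                            sigmaLog = 0.1) {
  new("SpliceSimConfig", seed = as.integer(seed),
      readLength = as.integer(readLength), depth = as.integer(depth),
      genotypes = genotypes, mutant = mutant, retention = retention,
      crypticFraction = crypticFraction,
      crypticOffset = as.integer(crypticOffset), enrichment = enrichment,
      dispersion = dispersion, libFactorRange = libFactorRange,
      sigmaLog = sigmaLog)
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields map directly to [spliceSimConfig()] arguments; `genotypes`,
#' `retention` and `crypticFraction` are lists of records; `enrichment` is a
#' mapping feature -> factor.
#'
#' @param path YAML file.
#' @return A [SpliceSimConfig-class].
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("seed", "readLength", "depth", "mutant", "crypticOffset",
              "dispersion", "sigmaLog"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$libFactorRange)) args$libFactorRange <- unlist(y$libFactorRange)
  todf <- function(x) do.call(rbind, lapply(x, as.data.frame))
  if (!is.null(y$genotypes)) args$genotypes <- todf(y$genotypes)
  if (!is.null(y$retention)) args$retention <- todf(y$retention)
  if (!is.null(y$crypticFraction)) args$crypticFraction <- todf(y$crypticFraction)
  if (!is.null(y$enrichment)) args$enrichment <- unlist(y$enrichment)
  do.call(spliceSimConfig, args)
}

#' Sample labels of a configuration
#' @param config a [SpliceSimConfig-class].
#' @return data.frame `sample`, `genotype`, `replicate` in simulation order.
#' @export
simSamples <- function(config) {
  g <- config@genotypes
  do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    data.frame(sample = sprintf("%s_rep%d", g$genotype[i],
                                seq_len(g$replicates[i])),
               genotype = g$genotype[i],
               replicate = seq_len(g$replicates[i]))))
}

#' Generate synthetic multi-exon gene models
#'
#' Each gene gets its own contig, `nExons` exons of width `exonLength`
#' separated by introns of width `intronLength`, and one intron (by default
#' the second, in transcription order) labelled `"minor"`. Strands alternate
#' so that minus-strand geometry is always exercised.
#'
#' @param nGenes number of genes.
#' @param nExons exons per gene (>= 2 for any gene to have an intron).
#' @param exonLength,intronLength widths in nt.
#' @param minorIntronIndex transcription-order index of the minor intron;
#'   `NA` for genes whose introns are all major.
#' @param prefix gene-id prefix.
#' @param alternateStrand alternate `+`/`-` across genes.
#' @return A [GeneModelList-class]; contig lengths are set so SAM headers
#'   can be emitted.
#' @export
simulateGeneModels <- function(nGenes = 1L, nExons = 4L, exonLength = 300L,
                               intronLength = 200L, minorIntronIndex = 2L,
                               prefix = "gene", alternateStrand = TRUE) {
  stopifnot(nExons >= 1L, exonLength >= 1L, intronLength >= 1L)
  models <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    gid <- sprintf("%s%02d", prefix, i)
    starts <- 1001L + (seq_len(nExons) - 1L) * (exonLength + intronLength)
    ends <- starts + exonLength - 1L
    strand <- if (alternateStrand && i %% 2L == 0L) "-" else "+"
    gm <- geneModel(gid, paste0(gid, ".t1"), paste0("ctg_", gid), strand,
                    starts, ends, intronClass = "major",
                    seqlength = max(ends) + 1000L)
    if (!is.na(minorIntronIndex) && nExons >= 2L)
      gm <- setIntronClass(gm, min(minorIntronIndex, nExons - 1L), "minor")
    models[[i]] <- gm
  }
  GeneModelList(models)
}

# genomic index (between exon k and k+1) of the designated, i.e. minor, intron
.designatedIntron <- function(gm) {
  k <- which(gm@intronClass == "minor")
  if (length(k) == 0L) return(NA_integer_)
  if (length(k) > 1L) stop("gene ", gm@geneId, " has several minor introns; ",
                           "the simulator supports one designated intron per gene")
  k
}

# segments of each isoform template, in genomic order, plus the designated
# gap bounds (1-based closed) for junction-truth bookkeeping
.isoformSegments <- function(gm, isoform, crypticOffset) {
  ex <- gm@exons
  k <- .designatedIntron(gm)
  seg <- data.frame(start = start(ex), end = end(ex))
  gap <- c(NA_integer_, NA_integer_)
  if (isoform != "spliced" && is.na(k))
    stop("gene ", gm@geneId, " has no designated (minor) intron")
  if (isoform == "retained") {
    # merge exons k and k+1 across the intron
    seg$end[k] <- seg$end[k + 1L]
    seg <- seg[-(k + 1L), , drop = FALSE]
  } else if (!is.na(k)) {
    a <- end(ex)[k] + 1L; b <- start(ex)[k + 1L] - 1L
    if (isoform == "cryptic") {
      minus <- as.character(strand(ex)[1L]) == "-"
      if (minus) {
        # downstream exon (transcription) is the genomic-left one
        seg$end[k] <- seg$end[k] - crypticOffset
        gap <- c(a - crypticOffset, b)
      } else {
        seg$start[k + 1L] <- seg$start[k + 1L] + crypticOffset
        gap <- c(a, b + crypticOffset)
      }
      if (seg$end[k] < seg$start[k] || seg$end[k + 1L] < seg$start[k + 1L])
        stop("crypticOffset exceeds the exon flanking the designated intron")
    } else {
      gap <- c(a, b)
    }
  }
  list(seg = seg, gap = gap)
}

# map 0-based template starts to genomic blocks (reads of length L placed on
# the genomic-order concatenation of kept segments)
.templateToBlocks <- function(seg, starts0, L) {
  wseg <- seg$end - seg$start + 1L
  cumw <- cumsum(wseg)
  tplStart <- cumw - wseg + 1L
  segTpl <- IRanges(tplStart, width = wseg)
  rd <- IRanges(starts0 + 1L, width = L)
  ov <- findOverlaps(rd, segTpl)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  inter <- IRanges::pintersect(rd[q], segTpl[s])
  data.frame(read = q,
             start = seg$start[s] + (start(inter) - tplStart[s]),
             end = seg$start[s] + (end(inter) - tplStart[s]))
}

.lookupFraction <- function(df, col, genotype, gene) {
  i <- which(df$genotype == genotype & df$gene_id == gene)
  if (length(i)) df[[col]][i[1L]] else 0
}

#' Simulate aligned reads with controlled intron retention
#'
#' For every sample and transcript, `depth` single-end reads of fixed length
#' are drawn. Each read's template is intron-retained with the genotype's
#' retention fraction `r`, otherwise spliced; spliced templates use the
#' cryptic acceptor with the configured cryptic fraction. Start positions
#' are uniform over the template, and reads crossing a spliced-out segment
#' carry multiple blocks (one alignment gap per crossed intron). There is no
#' sequencing-error or bias model: the boundary-window statistic depends only
#' on placement geometry.
#'
#' @param config a [SpliceSimConfig-class].
#' @param models a [GeneModelList-class]; genes named in
#'   `config@retention`/`config@crypticFraction` must carry a `"minor"`
#'   intron (the designated one).
#' @return list with elements
#'   \describe{
#'     \item{reads}{an [AlignedReadSet-class];}
#'     \item{truth}{data.frame of per-sample, per-gene template counts
#'       (`n_spliced`, `n_retained`, `n_cryptic`) and the number of reads
#'       spanning the designated junction (`jr_normal`, `jr_cryptic`),
#'       derived from template geometry, not from the emitted blocks;}
#'     \item{design}{sample sheet as from [simSamples()].}
#'   }
#' @export
simulateReads <- function(config, models) {
  stopifnot(is(config, "SpliceSimConfig"), is(models, "GeneModelList"))
  validObject(config)
  L <- config@readLength
  for (gm in as.list(models)) {
    spliced_len <- sum(width(gm@exons))
    if (L >= spliced_len)
      stop("readLength (", L, ") must be shorter than the spliced template of ",
           gm@geneId, " (", spliced_len, " nt)")
  }
  set.seed(config@seed)
  design <- simSamples(config)
  blocks <- list()
  truth <- list()
  for (si in seq_len(nrow(design))) {
    smp <- design$sample[si]; gt <- design$genotype[si]
    for (gm in as.list(models)) {
      gid <- gm@geneId
      r <- .lookupFraction(config@retention, "r", gt, gid)
      cf <- .lookupFraction(config@crypticFraction, "fraction", gt, gid)
      n <- config@depth
      cnt <- as.vector(stats::rmultinom(1L, n,
        c((1 - r) * (1 - cf), (1 - r) * cf, r)))
      names(cnt) <- c("spliced", "cryptic", "retained")
      jr <- c(normal = 0L, cryptic = 0L)
      for (iso in names(cnt)) {
        m <- cnt[[iso]]
        if (m == 0L) next
        if (iso %in% c("retained", "cryptic") && is.na(.designatedIntron(gm)))
          stop("retention/cryptic configured for ", gid,
               " but it has no minor intron")
        isoseg <- .isoformSegments(gm, iso, config@crypticOffset)
        Ltpl <- sum(isoseg$seg$end - isoseg$seg$start + 1L)
        if (L >= Ltpl)
          stop("readLength >= ", iso, " template of ", gid)
        s0 <- sample.int(Ltpl - L + 1L, m, replace = TRUE) - 1L
        if (!is.na(isoseg$gap[1L])) {
          # template coordinate of the designated junction
          J <- sum(pmax(0L, pmin(isoseg$seg$end, isoseg$gap[1L] - 1L) -
                          isoseg$seg$start + 1L) *
                     (isoseg$seg$end < isoseg$gap[1L]))
          spans <- sum(s0 >= J - L + 1L & s0 <= J - 1L)
          if (iso == "spliced") jr["normal"] <- jr[["normal"]] + spans
          if (iso == "cryptic") jr["cryptic"] <- jr[["cryptic"]] + spans
        }
        bl <- .templateToBlocks(isoseg$seg, s0, L)
        gr <- GRanges(as.character(seqnames(gm@exons)[1L]),
                      IRanges(bl$start, bl$end),
                      strand = as.character(strand(gm@exons)[1L]),
                      seqinfo = seqinfo(gm@exons))
        mcols(gr) <- DataFrame(
          read_id = sprintf("%s:%s:%s%05d", smp, gid, substr(iso, 1, 1),
                            bl$read),
          sample = smp)
        blocks[[length(blocks) + 1L]] <- gr
      }
      truth[[length(truth) + 1L]] <- data.frame(
        sample = smp, genotype = gt, gene_id = gid,
        n_spliced = cnt[["spliced"]], n_cryptic = cnt[["cryptic"]],
        n_retained = cnt[["retained"]],
        jr_normal = jr[["normal"]], jr_cryptic = jr[["cryptic"]])
    }
  }
  all_blocks <- if (length(blocks)) {
    suppressWarnings(do.call(c, unname(blocks)))
  } else {
    gr <- GRanges()
    mcols(gr) <- DataFrame(read_id = character(), sample = character())
    gr
  }
  list(reads = new("AlignedReadSet", blocks = all_blocks),
       truth = do.call(rbind, truth), design = design)
}

#' @describeIn AlignedReadSet-class number of distinct reads
#' @param x an `AlignedReadSet`
#' @export
setMethod("length", "AlignedReadSet", function(x)
  length(unique(mcols(x@blocks)$read_id)))

#' @describeIn AlignedReadSet-class the flat block `GRanges`
#' @export
setMethod("readBlocks", "AlignedReadSet", function(x) x@blocks)

#' @describeIn AlignedReadSet-class sample labels present
#' @param object an `AlignedReadSet`
#' @export
setMethod("sampleNames", "AlignedReadSet", function(object)
  unique(mcols(object@blocks)$sample))

setMethod("show", "AlignedReadSet", function(object) {
  cat("AlignedReadSet:", length(object), "read(s),",
      length(object@blocks), "block(s),",
      length(sampleNames(object)), "sample(s)\n")
})

#' Construct an AlignedReadSet from a block GRanges
#' @param blocks `GRanges` with metadata columns `read_id`, `sample`.
#' @return An [AlignedReadSet-class].
#' @export
AlignedReadSet <- function(blocks) new("AlignedReadSet", blocks = blocks)

#' Subset an AlignedReadSet by sample label
#' @param x an [AlignedReadSet-class].
#' @param sample sample label(s) to keep.
#' @export
subsetBySample <- function(x, sample) {
  AlignedReadSet(x@blocks[mcols(x@blocks)$sample %in% sample])
}

#' Write reads as SAM
#'
#' Emits an unsorted single-end SAM with `@SQ` lines from the reads'
#' `Seqinfo` (contig lengths must be set, as [simulateGeneModels()] does).
#' Alignment gaps between blocks become `N` CIGAR operations; sequence and
#' quality are `*` since the simulator models placement, not base calls.
#'
#' @param reads an [AlignedReadSet-class].
#' @param path output `.sam` file.
#' @return `path`, invisibly.
#' @export
writeSam <- function(reads, path) {
  b <- readBlocks(reads)
  si <- seqinfo(b)
  if (any(is.na(seqlengths(si))))
    stop("seqlengths must be set to emit @SQ headers")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", seqlevels(si), seqlengths(si)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (length(b)) {
    rid <- mcols(b)$read_id
    o <- order(match(rid, unique(rid)), start(b))
    rid <- rid[o]
    st <- start(b)[o]; en <- end(b)[o]
    chr <- as.character(seqnames(b))[o]
    neg <- as.character(strand(b))[o] == "-"
    grp <- match(rid, unique(rid))
    first <- !duplicated(grp)
    nb <- tabulate(grp)
    # vectorised CIGAR assembly: blocks become M ops, inter-block gaps N ops
    mop <- paste0(en - st + 1L, "M")
    gap <- integer(length(st))
    gap[-1L] <- st[-1L] - en[-length(st)] - 1L
    piece <- ifelse(first, mop, paste0(gap, "N", mop))
    cig <- vapply(split(piece, grp), paste0, character(1), collapse = "")
    recs <- paste(rid[first], ifelse(neg[first], 16L, 0L), chr[first],
                  st[first], 60L, cig, "*", 0L, 0L, "*", "*", sep = "\t")
    writeLines(recs, con)
  }
  invisible(path)
}

#' Write reads as BED12
#'
#' Block-for-block equivalent of the SAM export (one BED12 line per read,
#' blocks = aligned segments), in BED's 0-based half-open convention.
#'
#' @param reads an [AlignedReadSet-class].
#' @param path output `.bed` file.
#' @return `path`, invisibly.
#' @export
writeReadsBed12 <- function(reads, path) {
  b <- readBlocks(reads)
  grl <- GenomicRanges::split(b, factor(mcols(b)$read_id,
                                        levels = unique(mcols(b)$read_id)))
  rtracklayer::export(grl, path, format = "bed")
  invisible(path)
}

#' Read alignments from SAM/BAM or BED12
#'
#' SAM/BAM parsing is delegated to Rsamtools/GenomicAlignments (`N` CIGAR
#' gaps become inter-block gaps); BED12 blocks are converted from 0-based
#' half-open to the internal 1-based `GRanges` representation.
#'
#' @param path alignment file (`.sam`, `.bam`, or `.bed`).
#' @param sample sample label to attach; default: `read_id` prefix up to the
#'   first `:` if present, else the file base name.
#' @return An [AlignedReadSet-class].
#' @export
readAlignments <- function(path, sample = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    if (!requireNamespace("GenomicAlignments", quietly = TRUE) ||
        !requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading SAM/BAM requires Rsamtools and GenomicAlignments")
    bam <- if (ext == "sam")
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE)
    else path
    gal <- GenomicAlignments::readGAlignments(bam, use.names = TRUE)
    grl <- GenomicAlignments::grglist(gal)
    b <- unlist(grl, use.names = FALSE)
    rid <- rep(names(grl), lengths(grl))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    bl <- mcols(gr)$blocks
    if (is.null(bl)) {  # plain BED: one block per feature
      b <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                   strand = strand(gr))
      rid <- mcols(gr)$name
    } else {
      shifted <- IRanges::shift(bl, start(gr) - 1L)  # block starts are relative
      nb <- lengths(shifted)
      b <- GRanges(rep(seqnames(gr), nb), unlist(shifted, use.names = FALSE),
                   strand = rep(strand(gr), nb))
      rid <- rep(mcols(gr)$name, nb)
    }
  }
  if (is.null(sample)) {
    sample <- sub(":.*$", "", rid)
    if (all(sample == rid)) sample <- tools::file_path_sans_ext(basename(path))
  }
  mcols(b) <- DataFrame(read_id = rid, sample = sample)
  AlignedReadSet(b)
}

.nbCounts <- function(mu, dispersion) {
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a replicate count table
#'
#' Negative-binomial counts around per-condition means, with per-sample
#' library-size factors drawn from `config@libFactorRange`.
#'
#' For `kind = "rip"`, samples are `IP` and `control` arms (`replicates`
#' each); features named in `config@enrichment` have their IP means
#' multiplied by the planted factor. For `kind = "rnaseq"`, samples follow
#' the genotype design and features listed in `planted` get a `log2fc`
#' shift in the mutant genotype.
#'
#' @param config a [SpliceSimConfig-class] (seed, dispersion, library-size
#'   range, enrichment, genotype design).
#' @param kind `"rip"` or `"rnaseq"`.
#' @param nFeatures number of background features (planted features are
#'   added on top for `"rip"` if not among the `featureNames`).
#' @param baseMeanRange range of per-feature base means (log-uniform).
#' @param replicates per-arm replicates for `"rip"` (ignored for
#'   `"rnaseq"`, which uses the genotype design).
#' @param planted for `"rnaseq"`: data.frame `feature`, `log2fc`.
#' @param featureNames optional feature names (length `nFeatures`).
#' @return list: `counts` (matrix features x samples), `design` (data.frame
#'   `sample` plus `arm`/`replicate` or `genotype`/`replicate`), and
#'   `truth` (per-feature planted factor / log2fc).
#' @export
simulateCountTable <- function(config, kind = c("rip", "rnaseq"),
                               nFeatures = 100L,
                               baseMeanRange = c(50, 500),
                               replicates = 3L,
                               planted = data.frame(feature = character(),
                                                    log2fc = numeric()),
                               featureNames = NULL) {
  stopifnot(is(config, "SpliceSimConfig"))
  validObject(config)
  kind <- match.arg(kind)
  set.seed(config@seed)
  if (is.null(featureNames))
    featureNames <- sprintf("feature%03d", seq_len(nFeatures))
  if (kind == "rip") {
    extra <- setdiff(names(config@enrichment), featureNames)
    featureNames <- c(extra, featureNames)
  }
  nf <- length(featureNames)
  base <- exp(stats::runif(nf, log(baseMeanRange[1L]), log(baseMeanRange[2L])))
  names(base) <- featureNames
  if (kind == "rip") {
    stopifnot(replicates >= 2L)
    design <- data.frame(
      sample = c(sprintf("IP_rep%d", seq_len(replicates)),
                 sprintf("control_rep%d", seq_len(replicates))),
      arm = rep(c("IP", "control"), each = replicates),
      replicate = rep(seq_len(replicates), 2L))
    fac <- setNames(rep(1, nf), featureNames)
    fac[names(config@enrichment)] <- config@enrichment
    truth <- data.frame(feature = featureNames, enrichment = unname(fac))
    mean_mat <- cbind(base * fac, base)[, rep(1:2, each = replicates)]
  } else {
    design <- simSamples(config)
    lfc <- setNames(rep(0, nf), featureNames)
    lfc[planted$feature] <- planted$log2fc
    truth <- data.frame(feature = featureNames, log2fc = unname(lfc))
    fac <- ifelse(design$genotype == config@mutant, 1, 0)
    mean_mat <- outer(base, rep(1, nrow(design))) *
      2^outer(lfc, fac)
  }
  lib <- stats::runif(nrow(design), config@libFactorRange[1L],
                      config@libFactorRange[2L])
  mu <- sweep(mean_mat, 2L, lib, `*`)
  counts <- matrix(.nbCounts(as.vector(mu), config@dispersion),
                   nrow = nf, dimnames = list(featureNames, design$sample))
  list(counts = counts, design = design, truth = truth)
}

#' Simulate a protein-abundance table
#'
#' Log-normal abundances per genotype design, with planted fold-changes in
#' the mutant genotype. `sigmaLog = 0` gives noise-free identities.
#'
#' @param config a [SpliceSimConfig-class].
#' @param nFeatures number of features.
#' @param baseRange range of base abundances (log-uniform).
#' @param planted data.frame `feature`, `fc` (linear fold-change applied in
#'   the mutant genotype).
#' @param featureNames optional feature names.
#' @return list: `abundance` matrix, `design`, `truth`.
#' @export
simulateAbundanceTable <- function(config, nFeatures = 100L,
                                   baseRange = c(1e3, 1e6),
                                   planted = data.frame(feature = character(),
                                                        fc = numeric()),
                                   featureNames = NULL) {
  stopifnot(is(config, "SpliceSimConfig"))
  validObject(config)
  set.seed(config@seed + 1L)
  if (is.null(featureNames))
    featureNames <- sprintf("protein%03d", seq_len(nFeatures))
  nf <- length(featureNames)
  if (nf < 1L) stop("nFeatures must be >= 1")
  design <- simSamples(config)
  base <- exp(stats::runif(nf, log(baseRange[1L]), log(baseRange[2L])))
  fc <- setNames(rep(1, nf), featureNames)
  fc[planted$feature] <- planted$fc
  mean_mat <- outer(base, rep(1, nrow(design))) *
    outer(fc, ifelse(design$genotype == config@mutant, 1, 0),
          function(f, m) f^m)
  ab <- mean_mat * exp(matrix(stats::rnorm(nf * nrow(design), 0,
                                           config@sigmaLog),
                              nrow = nf))
  dimnames(ab) <- list(featureNames, design$sample)
  list(abundance = ab, design = design,
       truth = data.frame(feature = featureNames, fc = unname(fc)))
}

#' Simulate an RT-qPCR Ct table
#'
#' Reference genes get Ct values around `baseCt`; each target's Ct is offset
#' by `-log2(level)` from the reference mean in each genotype, so a planted
#' relative level of 2 shows up as a Ct one cycle lower (amplification
#' efficiency 2 per cycle).
#'
#' @param config a [SpliceSimConfig-class].
#' @param levels data.frame `target`, `genotype`, `level`: planted relative
#'   level of each target per genotype (relative to the references).
#' @param references reference-gene names.
#' @param baseCt mean reference Ct.
#' @param noiseSd per-well Ct noise (cycles); 0 for exact identities.
#' @return list: `ct` (matrix genes x samples), `design`.
#' @export
simulateCtTable <- function(config,
                            levels = data.frame(target = "targetA",
                                                genotype = "mut", level = 2),
                            references = c("act5c", "gapdh", "rp49"),
                            baseCt = 18, noiseSd = 0.05) {
  stopifnot(is(config, "SpliceSimConfig"))
  set.seed(config@seed + 2L)
  design <- simSamples(config)
  targets <- unique(levels$target)
  genes <- c(references, targets)
  ct <- matrix(NA_real_, length(genes), nrow(design),
               dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design))) {
    refct <- baseCt + stats::rnorm(length(references), 0, noiseSd)
    ct[references, j] <- refct
    for (tg in targets) {
      i <- which(levels$target == tg & levels$genotype == design$genotype[j])
      lvl <- if (length(i)) levels$level[i[1L]] else 1
      ct[tg, j] <- mean(refct) - log2(lvl) + stats::rnorm(1L, 0, noiseSd)
    }
  }
  list(ct = ct, design = design)
}
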