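#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- mcols mcols<-
#' @importFrom BiocGenerics start end width strand
#' @importFrom GenomicRanges GRanges GRangesList findOverlaps seqnames
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqinfo Seqinfo seqlevels
NULL

#' GeneModel: one transcript's exon structure
#'
#' A `GeneModel` holds the exon chain of a single (representative) transcript
#' together with a class label (`"major"` or `"minor"`) for each of its
#' introns.  Minor (U12-type) introns are a rare intron class excised by the
#' minor spliceosome; the label is always assigned explicitly (from a registry
#' or a simulation design), never inferred from sequence.
#'
#' Exons are stored as a [GenomicRanges::GRanges] in 1-based closed
#' coordinates (the Bioconductor convention); BED input/output converts at the
#' boundary.  Validity requires exons on one chromosome and strand, sorted by
#' start, non-overlapping, and separated by at least 1 nt (the intron).
#'
#' @slot geneId character(1) gene identifier.
#' @slot transcriptId character(1) transcript identifier.
#' @slot exons `GRanges` of exons, sorted by genomic start.
#' @slot intronClass character vector, one of `"major"`/`"minor"` per intron
#'   (length = number of exons - 1, in genomic order).
#'
#' @seealso [geneModel()], [introns()], [boundaryWindows()]
#' @export
setClass("GeneModel",
  slots = c(
    geneId = "character",
    transcriptId = "character",
    exons = "GRanges",
    intronClass = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (length(object@geneId) != 1L || is.na(object@geneId))
    msg <- c(msg, "geneId must be a single non-NA string")
  if (length(object@transcriptId) != 1L || is.na(object@transcriptId))
    msg <- c(msg, "transcriptId must be a single non-NA string")
  if (length(ex) < 1L)
    msg <- c(msg, "a transcript needs at least one exon")
  if (length(unique(as.character(seqnames(ex)))) > 1L)
    msg <- c(msg, "all exons must lie on one chromosome")
  if (length(unique(as.character(strand(ex)))) > 1L)
    msg <- c(msg, "all exons must share one strand")
  if (length(ex) >= 1L && any(as.character(strand(ex)) == "*"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (any(width(ex) < 1L))
    msg <- c(msg, "every exon must have length >= 1")
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be sorted by start")
    else if (any(start(ex)[-1L] <= end(ex)[-length(ex)] + 1L))
      msg <- c(msg, "exons must be non-overlapping and separated by >= 1 nt")
  }
  nint <- max(length(ex) - 1L, 0L)
  if (length(object@intronClass) != nint)
    msg <- c(msg, sprintf("intronClass must have length %d (one per intron)", nint))
  else if (nint > 0L && !all(object@intronClass %in% c("major", "minor")))
    msg <- c(msg, "intronClass values must be 'major' or 'minor'")
  if (length(msg)) msg else TRUE
})

#' List of GeneModel objects
#'
#' A `SimpleList` whose elements are [GeneModel-class] objects, named by
#' transcript id.
#'
#' @export
setClass("GeneModelList",
  contains = "SimpleList",
  prototype = prototype(elementType = "GeneModel")
)

#' AlignedReadSet: block-structured read placements
#'
#' A compact container for aligned single-end reads.  Each read is an ordered
#' set of one or more genomic blocks (aligned segments); the gaps between
#' consecutive blocks are spliced-out segments, exactly as encoded by `N`
#' operations in a SAM CIGAR or by the block fields of BED12.  Blocks are
#' stored as one flat `GRanges` carrying `read_id` and `sample` metadata
#' columns, which keeps window and junction counting vectorised even for
#' millions of reads.
#'
#' @slot blocks `GRanges` with mandatory metadata columns `read_id`
#'   (character) and `sample` (character); blocks of one read are
#'   non-overlapping and sorted by start.
#'
#' @seealso [simulateReads()], [readAlignments()], [countWindowReads()]
#' @export
setClass("AlignedReadSet", slots = c(blocks = "GRanges"))

setValidity("AlignedReadSet", function(object) {
  b <- object@blocks
  mc <- names(mcols(b))
  if (!all(c("read_id", "sample") %in% mc))
    return("blocks must carry 'read_id' and 'sample' metadata columns")
  if (length(b) > 1L) {
    o <- order(mcols(b)$read_id, start(b))
    bo <- b[o]
    same <- mcols(bo)$read_id[-1L] == mcols(bo)$read_id[-length(bo)]
    if (any(same & (start(bo)[-1L] <= end(bo)[-length(bo)])))
      return("blocks of a single read must be sorted and non-overlapping")
  }
  TRUE
})

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators: the seed, the read
#' geometry, the genotype/replicate design, per-genotype minor-intron
#' retention fractions, cryptic-splice-site usage, planted RIP enrichment
#' factors, and the noise model for count and abundance tables.  The defaults
#' reproduce the study design the analysis modules are validated against:
#' four genotypes (a homozygous mutant, wild type, heterozygote, and a
#' transgenic rescue) with three replicates each, 100-nt single-end reads,
#' and 5000 reads per transcript per sample.
#'
#' @slot seed integer(1) master RNG seed; identical configs give
#'   byte-identical outputs.
#' @slot readLength integer(1) read length in nt (default 100).
#' @slot depth integer(1) reads per transcript per sample (default 5000).
#' @slot genotypes data.frame with columns `genotype`, `replicates`
#'   (replicates >= 2 for any genotype entering a t-test).
#' @slot mutant character(1) which genotype carries the perturbation; the
#'   remaining genotypes are its comparators.
#' @slot retention data.frame with columns `genotype`, `gene_id`, `r`:
#'   the fraction of transcript molecules that retain the gene's minor
#'   intron in that genotype (r in \[0,1\]).
#' @slot crypticFraction data.frame with columns `genotype`, `gene_id`,
#'   `fraction`: among spliced molecules, the fraction using the cryptic
#'   acceptor instead of the normal one.
#' @slot crypticOffset integer(1) nt by which the cryptic acceptor lies
#'   inside the exon downstream of the designated intron.
#' @slot enrichment named numeric, planted IP/control ratio per feature for
#'   RIP count tables.
#' @slot dispersion numeric(1) negative-binomial dispersion of simulated
#'   counts (default 0.05).
#' @slot libFactorRange numeric(2) range of per-sample library-size factors.
#' @slot sigmaLog numeric(1) log-normal sd (natural log) of simulated protein
#'   abundances.
#'
#' @seealso [spliceSimConfig()], [simulateReads()], [simulateCountTable()]
#' @export
setClass("SpliceSimConfig",
  slots = c(
    seed = "integer",
    readLength = "integer",
    depth = "integer",
    genotypes = "data.frame",
    mutant = "character",
    retention = "data.frame",
    crypticFraction = "data.frame",
    crypticOffset = "integer",
    enrichment = "numeric",
    dispersion = "numeric",
    libFactorRange = "numeric",
    sigmaLog = "numeric"
  )
)

setValidity("SpliceSimConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (object@readLength < 1L)
    msg <- c(msg, "readLength must be >= 1")
  if (object@depth < 0L)
    msg <- c(msg, "depth must be >= 0")
  g <- object@genotypes
  if (!all(c("genotype", "replicates") %in% names(g)))
    msg <- c(msg, "genotypes needs columns 'genotype' and 'replicates'")
  else {
    if (anyDuplicated(g$genotype))
      msg <- c(msg, "genotype labels must be unique")
    if (any(g$replicates < 2L))
      msg <- c(msg, "every genotype needs >= 2 replicates (t-test precondition)")
    if (!(object@mutant %in% g$genotype))
      msg <- c(msg, "mutant must be one of the genotype labels")
  }
  for (nm in c("retention", "crypticFraction")) {
    df <- slot(object, nm)
    fr <- if (nm == "retention") df$r else df$fraction
    if (nrow(df) && (any(fr < 0) || any(fr > 1)))
      msg <- c(msg, sprintf("%s fractions must lie in [0, 1]", nm))
  }
  if (any(object@enrichment <= 0))
    msg <- c(msg, "enrichment factors must be > 0")
  if (object@dispersion <= 0)
    msg <- c(msg, "dispersion must be > 0")
  if (length(object@libFactorRange) != 2L || any(object@libFactorRange <= 0))
    msg <- c(msg, "libFactorRange must be two positive numbers")
  if (object@sigmaLog < 0)
    msg <- c(msg, "sigmaLog must be >= 0")
  if (length(msg)) msg else TRUE
})
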