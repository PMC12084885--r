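#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GeneModel
#'
#' @param geneId,transcriptId identifiers.
#' @param chrom chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exonStarts,exonEnds integer vectors of exon bounds, 1-based closed
#'   (Bioconductor convention). Must describe sorted, non-overlapping exons
#'   separated by at least 1 nt.
#' @param intronClass `"major"` or `"minor"` per intron, in genomic order;
#'   recycled if length 1. Minor introns are the rare U12-type class; the
#'   label is assigned, never inferred.
#' @param seqlength optional contig length for the underlying `Seqinfo`.
#'
#' @return A [GeneModel-class] object.
#' @examples
#' gm <- geneModel("g1", "g1.t1", "chr2L", "+",
#'                 exonStarts = c(101, 401, 701),
#'                 exonEnds   = c(200, 500, 800),
#'                 intronClass = c("minor", "major"))
#' introns(gm)
#' @export
geneModel <- function(geneId, transcriptId = paste0(geneId, ".t1"),
                      chrom, strand, exonStarts, exonEnds,
                      intronClass = "major", seqlength = NA_integer_) {
  stopifnot(length(exonStarts) == length(exonEnds))
  si <- Seqinfo(seqnames = chrom, seqlengths = as.integer(seqlength))
  ex <- GRanges(chrom, IRanges(as.integer(exonStarts), as.integer(exonEnds)),
                strand = strand, seqinfo = si)
  nint <- max(length(ex) - 1L, 0L)
  if (nint == 0L) intronClass <- character()
  else if (length(intronClass) == 1L) intronClass <- rep(intronClass, nint)
  new("GeneModel", geneId = as.character(geneId),
      transcriptId = as.character(transcriptId),
      exons = ex, intronClass = as.character(intronClass))
}

#' Construct a GeneModelList
#'
#' @param ... [GeneModel-class] objects (or a single list of them).
#' @return A [GeneModelList-class], named by transcript id.
#' @export
GeneModelList <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is(args[[1]], "GeneModel"))
    args <- args[[1]]
  lapply(args, function(x) stopifnot(is(x, "GeneModel")))
  names(args) <- vapply(args, function(x) x@transcriptId, character(1))
  new("GeneModelList", listData = args)
}

#' @describeIn geneModel gene identifier accessor
#' @param x a `GeneModel`
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @describeIn geneModel transcript identifier accessor
#' @export
setMethod("transcriptId", "GeneModel", function(x) x@transcriptId)

#' @describeIn geneModel exon `GRanges` accessor
#' @export
setMethod("exons", "GeneModel", function(x, ...) x@exons)

setMethod("show", "GeneModel", function(object) {
  ex <- object@exons
  cat("GeneModel", object@geneId, "(", object@transcriptId, ")\n")
  cat(" ", as.character(seqnames(ex)[1L]), ":",
      min(start(ex)), "-", max(end(ex)),
      " (", as.character(strand(ex)[1L]), "), ",
      length(ex), " exon(s), ", max(length(ex) - 1L, 0L), " intron(s)",
      if (any(object@intronClass == "minor"))
        sprintf(" [%d minor]", sum(object@intronClass == "minor")) else "",
      "\n", sep = "")
})

#' Introns of a gene model
#'
#' Introns are the gaps between consecutive exons. The `intron_index`
#' metadata column numbers introns in transcription order (so index 1 is the
#' 5'-most intron of the transcript, which for a minus-strand gene lies at
#' the high-coordinate end), and `intron_class` carries the assigned
#' major/minor label.
#'
#' @param x a [GeneModel-class] (or [GeneModelList-class]).
#' @return A `GRanges` of introns (1-based closed) with metadata columns
#'   `gene_id`, `transcript_id`, `intron_index`, `intron_class`.
#' @export
setMethod("introns", "GeneModel", function(x, ...) {
  ex <- x@exons
  n <- length(ex)
  if (n < 2L) {
    gr <- GRanges(seqinfo = seqinfo(ex))
    mcols(gr) <- DataFrame(gene_id = character(), transcript_id = character(),
                           intron_index = integer(), intron_class = character())
    return(gr)
  }
  ir <- GRanges(seqnames(ex)[-1L],
                IRanges(end(ex)[-n] + 1L, start(ex)[-1L] - 1L),
                strand = strand(ex)[-1L], seqinfo = seqinfo(ex))
  minus <- as.character(strand(ex)[1L]) == "-"
  idx <- if (minus) rev(seq_len(n - 1L)) else seq_len(n - 1L)
  mcols(ir) <- DataFrame(gene_id = x@geneId, transcript_id = x@transcriptId,
                         intron_index = idx, intron_class = x@intronClass)
  ir
})

#' @rdname introns-GeneModel-method
#' @export
setMethod("introns", "GeneModelList", function(x, ...) {
  grs <- lapply(as.list(x), introns)
  suppressWarnings(do.call(c, unname(grs)))  # genes may live on distinct contigs
})

#' Splice sites of a gene model
#'
#' Each intron contributes a 5' (donor) and a 3' (acceptor) splice site.
#' Site kind is defined in transcript orientation: on the minus strand the
#' 5' site lies at the high-coordinate end of the intron. The reported
#' position is the intron-side base adjacent to the exon/intron junction
#' (the first intronic base of the intron for a 5' site on the plus strand).
#'
#' @param x a [GeneModel-class] or [GeneModelList-class].
#' @return A width-1 `GRanges` with metadata columns `gene_id`,
#'   `intron_index`, `intron_class`, `site_kind` (`"five_prime"` /
#'   `"three_prime"`).
#' @export
setMethod("spliceSites", "GeneModel", function(x, ...) {
  ir <- introns(x)
  if (!length(ir)) {
    gr <- GRanges(seqinfo = seqinfo(x@exons))
    mcols(gr) <- DataFrame(gene_id = character(), intron_index = integer(),
                           intron_class = character(), site_kind = character())
    return(gr)
  }
  minus <- as.character(strand(ir)[1L]) == "-"
  donor_pos <- if (minus) end(ir) else start(ir)
  accep_pos <- if (minus) start(ir) else end(ir)
  gr <- GRanges(rep(seqnames(ir), 2L),
                IRanges(c(donor_pos, accep_pos), width = 1L),
                strand = rep(strand(ir), 2L), seqinfo = seqinfo(ir))
  mcols(gr) <- DataFrame(
    gene_id = rep(mcols(ir)$gene_id, 2L),
    intron_index = rep(mcols(ir)$intron_index, 2L),
    intron_class = rep(mcols(ir)$intron_class, 2L),
    site_kind = rep(c("five_prime", "three_prime"), each = length(ir)))
  gr
})

#' @rdname spliceSites-GeneModel-method
#' @export
setMethod("spliceSites", "GeneModelList", function(x, ...) {
  suppressWarnings(do.call(c, unname(lapply(as.list(x), spliceSites))))
})

.windowsForModel <- function(x, w) {
  w <- as.integer(w)
  stopifnot(w >= 1L)
  ex <- x@exons
  ir <- introns(x)
  out <- GRanges(seqinfo = seqinfo(ex))
  mcols(out) <- DataFrame(gene_id = character(), intron_index = integer(),
                          intron_class = character(), site_kind = character(),
                          window_kind = character(), truncated = logical())
  if (!length(ir)) return(out)
  n <- length(ex)
  minus <- as.character(strand(ex)[1L]) == "-"
  # per genomic intron k (between exon k and exon k+1)
  rows <- vector("list", length(ir))
  for (k in seq_along(ir)) {
    a <- start(ir)[k]; b <- end(ir)[k]
    upstream_exon <- ex[k]; downstream_exon <- ex[k + 1L]
    # genomic-left junction windows: exonic [a-w, a-1], intronic [a, a+w-1]
    # genomic-right junction windows: intronic [b-w+1, b], exonic [b+1, b+w]
    left_ex <- c(max(start(upstream_exon), a - w), a - 1L)
    left_in <- c(a, min(b, a + w - 1L))
    right_in <- c(max(a, b - w + 1L), b)
    right_ex <- c(b + 1L, min(end(downstream_exon), b + w))
    starts <- c(left_ex[1L], left_in[1L], right_in[1L], right_ex[1L])
    ends <- c(left_ex[2L], left_in[2L], right_in[2L], right_ex[2L])
    trunc <- (ends - starts + 1L) < w
    # transcription-orientation labels: on '-' the donor is the right junction
    kinds <- if (minus) c("three_prime", "three_prime", "five_prime", "five_prime")
             else c("five_prime", "five_prime", "three_prime", "three_prime")
    gr <- GRanges(seqnames(ir)[k], IRanges(starts, ends),
                  strand = strand(ir)[k], seqinfo = seqinfo(ex))
    mcols(gr) <- DataFrame(
      gene_id = x@geneId,
      intron_index = mcols(ir)$intron_index[k],
      intron_class = mcols(ir)$intron_class[k],
      site_kind = kinds,
      window_kind = c("exonic", "intronic", "intronic", "exonic"),
      truncated = trunc)
    rows[[k]] <- gr
  }
  do.call(c, rows)
}

#' Boundary windows flanking each splice site
#'
#' For every intron, derives the four fixed-width windows used by the SSun
#' statistic: at each splice site, a `w`-nt exonic window inside the flanking
#' exon and a `w`-nt intronic window inside the intron, meeting at the
#' exon/intron junction. For a plus-strand intron spanning 0-based
#' half-open \[s, e), the 5' site has exonic window \[s-w, s) and intronic
#' window \[s, s+w), and the 3' site intronic \[e-w, e) and exonic
#' \[e, e+w); internally these are held as 1-based closed `GRanges`. On the minus strand the `site_kind` labels swap so that
#' `five_prime` always names the transcriptional donor. Windows that would
#' exceed the flanking exon or the intron are truncated to it and flagged
#' `truncated = TRUE`, never silently.
#'
#' @param x a [GeneModel-class] or [GeneModelList-class].
#' @param w window width in nt; default 40.
#' @param ... unused.
#' @return `GRanges` with metadata columns `gene_id`, `intron_index`,
#'   `intron_class`, `site_kind`, `window_kind` (`"exonic"`/`"intronic"`),
#'   `truncated`.
#' @seealso [computeSSun()], [exportWindowsBed()]
#' @export
setMethod("boundaryWindows", "GeneModel", function(x, w = 40L, ...)
  .windowsForModel(x, w))

#' @rdname boundaryWindows-GeneModel-method
#' @export
setMethod("boundaryWindows", "GeneModelList", function(x, w = 40L, ...)
  suppressWarnings(
    do.call(c, unname(lapply(as.list(x), .windowsForModel, w = w)))))

#' Write boundary windows as BED6
#'
#' The name field is `gene|intron_index|site_kind|window_kind`; a trailing
#' `|trunc` marks truncated windows. Coordinates convert to BED's 0-based
#' half-open convention on output.
#'
#' @param windows output of [boundaryWindows()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportWindowsBed <- function(windows, path) {
  nm <- with(as.data.frame(mcols(windows)),
             paste(gene_id, intron_index, site_kind, window_kind, sep = "|"))
  nm <- ifelse(mcols(windows)$truncated, paste0(nm, "|trunc"), nm)
  df <- data.frame(chrom = as.character(seqnames(windows)),
                   start = start(windows) - 1L, end = end(windows),
                   name = nm, score = 0L,
                   strand = as.character(strand(windows)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load gene models from GTF or BED12
#'
#' Reads transcript structures and returns one [GeneModel-class] per
#' transcript. GTF's 1-based closed exon coordinates and BED12's 0-based
#' half-open blocks both land in the same internal 1-based closed `GRanges`
#' representation, so downstream window arithmetic is dialect-independent.
#' Intron class labels are not present in either format; all introns are
#' loaded as `"major"` and relabelled from a registry or by
#' [setIntronClass()].
#'
#' @param path annotation file.
#' @param dialect `"auto"` (by file extension), `"GTF"`, or `"BED12"`.
#' @param geneIdFrom for GTF, the attribute naming the gene (default
#'   `"gene_id"`).
#' @return A [GeneModelList-class]. Transcripts whose exon chains violate the
#'   `GeneModel` contract (e.g. overlapping exons) are rejected with a
#'   message naming the transcript, not an error.
#' @export
loadGeneModels <- function(path, dialect = c("auto", "GTF", "BED12"),
                           geneIdFrom = "gene_id") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("gtf", "gff")) "GTF" else "BED12"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "GTF") "gtf" else "bed"),
    error = function(e)
      stop(sprintf("failed to parse '%s' as %s: %s", path, dialect,
                   conditionMessage(e)), call. = FALSE))
  out <- list()
  rejected <- character()
  if (dialect == "GTF") {
    gr <- gr[mcols(gr)$type == "exon"]
    if (!length(gr)) stop("no exon records in ", path)
    txs <- split(gr, mcols(gr)$transcript_id)
    for (tx in names(txs)) {
      e <- sort(txs[[tx]])
      gid <- as.character(mcols(e)[[geneIdFrom]][1L])
      gm <- tryCatch(
        geneModel(gid, tx, as.character(seqnames(e)[1L]),
                  as.character(strand(e)[1L]), start(e), end(e)),
        error = function(err) NULL)
      if (is.null(gm)) rejected <- c(rejected, tx) else out[[tx]] <- gm
    }
  } else {
    for (i in seq_along(gr)) {
      nm <- mcols(gr)$name[i]
      if (is.na(nm) || !nzchar(nm)) nm <- sprintf("record%d", i)
      bl <- mcols(gr)$blocks[[i]]  # relative to feature start
      es <- start(gr)[i] + start(bl) - 1L
      ee <- start(gr)[i] + end(bl) - 1L
      gm <- tryCatch(
        geneModel(nm, nm, as.character(seqnames(gr)[i]),
                  as.character(strand(gr)[i]), es, ee),
        error = function(err) NULL)
      if (is.null(gm)) rejected <- c(rejected, nm) else out[[nm]] <- gm
    }
  }
  if (length(rejected))
    message("rejected ", length(rejected), " malformed transcript(s): ",
            paste(utils::head(rejected, 5L), collapse = ", "))
  GeneModelList(out)
}

#' Relabel introns of a gene model
#'
#' @param x a [GeneModel-class].
#' @param index intron index in transcription order.
#' @param class `"minor"` or `"major"`.
#' @return the modified `GeneModel`.
#' @export
setIntronClass <- function(x, index, class = "minor") {
  stopifnot(is(x, "GeneModel"), class %in% c("major", "minor"))
  ir <- introns(x)
  pos <- match(as.integer(index), mcols(ir)$intron_index)
  if (anyNA(pos)) stop("no intron with index ", index, " in ", x@geneId)
  # intronClass slot is stored in genomic order
  genomic_pos <- order(start(ir))[pos]
  x@intronClass[genomic_pos] <- class
  validObject(x)
  x
}

#' Write gene models to BED12
#'
#' @param x a [GeneModelList-class] (or single [GeneModel-class]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModelsBed <- function(x, path) {
  if (is(x, "GeneModel")) x <- GeneModelList(x)
  grl <- GRangesList(lapply(as.list(x), function(gm) gm@exons))
  names(grl) <- vapply(as.list(x), transcriptId, character(1))
  rtracklayer::export(grl, path, format = "bed")
  invisible(path)
}

.registryFile <- function(name) {
  p <- system.file("extdata", name, package = "minorsplice", mustWork = FALSE)
  if (!nzchar(p)) p <- file.path("inst", "extdata", name)  # during development
  if (!file.exists(p)) stop("registry file not found: ", name)
  p
}

#' Packaged minor-intron registry
#'
#' The registry lists the known minor (U12-type) introns per species by host
#' gene symbol. Genomic coordinates are not bundled (they depend on the
#' annotation release the user aligns against) and are supplied by the user;
#' entries without a curated gene symbol are placeholders flagged
#' `coordinates_unknown`, so the census is complete even where the per-entry
#' metadata is not.
#'
#' @param species registry key, e.g. `"Dmel"`.
#' @return data.frame with columns `species`, `gene_symbol`, `chrom`,
#'   `start`, `end`, `strand`, `intron_class`, `source_flag`.
#' @export
minorIntronRegistry <- function(species = "Dmel") {
  reg <- utils::read.delim(.registryFile("minor_introns.tsv"),
                           stringsAsFactors = FALSE)
  if (!species %in% reg$species)
    stop("unknown species '", species, "'; available: ",
         paste(unique(reg$species), collapse = ", "))
  reg[reg$species == species, , drop = FALSE]
}

#' Minor-intron census for a species
#'
#' @param species registry key, e.g. `"Dmel"` (Drosophila melanogaster,
#'   whose genome contains 19 minor introns).
#' @return integer count of minor-intron registry entries.
#' @export
minorIntronCensus <- function(species = "Dmel") {
  nrow(minorIntronRegistry(species))
}

#' Packaged snRNA registry
#'
#' Annotated lengths and spliceosome membership of the spliceosomal snRNAs
#' (major: U1, U2, U4, U5, U6; minor: U11, U12, U4atac, U6atac; U5 is shared)
#' for human and Drosophila. U11 and U12 diverge strongly between species:
#' the Drosophila snRNAs (275 and 238 nt) are much longer than their human
#' counterparts (135 and 150 nt).
#'
#' @param species optional registry key to filter by.
#' @return data.frame with columns `species`, `snrna`, `length_nt`,
#'   `spliceosome`.
#' @export
snRNARegistry <- function(species = NULL) {
  reg <- utils::read.delim(.registryFile("snrna_registry.tsv"),
                           stringsAsFactors = FALSE)
  if (!is.null(species)) {
    if (!species %in% reg$species)
      stop("unknown species '", species, "'; available: ",
           paste(unique(reg$species), collapse = ", "))
    reg <- reg[reg$species == species, , drop = FALSE]
  }
  reg
}

#' Length of a registered snRNA
#'
#' @param species registry key (`"Dmel"`, `"Hsap"`).
#' @param snrna snRNA name, e.g. `"U11"`.
#' @return annotated length in nt (integer).
#' @export
snRNALength <- function(species, snrna) {
  reg <- snRNARegistry(species)
  i <- match(snrna, reg$snrna)
  if (is.na(i)) stop("no snRNA '", snrna, "' registered for ", species)
  as.integer(reg$length_nt[i])
}
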