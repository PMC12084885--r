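#' @include AllClasses.R
NULL

#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @export
setGeneric("exons", function(x, ...) standardGeneric("exons"))

#' @export
setGeneric("introns", function(x, ...) standardGeneric("introns"))

#' @export
setGeneric("spliceSites", function(x, ...) standardGeneric("spliceSites"))

#' @export
setGeneric("boundaryWindows", function(x, w = 40L, ...)
  standardGeneric("boundaryWindows"))

#' @export
setGeneric("readBlocks", function(x) standardGeneric("readBlocks"))

#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))
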