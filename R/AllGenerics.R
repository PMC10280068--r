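#' @rdname accessors
#' @export
setGeneric("haplotypeTable", function(x) standardGeneric("haplotypeTable"))

#' @rdname accessors
#' @export
setGeneric("haplotypeAlignment", function(x) standardGeneric("haplotypeAlignment"))

#' @rdname accessors
#' @export
setGeneric("alignmentAnchor", function(x) standardGeneric("alignmentAnchor"))

#' @rdname accessors
#' @export
setGeneric("validHaplotypes", function(x) standardGeneric("validHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("haplotypeMode", function(x) standardGeneric("haplotypeMode"))

#' @rdname accessors
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @rdname accessors
#' @export
setGeneric("exonIntervals", function(x) standardGeneric("exonIntervals"))

#' @rdname accessors
#' @export
setGeneric("readingFrame", function(x) standardGeneric("readingFrame"))

#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' @rdname accessors
#' @export
setGeneric("truthHaplotypes", function(x) standardGeneric("truthHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' Accessors for ighap S4 objects
#'
#' Read-only accessors for [GeneModel-class], [TruthTable-class] and
#' [HaplotypeSet-class] slots.
#'
#' @param x an ighap S4 object.
#' @return The slot content: a `data.frame` for tables, character vectors for
#'   alignments and sequences, scalars otherwise.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("haplotypeTable", "HaplotypeSet", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("haplotypeAlignment", "HaplotypeSet", function(x) {
  a <- x@alignment
  names(a) <- x@entries$id
  a
})

#' @rdname accessors
#' @export
setMethod("alignmentAnchor", "HaplotypeSet", function(x) x@referenceRow)

#' @rdname accessors
#' @export
setMethod("validHaplotypes", "HaplotypeSet", function(x) {
  x@entries[x@entries$valid, , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("haplotypeMode", "HaplotypeSet", function(x) x@mode)

#' @rdname accessors
#' @export
setMethod("geneFeatures", "GeneModel", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("exonIntervals", "GeneModel", function(x) {
  f <- x@features
  f[f$kind == "exon", c("start", "end"), drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("readingFrame", "GeneModel", function(x) x@frame)

#' @rdname accessors
#' @export
setMethod("locusId", "GeneModel", function(x) x@locusId)

#' @rdname accessors
#' @export
setMethod("truthHaplotypes", "TruthTable", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setMethod("truthEvents", "TruthTable", function(x) x@events)
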