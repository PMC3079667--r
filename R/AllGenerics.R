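## Accessor generics and show methods.

#' @describeIn ReferenceSequence identifier of the reference record
#' @param object,x a pipeline object
#' @export
setGeneric("refId", function(object) standardGeneric("refId"))
#' @describeIn ReferenceSequence nucleotide string
#' @export
setGeneric("refBases", function(object) standardGeneric("refBases"))
#' @describeIn AmpliconPanel amplicon table (one row per amplicon)
#' @export
setGeneric("ampliconTable", function(object) standardGeneric("ampliconTable"))
#' @describeIn ExperimentDesign sample table
#' @export
setGeneric("designSamples", function(object) standardGeneric("designSamples"))
#' @describeIn ExperimentDesign MID table
#' @export
setGeneric("designMids", function(object) standardGeneric("designMids"))
#' @describeIn SimulatedRun read sequences (named character vector)
#' @export
setGeneric("simReads", function(object) standardGeneric("simReads"))
#' @describeIn SimulatedRun per-read provenance table
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @describeIn SimulatedRun planted-variant truth table
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @describeIn DemuxResult per-read assignment table
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))
#' @describeIn AmpliconPileup strand-resolved base counts
#' @export
setGeneric("baseCounts", function(object) standardGeneric("baseCounts"))
#' @describeIn VariantCallSet all candidate variants with filter state
#' @export
setGeneric("variantTable", function(object) standardGeneric("variantTable"))
#' @describeIn VariantCallSet validated variants only
#' @export
setGeneric("validatedVariants",
           function(object) standardGeneric("validatedVariants"))
#' @describeIn VariantCallSet per-(variant, sample) evidence
#' @export
setGeneric("variantEvidence",
           function(object) standardGeneric("variantEvidence"))
#' @describeIn VariantCallSet survivor counts along the cascade
#' @export
setGeneric("filterTrace", function(object) standardGeneric("filterTrace"))

#' @rdname ReferenceSequence-class
#' @export
setMethod("refId", "ReferenceSequence", function(object) object@id)
#' @rdname ReferenceSequence-class
#' @export
setMethod("refBases", "ReferenceSequence", function(object) object@bases)
#' @rdname ReferenceSequence-class
#' @export
setMethod("length", "ReferenceSequence", function(x) nchar(x@bases))
#' @rdname AmpliconPanel-class
#' @export
setMethod("refId", "AmpliconPanel", function(object) object@reference@id)
#' @rdname AmpliconPanel-class
#' @export
setMethod("refBases", "AmpliconPanel", function(object) object@reference@bases)
#' @rdname AmpliconPanel-class
#' @export
setMethod("ampliconTable", "AmpliconPanel", function(object) object@amplicons)
#' @rdname ExperimentDesign-class
#' @export
setMethod("ampliconTable", "ExperimentDesign",
          function(object) object@panel@amplicons)
#' @rdname ExperimentDesign-class
#' @export
setMethod("designSamples", "ExperimentDesign", function(object) object@samples)
#' @rdname ExperimentDesign-class
#' @export
setMethod("designMids", "ExperimentDesign", function(object) object@mids)
#' @rdname SimulatedRun-class
#' @export
setMethod("simReads", "SimulatedRun", function(object) object@reads)
#' @rdname SimulatedRun-class
#' @export
setMethod("provenance", "SimulatedRun", function(object) object@provenance)
#' @rdname SimulatedRun-class
#' @export
setMethod("groundTruth", "SimulatedRun", function(object) object@truth)
#' @rdname DemuxResult-class
#' @export
setMethod("assignments", "DemuxResult", function(object) object@assignments)
#' @rdname AmpliconPileup-class
#' @export
setMethod("baseCounts", "AmpliconPileup", function(object) object@baseCounts)
#' @rdname VariantCallSet-class
#' @export
setMethod("variantTable", "VariantCallSet", function(object) object@variants)
#' @rdname VariantCallSet-class
#' @export
setMethod("validatedVariants", "VariantCallSet", function(object)
  object@variants[object@variants$validated, , drop = FALSE])
#' @rdname VariantCallSet-class
#' @export
setMethod("variantEvidence", "VariantCallSet", function(object)
  object@evidence)
#' @rdname VariantCallSet-class
#' @export
setMethod("filterTrace", "VariantCallSet", function(object) object@trace)

setMethod("show", "ReferenceSequence", function(object) {
  cat(sprintf("ReferenceSequence %s: %d bp\n", object@id, length(object)))
})

setMethod("show", "AmpliconPanel", function(object) {
  a <- object@amplicons
  cat(sprintf("AmpliconPanel on %s (%d bp): %d amplicons, %d regions, %d insert bp\n",
              refId(object), length(object@reference), nrow(a),
              length(unique(a$region)), sum(a$insert_length)))
})

setMethod("show", "ExperimentDesign", function(object) {
  s <- object@samples
  cat(sprintf(
    "ExperimentDesign: %d samples in %d groups, %d amplicons (%d reactions)\n",
    nrow(s), length(unique(s$group_id)), nrow(object@panel@amplicons),
    nrow(s) * nrow(object@panel@amplicons)))
})

setMethod("show", "SimulatedRun", function(object) {
  cat(sprintf("SimulatedRun: %d reads, %d planted variants, %d groups\n",
              length(object@reads), nrow(object@truth),
              length(unique(object@groups))))
})

setMethod("show", "DemuxResult", function(object) {
  a <- object@assignments
  n <- nrow(a); k <- sum(a$status == "assigned")
  cat(sprintf("DemuxResult: %d/%d reads assigned (%.1f%%)\n",
              k, n, if (n) 100 * k / n else 0))
})

setMethod("show", "AmpliconPileup", function(object) {
  cat(sprintf("AmpliconPileup: %d (sample, amplicon, pos, strand) keys; %s\n",
              nrow(object@baseCounts),
              paste(names(object@qc), unlist(object@qc),
                    sep = "=", collapse = ", ")))
})

setMethod("show", "VariantCallSet", function(object) {
  v <- object@variants
  cat(sprintf("VariantCallSet: %d candidates, %d validated\n",
              nrow(v), sum(v$validated)))
  tr <- object@trace
  cat(paste(sprintf("  %-18s %d", tr$stage, tr$n), collapse = "\n"), "\n")
})
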