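## S4 classes for the pipeline's central objects.

#' ReferenceSequence: a validated nucleotide reference
#'
#' Holds the (linearized) circular mitochondrial reference the amplicon
#' panel is defined on.  Only unambiguous bases are accepted: calling and
#' artifact flagging reason about exact base identity, so IUPAC ambiguity
#' codes are rejected at load time.
#'
#' @slot id single text identifier (FASTA record name)
#' @slot bases nucleotide string over A, C, G, T
#' @export
setClass("ReferenceSequence",
         representation(id = "character", bases = "character"))

setValidity("ReferenceSequence", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("id must be a single non-empty string")
  if (length(object@bases) != 1L || nchar(object@bases) == 0L)
    return("reference has no bases")
  bad <- regexpr("[^ACGT]", object@bases)
  if (bad > 0L)
    return(sprintf("non-ACGT character '%s' at position %d",
                   substr(object@bases, bad, bad), bad))
  TRUE
})

#' AmpliconPanel: the target amplicons over a reference
#'
#' The panel lists each amplicon's 1-based insert coordinates on the
#' reference (excluding primer binding sites, so per-base SNP densities use
#' the sequenced insert length) together with its primer pair.  The insert
#' sequence is materialized from the reference at construction.
#'
#' @slot reference a [ReferenceSequence-class]
#' @slot amplicons data.frame with columns index, region, fwd_primer,
#'   rev_primer, ref_start, ref_end, insert_length, insert_seq
#' @export
setClass("AmpliconPanel",
         representation(reference = "ReferenceSequence",
                        amplicons = "data.frame"))

setValidity("AmpliconPanel", function(object) {
  a <- object@amplicons
  need <- c("index", "region", "fwd_primer", "rev_primer",
            "ref_start", "ref_end", "insert_length", "insert_seq")
  if (!all(need %in% names(a)))
    return(paste("missing amplicon columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (anyDuplicated(a$index)) return("duplicate amplicon index")
  if (any(a$ref_end < a$ref_start)) return("ref_end < ref_start")
  if (any(a$ref_start < 1L) || any(a$ref_end > nchar(object@reference@bases)))
    return("amplicon coordinates outside the reference")
  if (any(a$insert_length != a$ref_end - a$ref_start + 1L))
    return("insert_length does not match coordinates")
  if (any(a$insert_seq != substring(object@reference@bases,
                                    a$ref_start, a$ref_end)))
    return("insert_seq inconsistent with reference")
  TRUE
})

#' ExperimentDesign: groups, samples and their MID pairs
#'
#' Maps each sample to its sequencing group (plate region) and its
#' (forward MID, reverse MID) pair.  MID pairs must be unique within a
#' group - that is the traceability contract; reuse of the same pair across
#' groups is allowed because groups are sequenced in separate plate
#' regions.  Each role set of MIDs must be pairwise at edit distance >= 5
#' so that decoding with up to 2 errors is unambiguous.
#'
#' @slot panel an [AmpliconPanel-class]
#' @slot samples data.frame with columns sample_id, species, location_id,
#'   group_id, fwd_mid, rev_mid
#' @slot mids data.frame with columns id, role ("forward"/"reverse"),
#'   sequence (10 bp)
#' @export
setClass("ExperimentDesign",
         representation(panel = "AmpliconPanel",
                        samples = "data.frame",
                        mids = "data.frame"))

setValidity("ExperimentDesign", function(object) {
  m <- object@mids
  s <- object@samples
  if (!all(c("id", "role", "sequence") %in% names(m)))
    return("mids must have columns id, role, sequence")
  if (!all(m$role %in% c("forward", "reverse")))
    return("MID role must be 'forward' or 'reverse'")
  if (any(nchar(m$sequence) != 10L)) return("MID sequences must be 10 bp")
  for (r in c("forward", "reverse")) {
    msg <- .checkMidDistances(m$sequence[m$role == r], min_distance = 5L)
    if (!isTRUE(msg)) return(sprintf("%s MID set: %s", r, msg))
  }
  need <- c("sample_id", "species", "location_id", "group_id",
            "fwd_mid", "rev_mid")
  if (!all(need %in% names(s)))
    return(paste("missing sample columns:",
                 paste(setdiff(need, names(s)), collapse = ", ")))
  if (anyDuplicated(s$sample_id)) return("duplicate sample_id")
  if (!all(s$fwd_mid %in% m$id[m$role == "forward"]))
    return("unknown forward MID id in sample sheet")
  if (!all(s$rev_mid %in% m$id[m$role == "reverse"]))
    return("unknown reverse MID id in sample sheet")
  key <- paste(s$group_id, s$fwd_mid, s$rev_mid)
  if (anyDuplicated(key))
    return("duplicate (group, fwd_mid, rev_mid) - traceability would be lost")
  sizes <- table(s$group_id)
  if (any(sizes > 36L)) return("a group holds more than 36 samples")
  TRUE
})

#' SimulatedRun: reads plus their ground truth
#'
#' Output of [simulateReads()].  Every emitted read has exactly one
#' provenance record naming the sample, amplicon, strand and the errors
#' applied to it, so downstream assignments can be audited exhaustively.
#'
#' @slot reads named character vector of read sequences
#' @slot groups integer vector, the plate region (group) each read was
#'   sequenced in - physically known from the gasket, not inferred
#' @slot provenance data.frame keyed by read_id
#' @slot truth data.frame of planted variants (see [simulateHaplotypes()])
#' @slot models list with the coverage and error models used
#' @export
setClass("SimulatedRun",
         representation(reads = "character", groups = "integer",
                        provenance = "data.frame", truth = "data.frame",
                        models = "list"))

setValidity("SimulatedRun", function(object) {
  if (length(object@reads) != nrow(object@provenance))
    return("each read must have exactly one provenance record")
  if (length(object@reads) != length(object@groups))
    return("groups must parallel reads")
  if (!identical(names(object@reads), object@provenance$read_id))
    return("provenance order must match reads")
  TRUE
})

#' DemuxResult: per-read assignment outcomes
#'
#' One row per input read with either an assignment (sample, amplicon,
#' strand, trimmed reference-oriented insert) or an unassignment reason
#' code; the reason codes partition the input.
#'
#' @slot assignments data.frame, one row per read
#' @export
setClass("DemuxResult", representation(assignments = "data.frame"))

#' AmpliconPileup: per-individual, per-strand allele counts
#'
#' Base counts are keyed by (sample, amplicon, reference position, strand);
#' the depth column counts every read whose alignment spans the position
#' (including reads deleting it).  Deletion and insertion events are kept
#' in separate ledgers keyed by their left-normalized anchor so identical
#' events from different reads aggregate at one canonical position.
#'
#' @slot baseCounts data.frame: sample_id, amplicon, pos, strand,
#'   A, C, G, T, del, depth
#' @slot deletions data.frame: sample_id, amplicon, pos, len, strand, count
#' @slot insertions data.frame: sample_id, amplicon, pos, seq, strand, count
#' @slot qc list of alignment QC counters
#' @export
setClass("AmpliconPileup",
         representation(baseCounts = "data.frame", deletions = "data.frame",
                        insertions = "data.frame", qc = "list"))

#' VariantCallSet: candidates, evidence and the filter cascade outcome
#'
#' @slot variants data.frame, one row per candidate (position, alleles,
#'   kind, artifact flags, validation state, classification)
#' @slot evidence data.frame, one row per (variant, sample) with
#'   strand-resolved supporting reads and covering depth
#' @slot trace data.frame of survivor counts after each cascade stage
#' @slot thresholds the [filterThresholds()] used
#' @export
setClass("VariantCallSet",
         representation(variants = "data.frame", evidence = "data.frame",
                        trace = "data.frame", thresholds = "list"))
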