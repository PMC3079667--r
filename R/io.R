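## Reference, panel, MID and sample-sheet I/O.

#' Load the reference sequence from a single-record FASTA
#'
#' The circular mitochondrial genome is treated as a linear sequence (no
#' panel amplicon spans the origin).  Lowercase input is normalized to
#' uppercase; ambiguity codes are rejected because every downstream filter
#' reasons about exact base identity.
#'
#' @param path FASTA file with exactly one record
#' @return a [ReferenceSequence-class]
#' @export
loadReference <- function(path) {
  rec <- Biostrings::readDNAStringSet(path)
  if (length(rec) == 0L) stop("empty reference file: ", path)
  if (length(rec) > 1L)
    stop("multi-record reference: expected exactly one record, found ",
         length(rec))
  bases <- toupper(as.character(rec[[1L]]))
  bad <- regexpr("[^ACGT]", bases)
  if (bad > 0L)
    stop(sprintf("reference contains non-ACGT character '%s' at position %d",
                 substr(bases, bad, bad), bad))
  id <- sub("\\s.*$", "", names(rec)[1L])
  new("ReferenceSequence", id = id, bases = bases)
}

#' Load an amplicon panel definition
#'
#' Reads a tab-separated panel config (one row per amplicon: index, region,
#' fwd_primer, rev_primer, ref_start, ref_end, insert_length) and validates
#' every amplicon against the supplied reference.  Coordinates are 1-based
#' inclusive and delimit the insert excluding primer binding sites.
#'
#' @param path TSV file
#' @param reference a [ReferenceSequence-class]
#' @return an [AmpliconPanel-class]
#' @export
loadPanel <- function(path, reference) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("index", "region", "fwd_primer", "rev_primer",
            "ref_start", "ref_end", "insert_length")
  if (!all(need %in% names(a)))
    stop("panel file missing columns: ",
         paste(setdiff(need, names(a)), collapse = ", "))
  if (anyDuplicated(a$index)) stop("duplicate amplicon index in panel")
  if (any(a$ref_end < a$ref_start)) stop("panel has ref_end < ref_start")
  if (any(a$ref_start < 1L) || any(a$ref_end > length(reference)))
    stop("panel coordinate out of reference range")
  if (any(a$insert_length != a$ref_end - a$ref_start + 1L))
    stop("insert_length mismatch with coordinates")
  a$insert_seq <- substring(refBases(reference), a$ref_start, a$ref_end)
  a <- a[order(a$index), , drop = FALSE]
  rownames(a) <- NULL
  new("AmpliconPanel", reference = reference, amplicons = a)
}

#' Write a panel definition back to TSV
#'
#' Inverse of [loadPanel()]: writing and re-reading yields an identical
#' panel.
#'
#' @param panel an [AmpliconPanel-class]
#' @param path output TSV path
#' @export
writePanel <- function(panel, path) {
  a <- ampliconTable(panel)
  write.table(a[, c("index", "region", "fwd_primer", "rev_primer",
                    "ref_start", "ref_end", "insert_length")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load MID tag definitions
#'
#' Reads a TSV with columns id, role ("forward"/"reverse"), sequence and
#' validates each role set with [validateMidSet()].
#'
#' @param path TSV file
#' @return data.frame of tags
#' @export
loadMids <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "role", "sequence") %in% names(m)))
    stop("MID file must have columns id, role, sequence")
  m$sequence <- toupper(m$sequence)
  for (r in unique(m$role)) validateMidSet(m$sequence[m$role == r])
  m
}

#' Load a sample sheet and assemble the experiment design
#'
#' The sheet maps each sample to its group (plate region) and MID pair.
#' Per-group MID-pair uniqueness and group size are enforced; reuse of a
#' MID pair across groups is legitimate and accepted.
#'
#' @param path TSV with columns sample_id, species, location_id, group_id,
#'   fwd_mid, rev_mid
#' @param panel an [AmpliconPanel-class]
#' @param mids MID table from [loadMids()]
#' @return an [ExperimentDesign-class]
#' @export
loadSampleSheet <- function(path, panel, mids) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "location_id", "group_id",
            "fwd_mid", "rev_mid")
  if (!all(need %in% names(s)))
    stop("sample sheet missing columns: ",
         paste(setdiff(need, names(s)), collapse = ", "))
  s$group_id <- as.integer(s$group_id)
  new("ExperimentDesign", panel = panel, samples = s, mids = mids)
}

#' Enumerate PCR reactions implied by a design
#'
#' One reaction per (sample, amplicon) pair, optionally restricted to one
#' species (the full design may carry placeholder samples of other species
#' that are sequenced but excluded from analysis).
#'
#' @param design an [ExperimentDesign-class]
#' @param species optional species filter (exact match)
#' @return data.frame with columns sample_id, group_id, amplicon; the
#'   reaction count is `nrow()` of the result
#' @export
enumerateReactions <- function(design, species = NULL) {
  s <- designSamples(design)
  if (!is.null(species)) s <- s[s$species == species, , drop = FALSE]
  a <- ampliconTable(design)
  out <- expand.grid(sample_id = s$sample_id, amplicon = a$index,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$group_id <- s$group_id[match(out$sample_id, s$sample_id)]
  out[, c("sample_id", "group_id", "amplicon")]
}

#' Subset an experiment design for desk-scale runs
#'
#' Restricts a design to selected groups, the first `samples_per_group`
#' samples of each group, and/or selected amplicons.  Useful for
#' simulation studies at a fraction of the full plate layout.
#'
#' @param design an [ExperimentDesign-class]
#' @param groups group ids to keep (default all)
#' @param samples_per_group samples kept per group (default all)
#' @param amplicons amplicon indices to keep (default all)
#' @return an [ExperimentDesign-class]
#' @export
subsetDesign <- function(design, groups = NULL, samples_per_group = NULL,
                         amplicons = NULL) {
  s <- designSamples(design)
  if (!is.null(groups)) s <- s[s$group_id %in% groups, , drop = FALSE]
  if (!is.null(samples_per_group)) {
    s <- do.call(rbind, lapply(split(s, s$group_id), function(gg)
      utils::head(gg, samples_per_group)))
    rownames(s) <- NULL
  }
  a <- ampliconTable(design)
  if (!is.null(amplicons)) a <- a[a$index %in% amplicons, , drop = FALSE]
  panel <- new("AmpliconPanel", reference = design@panel@reference,
               amplicons = a)
  new("ExperimentDesign", panel = panel, samples = s,
      mids = designMids(design))
}

#' Path to a packaged example fixture
#'
#' @param file file name under the package's `extdata` (empty to list)
#' @return full path
#' @export
ampliSNPExample <- function(file = "") {
  system.file("extdata", file, package = "ampliSNP", mustWork = nzchar(file))
}
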