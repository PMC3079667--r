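## Small shared helpers.

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of ACGT sequences
#' @return character vector of the same length
#' @export
revComp <- function(x) {
  if (!length(x)) return(character(0))
  vapply(chartr("ACGTacgt", "TGCAtgca", x),
         function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

## pairwise edit distances for a MID role set; TRUE or a message
.checkMidDistances <- function(seqs, min_distance = 5L) {
  if (length(seqs) < 2L) return(TRUE)
  d <- utils::adist(seqs)
  dd <- d[upper.tri(d)]
  if (min(dd) < min_distance)
    return(sprintf("minimum pairwise edit distance %d < %d (ambiguous decoding)",
                   min(dd), min_distance))
  TRUE
}

#' Validate a MID tag set
#'
#' Checks that every tag is a 10-bp ACGT sequence and that the set is
#' pairwise at edit distance >= `min_distance`, the property that makes
#' decoding with up to 2 errors unambiguous.
#'
#' @param sequences character vector of tag sequences
#' @param min_distance minimum pairwise edit distance (default 5)
#' @return invisibly `TRUE`; errors otherwise
#' @export
validateMidSet <- function(sequences, min_distance = 5L) {
  if (!length(sequences)) stop("empty MID set")
  if (any(nchar(sequences) != 10L)) stop("MID sequences must be exactly 10 bp")
  if (any(grepl("[^ACGT]", sequences))) stop("MID sequences must be ACGT only")
  msg <- .checkMidDistances(sequences, min_distance)
  if (!isTRUE(msg)) stop(msg)
  invisible(TRUE)
}

## left-normalize a deletion of ref[start..start+len-1] (local coordinates
## on `ref`); identical events then aggregate at one canonical anchor
.leftNormalizeDeletion <- function(ref, start, len) {
  while (start > 1L &&
         substr(ref, start - 1L, start - 1L) ==
         substr(ref, start + len - 1L, start + len - 1L)) {
    start <- start - 1L
  }
  start
}

## left-normalize an insertion of `seq` after ref position `pos` (local);
## rotates the inserted sequence while it can slide left over the reference
.leftNormalizeInsertion <- function(ref, pos, seq) {
  while (pos >= 1L &&
         substr(ref, pos, pos) == substr(seq, nchar(seq), nchar(seq))) {
    seq <- paste0(substr(seq, nchar(seq), nchar(seq)),
                  substr(seq, 1L, nchar(seq) - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

## length of the homopolymer run of `ref` containing local position `pos`
.runLengthAt <- function(ref, pos) {
  b <- substr(ref, pos, pos)
  l <- pos
  while (l > 1L && substr(ref, l - 1L, l - 1L) == b) l <- l - 1L
  r <- pos
  n <- nchar(ref)
  while (r < n && substr(ref, r + 1L, r + 1L) == b) r <- r + 1L
  r - l + 1L
}
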