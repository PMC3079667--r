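## Semi-global alignment of trimmed inserts against reference amplicons.

#' Alignment scoring parameters
#'
#' Defaults: match +1, mismatch -1, gap open -2, gap extend -1 (a gap of
#' length L costs 2 + (L - 1)), free end-gaps on the reference side so a
#' truncated read aligns to a contiguous stretch of its amplicon.  Reads
#' whose alignment identity falls below `min_identity` are excluded from
#' the pileup and tallied in its QC ledger; reads longer than
#' `max_length_ratio` times the amplicon are flagged unalignable.
#'
#' @param match,mismatch per-base scores
#' @param gap_open,gap_extend gap penalties (positive magnitudes)
#' @param min_identity minimum fraction of match columns (default 0.70)
#' @param max_length_ratio insert/amplicon length ratio limit (default 2)
#' @return list of parameters
#' @export
alignParams <- function(match = 1, mismatch = -1, gap_open = 2,
                        gap_extend = 1, min_identity = 0.70,
                        max_length_ratio = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            min_identity >= 0, min_identity <= 1, max_length_ratio > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity,
                 max_length_ratio = max_length_ratio),
            class = "alignParams")
}

#' Align an insert to a reference amplicon sequence
#'
#' Optimal semi-global dynamic-programming alignment: the insert is
#' consumed in full, unaligned reference ends are free.  Tie-breaking is
#' deterministic (match/mismatch preferred over deletion over insertion,
#' leftmost end column), so the alignment of a given input never varies.
#'
#' @param insert trimmed, reference-oriented read sequence
#' @param ref amplicon insert sequence (local coordinates start at 1)
#' @param params an [alignParams()] list
#' @return list with `score`, `identity`, `ref_start`, `ref_end`, and an
#'   `ops` data.frame (`op` in M/X/D/I, `rpos` local reference position -
#'   for insertions the position the inserted base follows - and `qpos`
#'   read position, 0 for deletions); or `list(unalignable = TRUE)` when
#'   the insert exceeds the length-ratio limit
#' @export
alignRead <- function(insert, ref, params = alignParams()) {
  if (!nzchar(insert)) stop("empty insert")
  if (nchar(insert) > params$max_length_ratio * nchar(ref))
    return(list(unalignable = TRUE))
  al <- cpp_glocal_align(insert, ref, params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
  ops <- c("M", "X", "D", "I")[al$op + 1L]
  list(score = al$score,
       identity = if (length(ops)) sum(ops == "M") / length(ops) else 0,
       ref_start = al$ref_start, ref_end = al$ref_end,
       ops = data.frame(op = ops, rpos = al$rpos, qpos = al$qpos,
                        stringsAsFactors = FALSE))
}
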