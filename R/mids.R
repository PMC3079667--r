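## Error-correcting MID decoding.

## internal scan: returns list(id, errors, end) on a unique best hit,
## or a status string "tie" / "none"
.midScan <- function(window, tags, max_errors = 2L) {
  hits <- vapply(tags, function(tg) cpp_prefix_edit(tg, window),
                 integer(2))
  d <- hits[1L, ]
  best <- min(d)
  if (best > max_errors) return("none")
  which_best <- which(d == best)
  if (length(which_best) > 1L) return("tie")
  list(id = names(tags)[which_best], errors = best,
       end = hits[2L, which_best])
}

#' Decode a terminal window against a MID tag set
#'
#' Finds the tag at minimum edit distance from a prefix of `window`
#' (indels are the dominant pyrosequencing error, so Levenshtein distance
#' is used rather than Hamming).  A unique minimum at distance
#' `<= max_errors` is a match; a tie or all distances above the limit
#' yields no match - the tag sets are designed with pairwise distance >= 5,
#' so a tie indicates at least 3 errors and the read is not trusted.
#'
#' @param window observed terminal subsequence (at least the MID length)
#' @param tags named character vector of tag sequences
#' @param max_errors maximum edit operations tolerated (default 2)
#' @return list with `id`, `errors`, `end` (bases of the window consumed by
#'   the tag), or `NULL` when there is no unambiguous match
#' @export
matchMid <- function(window, tags, max_errors = 2L) {
  if (!length(tags)) stop("empty tag set")
  if (is.null(names(tags)) || any(!nzchar(names(tags))))
    stop("tags must be named")
  res <- .midScan(window, tags, max_errors)
  if (is.character(res)) NULL else res
}
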