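## Read-to-sample assignment via both terminal MIDs, amplicon routing via
## primers, and tag/primer trimming.

.MID_LEN <- 10L
.MID_WINDOW <- 12L   # MID length + 2, tolerates terminal indels

## forward/reverse tag vectors for a design
.fwdTags <- function(design) {
  m <- designMids(design)
  setNames(m$sequence[m$role == "forward"], m$id[m$role == "forward"])
}
.revTags <- function(design) {
  m <- designMids(design)
  setNames(m$sequence[m$role == "reverse"], m$id[m$role == "reverse"])
}

## scan one read orientation for both MIDs
.scanOrientation <- function(seq, fwd_tags, rev_tags, max_errors) {
  n <- nchar(seq)
  if (n < 2L * .MID_WINDOW + 1L)
    return(list(status = "missing-MID"))
  head_w <- substr(seq, 1L, .MID_WINDOW)
  tail_w <- revComp(substr(seq, n - .MID_WINDOW + 1L, n))
  m5 <- .midScan(head_w, fwd_tags, max_errors)
  m3 <- .midScan(tail_w, rev_tags, max_errors)
  if (is.list(m5) && is.list(m3))
    return(list(status = "ok", m5 = m5, m3 = m3))
  st <- c(if (is.character(m5)) m5 else "ok",
          if (is.character(m3)) m3 else "ok")
  if ("tie" %in% st) list(status = "ambiguous-MID")
  else list(status = "missing-MID")
}

#' Route a tag-trimmed read to its amplicon by primer matching
#'
#' All amplicons of the panel co-occur in each pool, so every read must be
#' routed to one target.  Both primers must match the read termini within
#' `max_errors` edit operations; the amplicon with the unique minimum total
#' distance wins, and a tie or no qualifying amplicon returns `NULL`
#' (reported upstream as `primer-mismatch`).
#'
#' @param seq read sequence after MID removal, amplicon orientation
#' @param panel an [AmpliconPanel-class]
#' @param max_errors per-primer edit budget (default 2)
#' @return list with `index`, `trim5`, `trim3` (bases consumed by each
#'   primer) or `NULL`
#' @export
identifyAmplicon <- function(seq, panel, max_errors = 2L) {
  a <- ampliconTable(panel)
  n <- nchar(seq)
  max_w <- max(nchar(a$rev_primer)) + 4L
  rc_tail <- revComp(substr(seq, max(1L, n - max_w + 1L), n))
  best <- NULL; best_d <- Inf; tie <- FALSE
  for (k in seq_len(nrow(a))) {
    fp <- a$fwd_primer[k]; rp <- a$rev_primer[k]
    # fast path: both primers exact at their nominal windows
    if (substr(seq, 1L, nchar(fp)) == fp &&
        substr(rc_tail, 1L, nchar(rp)) == rp) {
      if (0 < best_d) {
        best_d <- 0; tie <- FALSE
        best <- list(index = a$index[k], trim5 = nchar(fp),
                     trim3 = nchar(rp))
      } else tie <- TRUE
      next
    }
    w5 <- substr(seq, 1L, min(n, nchar(fp) + 4L))
    h5 <- cpp_prefix_edit(fp, w5)
    if (h5[1L] > max_errors) next
    h3 <- cpp_prefix_edit(rp, substr(rc_tail, 1L, nchar(rp) + 4L))
    if (h3[1L] > max_errors) next
    d <- h5[1L] + h3[1L]
    if (d < best_d) {
      best_d <- d; tie <- FALSE
      best <- list(index = a$index[k], trim5 = h5[2L], trim3 = h3[2L])
    } else if (d == best_d) tie <- TRUE
  }
  if (is.null(best) || tie) NULL else best
}

#' Assign a single read to its (sample, amplicon, strand)
#'
#' Requires a decodable forward-set MID at one end and a reverse-set MID at
#' the other (both orientations of the read are tested); the sample is then
#' looked up by the MID pair within the read's group.  Reads with only one
#' decodable MID are unassigned - the full sequence including both MIDs is
#' the traceability requirement, and no single-MID rescue is attempted.
#' MIDs and primer binding sites are trimmed and reverse-strand reads are
#' reverse-complemented, so the returned insert is reference-oriented.
#'
#' @param read read sequence
#' @param design an [ExperimentDesign-class]
#' @param group_id the plate region (group) the read was sequenced in
#' @param max_mid_errors per-MID edit budget (default 2)
#' @return list with fields `status` ("assigned" or a reason code among
#'   missing-MID, ambiguous-MID, unknown-pair, primer-mismatch,
#'   empty-insert), and on assignment `sample_id`, `amplicon`, `strand`,
#'   `insert`, `mid_errors`
#' @export
assignRead <- function(read, design, group_id, max_mid_errors = 2L) {
  fwd_tags <- .fwdTags(design); rev_tags <- .revTags(design)
  sc <- .scanOrientation(read, fwd_tags, rev_tags, max_mid_errors)
  strand <- "+"
  if (sc$status != "ok") {
    rc <- revComp(read)
    sc2 <- .scanOrientation(rc, fwd_tags, rev_tags, max_mid_errors)
    if (sc2$status == "ok") {
      sc <- sc2; read <- rc; strand <- "-"
    } else {
      # prefer the more informative reason across orientations
      reason <- if ("ambiguous-MID" %in% c(sc$status, sc2$status))
        "ambiguous-MID" else "missing-MID"
      return(list(status = reason))
    }
  }
  s <- designSamples(design)
  hit <- s$group_id == group_id & s$fwd_mid == sc$m5$id & s$rev_mid == sc$m3$id
  if (!any(hit)) return(list(status = "unknown-pair"))
  sample_id <- s$sample_id[which(hit)[1L]]

  n <- nchar(read)
  core <- substr(read, sc$m5$end + 1L, n - sc$m3$end)
  amp <- identifyAmplicon(core, design@panel, max_errors = 2L)
  if (is.null(amp)) return(list(status = "primer-mismatch"))
  insert <- substr(core, amp$trim5 + 1L, nchar(core) - amp$trim3)
  if (!nzchar(insert)) return(list(status = "empty-insert"))
  list(status = "assigned", sample_id = sample_id, amplicon = amp$index,
       strand = strand, insert = insert,
       mid_errors = c(fwd = sc$m5$errors, rev = sc$m3$errors))
}

#' Demultiplex a vector of reads from one plate region
#'
#' @param reads character vector of read sequences (named by read id)
#' @param design an [ExperimentDesign-class]
#' @param group_id the group all `reads` belong to
#' @param max_mid_errors per-MID edit budget (default 2)
#' @return a [DemuxResult-class]
#' @export
demultiplexReads <- function(reads, design, group_id, max_mid_errors = 2L) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  n <- length(reads)
  status <- character(n); sample_id <- rep(NA_character_, n)
  amplicon <- rep(NA_integer_, n); strand <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  mid_err_fwd <- rep(NA_integer_, n); mid_err_rev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- assignRead(reads[[i]], design, group_id, max_mid_errors)
    status[i] <- r$status
    if (r$status == "assigned") {
      sample_id[i] <- r$sample_id; amplicon[i] <- r$amplicon
      strand[i] <- r$strand; insert[i] <- r$insert
      mid_err_fwd[i] <- r$mid_errors[["fwd"]]
      mid_err_rev[i] <- r$mid_errors[["rev"]]
    }
  }
  new("DemuxResult", assignments = data.frame(
    read_id = ids, group_id = rep(as.integer(group_id), n), status = status,
    sample_id = sample_id, amplicon = amplicon, strand = strand,
    insert = insert, mid_err_fwd = mid_err_fwd, mid_err_rev = mid_err_rev,
    stringsAsFactors = FALSE))
}

#' Demultiplex a simulated run (all plate regions)
#'
#' Group membership comes from the run's plate-region labels, which are
#' physically known from the gasket layout; cross-group decoding is never
#' attempted because MID pairs are reused across groups.
#'
#' @param run a [SimulatedRun-class]
#' @param design an [ExperimentDesign-class]
#' @param max_mid_errors per-MID edit budget (default 2)
#' @return a [DemuxResult-class]
#' @export
demultiplexRun <- function(run, design, max_mid_errors = 2L) {
  reads <- simReads(run); groups <- run@groups
  parts <- lapply(sort(unique(groups)), function(g) {
    assignments(demultiplexReads(reads[groups == g], design, g,
                                 max_mid_errors))
  })
  out <- do.call(rbind, parts)
  out <- out[match(names(reads), out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  new("DemuxResult", assignments = out)
}

#' Summarize demultiplexing outcomes
#'
#' @param dx a [DemuxResult-class]
#' @return list with `total`, `assigned`, `unassigned`, `by_reason` (named
#'   counts), `rate` (percentage, one decimal; 0 with `rate_undefined =
#'   TRUE` when there are no reads) and `per_sample_amplicon` counts
#' @export
demuxStats <- function(dx) {
  a <- assignments(dx)
  total <- nrow(a)
  assigned <- sum(a$status == "assigned")
  reasons <- table(a$status[a$status != "assigned"])
  psa <- if (assigned) {
    as.data.frame(table(sample_id = a$sample_id[a$status == "assigned"],
                        amplicon = a$amplicon[a$status == "assigned"]),
                  stringsAsFactors = FALSE)
  } else data.frame(sample_id = character(), amplicon = character(),
                    Freq = integer())
  list(total = total, assigned = assigned, unassigned = total - assigned,
       by_reason = reasons,
       rate = if (total) round(100 * assigned / total, 1) else 0,
       rate_undefined = total == 0L,
       per_sample_amplicon = psa)
}
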