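## Per-individual, per-strand pileups over reference amplicons.

## extract per-read pileup contributions from one alignment as plain
## vectors (data.tables are assembled once over all reads)
.readEvents <- function(insert, ops, refseq, off) {
  chars <- strsplit(insert, "")[[1L]]
  out <- list(base_pos = integer(0), base_chr = character(0),
              del_pos = integer(0), del_len = integer(0),
              span_pos = integer(0),
              ins_pos = integer(0), ins_seq = character(0))

  mm <- ops$op == "M" | ops$op == "X"
  if (any(mm)) {
    out$base_pos <- off + ops$rpos[mm]
    out$base_chr <- chars[ops$qpos[mm]]
  }

  di <- which(ops$op == "D")
  if (length(di)) {
    grp <- cumsum(c(TRUE, diff(di) != 1L))
    for (g in split(di, grp)) {
      len <- length(g)
      st <- .leftNormalizeDeletion(refseq, ops$rpos[g[1L]], len)
      out$del_pos <- c(out$del_pos, off + st)
      out$del_len <- c(out$del_len, len)
      out$span_pos <- c(out$span_pos, off + st:(st + len - 1L))
    }
  }

  ii <- which(ops$op == "I")
  if (length(ii)) {
    grp <- cumsum(c(TRUE, diff(ii) != 1L | diff(ops$rpos[ii]) != 0L))
    for (g in split(ii, grp)) {
      nm <- .leftNormalizeInsertion(refseq, ops$rpos[g[1L]],
                                    paste(chars[ops$qpos[g]], collapse = ""))
      out$ins_pos <- c(out$ins_pos, off + nm$pos)
      out$ins_seq <- c(out$ins_seq, nm$seq)
    }
  }
  out
}

#' Build a strand-resolved pileup from demultiplexed reads
#'
#' Each assigned insert is aligned to its reference amplicon; every
#' aligned base, deletion and insertion then increments exactly one
#' counter.  Indels are left-normalized within homopolymer runs before
#' entry so identical events aggregate at one canonical anchor.  Reads
#' below the identity cutoff or beyond the length-ratio limit are excluded
#' and tallied in the QC ledger.  Positions are 1-based coordinates on the
#' full reference.
#'
#' @param dx a [DemuxResult-class]
#' @param design an [ExperimentDesign-class]
#' @param params an [alignParams()] list
#' @return an [AmpliconPileup-class]
#' @export
buildPileup <- function(dx, design, params = alignParams()) {
  a <- assignments(dx)
  a <- a[a$status == "assigned", , drop = FALSE]
  at <- ampliconTable(design)
  if (nrow(a) && !all(a$amplicon %in% at$index))
    stop("alignment references unknown amplicon")
  qc <- list(n_assigned = nrow(a), n_aligned = 0L,
             n_low_identity = 0L, n_unalignable = 0L)

  ev_l <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    k <- match(a$amplicon[i], at$index)
    refseq <- at$insert_seq[k]
    al <- alignRead(a$insert[i], refseq, params)
    if (isTRUE(al$unalignable)) {
      qc$n_unalignable <- qc$n_unalignable + 1L; next
    }
    if (al$identity < params$min_identity) {
      qc$n_low_identity <- qc$n_low_identity + 1L; next
    }
    qc$n_aligned <- qc$n_aligned + 1L
    ev_l[[i]] <- .readEvents(a$insert[i], al$ops, refseq,
                             at$ref_start[k] - 1L)
  }

  gather <- function(field, read_cols) {
    vals <- lapply(ev_l, `[[`, field)
    lens <- vapply(vals, length, integer(1))
    idx <- rep.int(seq_along(ev_l), lens)
    c(list(unlist(vals, use.names = FALSE)),
      lapply(read_cols, function(cc) a[[cc]][idx]))
  }
  g <- gather("base_pos", c("sample_id", "amplicon", "strand"))
  chr <- unlist(lapply(ev_l, `[[`, "base_chr"), use.names = FALSE)
  baseDT <- data.table(sample_id = g[[2L]], amplicon = g[[3L]],
                       pos = g[[1L]], strand = g[[4L]], base = chr)
  g <- gather("span_pos", c("sample_id", "amplicon", "strand"))
  spanDT <- data.table(sample_id = g[[2L]], amplicon = g[[3L]],
                       pos = g[[1L]], strand = g[[4L]])
  g <- gather("del_pos", c("sample_id", "amplicon", "strand"))
  dlen <- unlist(lapply(ev_l, `[[`, "del_len"), use.names = FALSE)
  deleDT <- data.table(sample_id = g[[2L]], amplicon = g[[3L]],
                       pos = g[[1L]], len = dlen, strand = g[[4L]])
  g <- gather("ins_pos", c("sample_id", "amplicon", "strand"))
  isq <- unlist(lapply(ev_l, `[[`, "ins_seq"), use.names = FALSE)
  inseDT <- data.table(sample_id = g[[2L]], amplicon = g[[3L]],
                       pos = g[[1L]], seq = isq, strand = g[[4L]])

  key <- c("sample_id", "amplicon", "pos", "strand")
  if (nrow(baseDT)) {
    cnt <- baseDT[, .N, by = c(key, "base")]
    wide <- dcast(cnt, sample_id + amplicon + pos + strand ~ base,
                  value.var = "N", fill = 0L)
  } else {
    wide <- data.table(sample_id = character(), amplicon = integer(),
                       pos = integer(), strand = character())
  }
  for (b in c("A", "C", "G", "T"))
    if (is.null(wide[[b]])) wide[[b]] <- rep(0L, nrow(wide))

  if (nrow(spanDT)) {
    sp <- spanDT[, .(del = .N), by = key]
    wide <- merge(wide, sp, by = key, all = TRUE)
    for (b in c("A", "C", "G", "T", "del"))
      wide[[b]][is.na(wide[[b]])] <- 0L
  } else wide$del <- rep(0L, nrow(wide))
  wide$depth <- wide$A + wide$C + wide$G + wide$T + wide$del
  setorder(wide, sample_id, amplicon, pos, strand)

  dele <- if (nrow(deleDT)) {
    as.data.frame(deleDT[, .(count = .N),
                         by = c("sample_id", "amplicon", "pos", "len",
                                "strand")])
  } else data.frame(sample_id = character(), amplicon = integer(),
                    pos = integer(), len = integer(), strand = character(),
                    count = integer())

  inse <- if (nrow(inseDT)) {
    as.data.frame(inseDT[, .(count = .N),
                         by = c("sample_id", "amplicon", "pos", "seq",
                                "strand")])
  } else data.frame(sample_id = character(), amplicon = integer(),
                    pos = integer(), seq = character(), strand = character(),
                    count = integer())

  new("AmpliconPileup", baseCounts = as.data.frame(wide),
      deletions = dele, insertions = inse, qc = qc)
}

#' Per-sample supporting coverage for a variant
#'
#' Counts the sample's reads whose aligned base or indel event at the
#' variant site equals the alternate allele; reads covering the site but
#' not showing the variant are excluded.  The covering depth is the number
#' of the sample's reads overlapping the site (both strands).
#'
#' @param pileup an [AmpliconPileup-class]
#' @param variant list or single-row data.frame with fields `amplicon`,
#'   `pos`, `ref`, `alt`, `kind`
#' @param sample_id sample to interrogate
#' @return list with `fwd`, `rev`, `total` supporting reads and `depth`
#' @export
supportingCoverage <- function(pileup, variant, sample_id) {
  bc <- pileup@baseCounts
  at <- bc$sample_id == sample_id & bc$amplicon == variant$amplicon &
    bc$pos == variant$pos
  if (!any(at))
    stop(sprintf("sample %s has no coverage at amplicon %s position %s",
                 sample_id, variant$amplicon, variant$pos))
  depth <- sum(bc$depth[at])
  fwd <- 0L; rev <- 0L
  if (variant$kind == "substitution") {
    fwd <- sum(bc[at & bc$strand == "+", variant$alt])
    rev <- sum(bc[at & bc$strand == "-", variant$alt])
  } else if (variant$kind == "deletion") {
    dl <- pileup@deletions
    hit <- dl$sample_id == sample_id & dl$amplicon == variant$amplicon &
      dl$pos == variant$pos & dl$len == nchar(variant$ref)
    fwd <- sum(dl$count[hit & dl$strand == "+"])
    rev <- sum(dl$count[hit & dl$strand == "-"])
  } else if (variant$kind == "insertion") {
    il <- pileup@insertions
    hit <- il$sample_id == sample_id & il$amplicon == variant$amplicon &
      il$pos == variant$pos & il$seq == variant$alt
    fwd <- sum(il$count[hit & il$strand == "+"])
    rev <- sum(il$count[hit & il$strand == "-"])
  } else stop("unknown variant kind: ", variant$kind)
  list(fwd = fwd, rev = rev, total = fwd + rev, depth = depth)
}

#' Majority-rule consensus for one sample and amplicon
#'
#' Walks the amplicon insert positions taking the majority allele (base or
#' deletion) per position, inserting any insertion supported by more than
#' half of the covering reads; uncovered positions fall back to the
#' reference base.  With error-free reads this reconstructs the sample's
#' haplotype exactly.
#'
#' @param pileup an [AmpliconPileup-class]
#' @param sample_id sample
#' @param amplicon amplicon index
#' @param panel an [AmpliconPanel-class]
#' @return consensus sequence (character)
#' @export
consensusSequence <- function(pileup, sample_id, amplicon, panel) {
  at <- ampliconTable(panel)
  k <- match(amplicon, at$index)
  if (is.na(k)) stop("unknown amplicon: ", amplicon)
  bc <- pileup@baseCounts
  bc <- bc[bc$sample_id == sample_id & bc$amplicon == amplicon, , drop = FALSE]
  il <- pileup@insertions
  il <- il[il$sample_id == sample_id & il$amplicon == amplicon, , drop = FALSE]

  alleles <- c("A", "C", "G", "T", "del")
  out <- character(0)
  for (p in at$ref_start[k]:at$ref_end[k]) {
    rows <- bc[bc$pos == p, , drop = FALSE]
    if (!nrow(rows)) {
      out <- c(out, substr(refBases(panel), p, p))
    } else {
      tot <- colSums(rows[, alleles, drop = FALSE])
      win <- alleles[which.max(tot)]
      if (win != "del") out <- c(out, win)
      depth_p <- sum(rows$depth)
      ins_p <- il[il$pos == p, , drop = FALSE]
      if (nrow(ins_p)) {
        agg <- tapply(ins_p$count, ins_p$seq, sum)
        top <- names(agg)[which.max(agg)]
        if (max(agg) > depth_p / 2) out <- c(out, top)
      }
    }
  }
  paste(out, collapse = "")
}
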