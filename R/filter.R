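## Candidate enumeration and the variant-validation cascade.

#' Validation cascade thresholds
#'
#' Defaults encode the published criteria: per-sample evidence must be
#' double-stranded; a sample supports a variant outright when at least 90
#' percent of its covering reads show the alternate allele and more than
#' 10 reads support it in total (with both directions already represented);
#' a sample at >= 90 percent but with 10 or fewer supporting reads counts
#' only if another sample passes the full thresholds (rescue); and a
#' variant is validated only when at least 2 individuals pass.
#' `strict_direction = TRUE` switches to the stricter reading that demands
#' more than 10 supporting reads in each direction separately.
#'
#' @param min_support_fraction minimum supporting fraction (default 0.90)
#' @param min_total_support support-count threshold, strict `>` (default 10)
#' @param min_carriers minimum individuals carrying the variant (default 2)
#' @param min_hp_len homopolymer run length for artifact flagging (default 3)
#' @param strict_direction require `> min_total_support` per direction
#' @param hp_override_fraction,hp_override_support evidence strong enough
#'   for a flagged indel to override its artifact flag (defaults 0.95 and
#'   20, in at least `min_carriers` samples) - the codified substitute for
#'   manual flowgram adjudication
#' @return classed list
#' @export
filterThresholds <- function(min_support_fraction = 0.90,
                             min_total_support = 10L,
                             min_carriers = 2L,
                             min_hp_len = 3L,
                             strict_direction = FALSE,
                             hp_override_fraction = 0.95,
                             hp_override_support = 20L) {
  stopifnot(min_support_fraction > 0, min_support_fraction <= 1,
            min_total_support >= 1, min_carriers >= 1, min_hp_len >= 2)
  structure(list(min_support_fraction = min_support_fraction,
                 min_total_support = as.integer(min_total_support),
                 min_carriers = as.integer(min_carriers),
                 min_hp_len = as.integer(min_hp_len),
                 strict_direction = isTRUE(strict_direction),
                 hp_override_fraction = hp_override_fraction,
                 hp_override_support = as.integer(hp_override_support)),
            class = "filterThresholds")
}

#' Enumerate candidate variants from a pileup
#'
#' A candidate is any non-reference allele observed at least once: a
#' substitution per (position, alternate base), a deletion per
#' (left-normalized anchor, length), an insertion per (anchor, inserted
#' sequence).  Evidence is aggregated per sample and strand; the covering
#' depth is the sample's total read depth at the anchor position.
#'
#' @param pileup an [AmpliconPileup-class]
#' @param panel an [AmpliconPanel-class]
#' @return list with `variants` and `evidence` data.frames
#' @export
enumerateCandidates <- function(pileup, panel) {
  ref <- refBases(panel)
  bc <- as.data.table(pileup@baseCounts)

  ## per-sample depth at each (amplicon, pos), both strands
  depthDT <- if (nrow(bc)) {
    bc[, .(depth = sum(depth)), by = .(sample_id, amplicon, pos)]
  } else data.table(sample_id = character(), amplicon = integer(),
                    pos = integer(), depth = integer())

  ev_l <- list()

  if (nrow(bc)) {
    long <- data.table::melt(bc, id.vars = c("sample_id", "amplicon",
                                             "pos", "strand"),
                             measure.vars = c("A", "C", "G", "T"),
                             variable.name = "base", value.name = "count",
                             variable.factor = FALSE)
    long <- long[count > 0L]
    long[, ref_base := substring(ref, pos, pos)]
    long <- long[base != ref_base]
    if (nrow(long)) {
      sub_ev <- dcast(long, sample_id + amplicon + pos + ref_base + base ~
                        strand, value.var = "count", fun.aggregate = sum,
                      fill = 0L)
      if (is.null(sub_ev[["+"]])) sub_ev[["+"]] <- 0L
      if (is.null(sub_ev[["-"]])) sub_ev[["-"]] <- 0L
      sub_ev[, `:=`(ref = ref_base, alt = base, kind = "substitution")]
      ev_l$sub <- sub_ev[, .(sample_id, amplicon, pos, ref, alt, kind,
                             fwd = `+`, rev_ = `-`)]
    }
  }

  dl <- as.data.table(pileup@deletions)
  if (nrow(dl)) {
    del_ev <- dcast(dl, sample_id + amplicon + pos + len ~ strand,
                    value.var = "count", fun.aggregate = sum, fill = 0L)
    if (is.null(del_ev[["+"]])) del_ev[["+"]] <- 0L
    if (is.null(del_ev[["-"]])) del_ev[["-"]] <- 0L
    del_ev[, `:=`(ref = substring(ref, pos, pos + len - 1L), alt = "",
                  kind = "deletion")]
    ev_l$del <- del_ev[, .(sample_id, amplicon, pos, ref, alt, kind,
                           fwd = `+`, rev_ = `-`)]
  }

  il <- as.data.table(pileup@insertions)
  if (nrow(il)) {
    ins_ev <- dcast(il, sample_id + amplicon + pos + seq ~ strand,
                    value.var = "count", fun.aggregate = sum, fill = 0L)
    if (is.null(ins_ev[["+"]])) ins_ev[["+"]] <- 0L
    if (is.null(ins_ev[["-"]])) ins_ev[["-"]] <- 0L
    ins_ev[, `:=`(ref = "", alt = seq, kind = "insertion")]
    ev_l$ins <- ins_ev[, .(sample_id, amplicon, pos, ref, alt, kind,
                           fwd = `+`, rev_ = `-`)]
  }

  ev <- rbindlist(ev_l)
  if (!nrow(ev)) {
    return(list(
      variants = data.frame(variant_id = character(), amplicon = integer(),
                            pos = integer(), ref = character(),
                            alt = character(), kind = character(),
                            stringsAsFactors = FALSE),
      evidence = data.frame(variant_id = character(),
                            sample_id = character(), fwd = integer(),
                            rev = integer(), depth = integer(),
                            stringsAsFactors = FALSE)))
  }
  ev[, variant_id := sprintf("%d:%d:%s>%s", amplicon, pos,
                             ifelse(ref == "", "-", ref),
                             ifelse(alt == "", "-", alt))]
  ev <- merge(ev, depthDT, by = c("sample_id", "amplicon", "pos"),
              all.x = TRUE)
  ev$depth[is.na(ev$depth)] <- 0L

  variants <- unique(ev[, .(variant_id, amplicon, pos, ref, alt, kind)])
  setorder(variants, amplicon, pos, kind, alt)
  evidence <- as.data.frame(ev[, .(variant_id, sample_id, fwd, rev = rev_,
                                   depth)])
  list(variants = as.data.frame(variants), evidence = evidence)
}

#' Flag candidate pyrosequencing artifacts
#'
#' Sets the homopolymer-under-read flag on 1-base deletions whose deleted
#' base sits inside or adjacent to a reference run of at least
#' `min_hp_len` identical bases, and the carry-forward flag on 1-base
#' insertions whose inserted base equals a reference base 1-2 positions
#' upstream of the insertion point.
#'
#' @param variants candidate table from [enumerateCandidates()]
#' @param panel an [AmpliconPanel-class]
#' @param min_hp_len homopolymer run threshold (default 3)
#' @return `variants` with logical columns `flag_hp` and `flag_cf`
#' @export
flagArtifacts <- function(variants, panel, min_hp_len = 3L) {
  ref <- refBases(panel)
  n <- nrow(variants)
  flag_hp <- logical(n); flag_cf <- logical(n)
  for (i in seq_len(n)) {
    if (variants$kind[i] == "deletion" && nchar(variants$ref[i]) == 1L) {
      p <- variants$pos[i]
      runs <- c(.runLengthAt(ref, p),
                if (p > 1L) .runLengthAt(ref, p - 1L) else 0L,
                if (p < nchar(ref)) .runLengthAt(ref, p + 1L) else 0L)
      flag_hp[i] <- max(runs) >= min_hp_len
    } else if (variants$kind[i] == "insertion" &&
               nchar(variants$alt[i]) == 1L) {
      p <- variants$pos[i]        # inserted after this reference base
      up <- c(if (p >= 1L) substring(ref, p, p) else "",
              if (p >= 2L) substring(ref, p - 1L, p - 1L) else "")
      flag_cf[i] <- variants$alt[i] %in% up
    }
  }
  variants$flag_hp <- flag_hp
  variants$flag_cf <- flag_cf
  variants
}

#' Per-sample double-strand criterion
#'
#' A sample's evidence counts only if the variant was seen in reads from
#' both DNA strands: at least one forward and one reverse supporting read.
#'
#' @param evidence evidence table from [enumerateCandidates()]
#' @param thresholds a [filterThresholds()] list (unused fields ignored)
#' @return `evidence` with logical column `both_strand`
#' @export
filterBothStrands <- function(evidence, thresholds = filterThresholds()) {
  evidence$both_strand <- evidence$fwd >= 1L & evidence$rev >= 1L
  evidence
}

#' Per-sample support criterion with cross-sample rescue
#'
#' A sample passes outright when its supporting fraction is at least
#' `min_support_fraction` of its covering depth and its total supporting
#' reads exceed `min_total_support` (per direction under
#' `strict_direction`).  A sample at the fraction threshold but at or
#' below the read-count threshold passes only by rescue: some other sample
#' must pass the full thresholds for the same variant.  Samples with zero
#' covering depth are excluded (not failed).  Requires `both_strand` from
#' [filterBothStrands()].
#'
#' @param evidence evidence table with `both_strand`
#' @param thresholds a [filterThresholds()] list
#' @return `evidence` with column `status` in `pass_full`, `pass_rescue`,
#'   `fail`, `excluded`
#' @export
filterSupport <- function(evidence, thresholds = filterThresholds()) {
  if (is.null(evidence$both_strand))
    evidence <- filterBothStrands(evidence, thresholds)
  total <- evidence$fwd + evidence$rev
  frac <- ifelse(evidence$depth > 0, total / evidence$depth, NA_real_)
  count_ok <- if (thresholds$strict_direction)
    evidence$fwd > thresholds$min_total_support &
      evidence$rev > thresholds$min_total_support
  else total > thresholds$min_total_support
  full <- evidence$both_strand & !is.na(frac) &
    frac >= thresholds$min_support_fraction & count_ok
  eligible <- evidence$both_strand & !is.na(frac) &
    frac >= thresholds$min_support_fraction & !count_ok

  has_full <- tapply(full, evidence$variant_id, any)
  rescue <- eligible & as.logical(has_full[evidence$variant_id])

  status <- rep("fail", nrow(evidence))
  status[is.na(frac)] <- "excluded"
  status[rescue] <- "pass_rescue"
  status[full] <- "pass_full"
  evidence$status <- status
  evidence
}

#' Multi-individual criterion
#'
#' Variants passing in fewer than `min_carriers` individuals are rejected:
#' a change seen in a single sample is uninformative and may be a PCR or
#' sequencing error.
#'
#' @param evidence evidence table with `status` from [filterSupport()]
#' @param thresholds a [filterThresholds()] list
#' @return data.frame per variant: `variant_id`, `n_carriers`, `validated`
#' @export
filterMultiIndividual <- function(evidence,
                                  thresholds = filterThresholds()) {
  pass <- evidence$status %in% c("pass_full", "pass_rescue")
  n <- tapply(pass, evidence$variant_id, sum)
  data.frame(variant_id = names(n), n_carriers = as.integer(n),
             validated = as.integer(n) >= thresholds$min_carriers,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify variants and group multiallelic sites
#'
#' Substitutions are transitions (A<->G, C<->T) or transversions; indels
#' keep their kind.  Validated variants sharing a reference position form
#' a multiallelic group.
#'
#' @param variants variant table with `validated` column
#' @return `variants` with `class` and `multiallelic_group` columns
#' @export
classifyVariants <- function(variants) {
  cls <- character(nrow(variants))
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(nrow(variants))) {
    cls[i] <- switch(variants$kind[i],
      substitution = if (identical(unname(ts[variants$ref[i]]),
                                   variants$alt[i]))
        "transition" else "transversion",
      insertion = "insertion",
      deletion = "deletion")
  }
  variants$class <- cls
  variants$multiallelic_group <- rep(NA_integer_, nrow(variants))
  if (!is.null(variants$validated) && any(variants$validated)) {
    v <- which(variants$validated)
    key <- paste(variants$amplicon[v], variants$pos[v])
    dup <- key %in% key[duplicated(key)]
    if (any(dup)) {
      gid <- as.integer(factor(key[dup], levels = unique(key[dup])))
      variants$multiallelic_group[v[dup]] <- gid
    }
  }
  variants
}

#' Run the full validation cascade
#'
#' Stages in fixed order: candidate enumeration, artifact rejection,
#' double-strand support, >= 90 percent replicate support with read-count
#' thresholds and rescue, multi-individual requirement.  An artifact flag
#' rejects a candidate only when no override-strength evidence exists: a
#' flagged indel survives when at least `min_carriers` samples each show
#' it at `hp_override_fraction` of depth with more than
#' `hp_override_support` double-stranded supporting reads.  The rescue
#' clause is evaluated after all per-sample fractions are known, so the
#' cascade is deterministic and read-order independent.
#'
#' @param pileup an [AmpliconPileup-class]
#' @param panel an [AmpliconPanel-class]
#' @param thresholds a [filterThresholds()] list
#' @return a [VariantCallSet-class]
#' @export
runCascade <- function(pileup, panel, thresholds = filterThresholds()) {
  cand <- enumerateCandidates(pileup, panel)
  variants <- cand$variants
  evidence <- cand$evidence
  trace <- data.frame(stage = "candidates", n = nrow(variants),
                      stringsAsFactors = FALSE)

  if (!nrow(variants)) {
    variants <- classifyVariants(cbind(variants, flag_hp = logical(0),
                                       flag_cf = logical(0),
                                       validated = logical(0),
                                       reason = character(0),
                                       n_carriers = integer(0)))
    trace <- rbind(trace, data.frame(
      stage = c("artifact_rejection", "both_strand", "support",
                "multi_individual"), n = 0L))
    evidence$both_strand <- logical(0)
    evidence$status <- character(0)
    return(new("VariantCallSet", variants = variants, evidence = evidence,
               trace = trace, thresholds = unclass(thresholds)))
  }

  variants <- flagArtifacts(variants, panel, thresholds$min_hp_len)
  evidence <- filterSupport(filterBothStrands(evidence, thresholds),
                            thresholds)

  ## artifact rejection with strong-evidence override
  pass <- evidence$status %in% c("pass_full", "pass_rescue")
  total <- evidence$fwd + evidence$rev
  override_sample <- evidence$both_strand & evidence$depth > 0 &
    total / pmax(evidence$depth, 1L) >= thresholds$hp_override_fraction &
    total > thresholds$hp_override_support
  n_override <- tapply(override_sample, evidence$variant_id, sum)
  n_override <- setNames(as.integer(n_override), names(n_override))
  flagged <- variants$flag_hp | variants$flag_cf
  ov <- n_override[variants$variant_id]
  ov[is.na(ov)] <- 0L
  artifact_rejected <- flagged & ov < thresholds$min_carriers
  surv <- !artifact_rejected
  trace <- rbind(trace, data.frame(stage = "artifact_rejection",
                                   n = sum(surv)))

  ## double-strand stage: at least one sample with both-strand evidence
  bs_any <- tapply(evidence$both_strand, evidence$variant_id, any)
  surv_bs <- surv & as.logical(bs_any[variants$variant_id])
  surv_bs[is.na(surv_bs)] <- FALSE
  trace <- rbind(trace, data.frame(stage = "both_strand", n = sum(surv_bs)))

  ## support stage: at least one passing sample
  pass_any <- tapply(pass, evidence$variant_id, any)
  surv_sup <- surv_bs & as.logical(pass_any[variants$variant_id])
  surv_sup[is.na(surv_sup)] <- FALSE
  trace <- rbind(trace, data.frame(stage = "support", n = sum(surv_sup)))

  ## multi-individual stage
  mi <- filterMultiIndividual(evidence, thresholds)
  nc <- setNames(mi$n_carriers, mi$variant_id)
  variants$n_carriers <- as.integer(nc[variants$variant_id])
  variants$n_carriers[is.na(variants$n_carriers)] <- 0L
  validated <- surv_sup & variants$n_carriers >= thresholds$min_carriers
  trace <- rbind(trace, data.frame(stage = "multi_individual",
                                   n = sum(validated)))

  variants$validated <- validated
  variants$reason <- ifelse(validated, "",
    ifelse(artifact_rejected,
           ifelse(variants$flag_hp, "homopolymer-underread",
                  "carry-forward"),
    ifelse(!surv_bs, "single-strand",
    ifelse(!surv_sup, "insufficient-support", "single-individual"))))
  variants <- classifyVariants(variants)

  new("VariantCallSet", variants = variants, evidence = evidence,
      trace = trace, thresholds = unclass(thresholds))
}

#' Demultiplex-to-variants convenience wrapper
#'
#' @param dx a [DemuxResult-class]
#' @param design an [ExperimentDesign-class]
#' @param thresholds a [filterThresholds()] list
#' @param params an [alignParams()] list
#' @return a [VariantCallSet-class]
#' @export
callVariants <- function(dx, design, thresholds = filterThresholds(),
                         params = alignParams()) {
  pileup <- buildPileup(dx, design, params)
  runCascade(pileup, design@panel, thresholds)
}
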