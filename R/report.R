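## Panel-level summary statistics, sharing summaries, VCF and SNP maps.

#' Per-amplicon variant densities from counts
#'
#' Low-level arithmetic shared by [regionStats()]: given per-amplicon
#' variant counts, computes variants-per-base densities (6 decimals,
#' round-half-even) and appends per-region and whole-panel totals whose
#' density is total variants over total insert length.
#'
#' @param panel an [AmpliconPanel-class]
#' @param counts integer vector of variant counts, one per amplicon in
#'   panel order (or named by amplicon index)
#' @param extra optional data.frame of additional per-amplicon count
#'   columns to aggregate (same row order)
#' @return data.frame with `level` in amplicon/region/total
#' @export
regionDensity <- function(panel, counts, extra = NULL) {
  a <- ampliconTable(panel)
  if (!is.null(names(counts))) counts <- counts[as.character(a$index)]
  counts <- as.integer(counts)
  stopifnot(length(counts) == nrow(a))
  base <- data.frame(level = "amplicon", region = a$region,
                     amplicon = a$index, insert_length = a$insert_length,
                     n_variants = counts, stringsAsFactors = FALSE)
  if (!is.null(extra)) base <- cbind(base, extra)
  num_cols <- setdiff(names(base), c("level", "region", "amplicon"))

  reg <- do.call(rbind, lapply(unique(a$region), function(r) {
    rows <- base[base$region == r, , drop = FALSE]
    out <- data.frame(level = "region", region = r, amplicon = NA,
                      stringsAsFactors = FALSE)
    for (cc in num_cols) out[[cc]] <- sum(rows[[cc]])
    out
  }))
  tot <- data.frame(level = "total", region = "ALL", amplicon = NA,
                    stringsAsFactors = FALSE)
  for (cc in num_cols) tot[[cc]] <- sum(base[[cc]])
  out <- rbind(base, reg, tot)
  out$snps_per_base <- round(out$n_variants / out$insert_length, 6)
  rownames(out) <- NULL
  out
}

#' Panel summary statistics for a validated call set
#'
#' One row per amplicon plus per-region and totals rows: validated variant
#' counts, per-base densities, the mean and SD of per-carrier supporting
#' coverage, and transition/transversion/indel/multiallelic class counts.
#' Class counts sum to the variant count on every row.
#'
#' @param vcs a [VariantCallSet-class]
#' @param panel an [AmpliconPanel-class]
#' @return data.frame as for [regionDensity()] plus class and coverage
#'   columns
#' @export
regionStats <- function(vcs, panel) {
  a <- ampliconTable(panel)
  v <- validatedVariants(vcs)
  if (nrow(v)) {
    inside <- vapply(seq_len(nrow(v)), function(i) {
      any(a$index == v$amplicon[i] & a$ref_start <= v$pos[i] &
            a$ref_end >= v$pos[i])
    }, logical(1L))
    if (!all(inside))
      stop("validated variant outside all amplicon inserts: ",
           paste(v$variant_id[!inside], collapse = ", "))
  }
  ev <- variantEvidence(vcs)
  ev <- ev[ev$status %in% c("pass_full", "pass_rescue"), , drop = FALSE]
  ev$support <- ev$fwd + ev$rev
  ev$amplicon <- v$amplicon[match(ev$variant_id, v$variant_id)]
  ev <- ev[!is.na(ev$amplicon), , drop = FALSE]

  counts <- integer(nrow(a)); extra <- data.frame(
    multiallelic = integer(nrow(a)), transitions = integer(nrow(a)),
    transversions = integer(nrow(a)), insertions = integer(nrow(a)),
    deletions = integer(nrow(a)))
  mean_sup <- rep(NA_real_, nrow(a)); sd_sup <- rep(NA_real_, nrow(a))
  for (k in seq_len(nrow(a))) {
    vk <- v[v$amplicon == a$index[k], , drop = FALSE]
    counts[k] <- nrow(vk)
    extra$transitions[k] <- sum(vk$class == "transition")
    extra$transversions[k] <- sum(vk$class == "transversion")
    extra$insertions[k] <- sum(vk$class == "insertion")
    extra$deletions[k] <- sum(vk$class == "deletion")
    extra$multiallelic[k] <-
      length(unique(vk$multiallelic_group[!is.na(vk$multiallelic_group)]))
    sup <- ev$support[ev$amplicon == a$index[k]]
    if (length(sup)) {
      mean_sup[k] <- mean(sup)
      sd_sup[k] <- if (length(sup) > 1L) sd(sup) else 0
    }
  }
  out <- regionDensity(panel, counts, extra)

  ## pooled per-carrier supporting coverage for region/total rows
  cov_for <- function(idx) {
    sup <- ev$support[ev$amplicon %in% idx]
    c(mean = if (length(sup)) mean(sup) else NA_real_,
      sd = if (length(sup) > 1L) sd(sup) else if (length(sup)) 0 else NA_real_)
  }
  out$mean_support <- NA_real_; out$sd_support <- NA_real_
  amp_rows <- out$level == "amplicon"
  out$mean_support[amp_rows] <- round(mean_sup, 1)
  out$sd_support[amp_rows] <- round(sd_sup, 1)
  for (i in which(out$level == "region")) {
    cv <- cov_for(a$index[a$region == out$region[i]])
    out$mean_support[i] <- round(cv[["mean"]], 1)
    out$sd_support[i] <- round(cv[["sd"]], 1)
  }
  ti <- which(out$level == "total")
  cv <- cov_for(a$index)
  out$mean_support[ti] <- round(cv[["mean"]], 1)
  out$sd_support[ti] <- round(cv[["sd"]], 1)
  out
}

#' Population-sharing summary over validated variants
#'
#' Maps each variant's carriers to sampling locations and reports, at one
#' decimal, the percentage of variants found in exactly one location, in
#' all locations, in fewer than 10 locations, and in more than half of the
#' locations.  Both natural denominators are exposed: all validated
#' variants, and SNPs only (indels excluded).
#'
#' @param vcs a [VariantCallSet-class]
#' @param design an [ExperimentDesign-class]
#' @return list with `per_variant` (location counts) and `summary`
#'   (percentages under both denominators)
#' @export
sharingSummary <- function(vcs, design) {
  v <- validatedVariants(vcs)
  s <- designSamples(design)
  ev <- variantEvidence(vcs)
  ev <- ev[ev$status %in% c("pass_full", "pass_rescue") &
             ev$variant_id %in% v$variant_id, , drop = FALSE]
  loc <- s$location_id[match(ev$sample_id, s$sample_id)]
  if (anyNA(loc)) stop("carrier with unknown location")
  n_loc <- tapply(loc, ev$variant_id, function(x) length(unique(x)))
  per_variant <- data.frame(variant_id = names(n_loc),
                            n_locations = as.integer(n_loc),
                            stringsAsFactors = FALSE, row.names = NULL)
  per_variant$kind <- v$kind[match(per_variant$variant_id, v$variant_id)]
  n_all_loc <- length(unique(s$location_id))

  pct <- function(x, n) if (n) round(100 * sum(x) / n, 1) else NA_real_
  summarize <- function(pv) {
    n <- nrow(pv)
    data.frame(
      n_variants = n,
      pct_single_location = pct(pv$n_locations == 1L, n),
      pct_all_locations = pct(pv$n_locations == n_all_loc, n),
      pct_lt10_locations = pct(pv$n_locations < 10L, n),
      pct_gt_half_locations = pct(pv$n_locations > n_all_loc / 2, n))
  }
  summary <- rbind(
    cbind(denominator = "all_variants", summarize(per_variant)),
    cbind(denominator = "snps_only",
          summarize(per_variant[per_variant$kind == "substitution", ,
                                drop = FALSE])))
  list(per_variant = per_variant, summary = summary,
       n_locations_total = n_all_loc)
}

#' Write validated variants as VCF 4.2
#'
#' Indels are anchored on the preceding reference base per VCF convention;
#' validated alternates sharing a position are emitted as one multiallelic
#' record with comma-separated alternates.  INFO carries the carrier count
#' (NS), mean supporting depth over carriers (MDP) and the class (VT).
#' Records are ordered by position, so output is deterministic.
#'
#' @param vcs a [VariantCallSet-class]
#' @param reference a [ReferenceSequence-class]
#' @param path output file
#' @export
writeVcf <- function(vcs, reference, path) {
  v <- validatedVariants(vcs)
  ev <- variantEvidence(vcs)
  ref <- refBases(reference)

  recs <- lapply(seq_len(nrow(v)), function(i) {
    pos <- v$pos[i]
    if (v$kind[i] == "substitution") {
      if (substring(ref, pos, pos) != v$ref[i])
        stop("allele inconsistent with reference at position ", pos)
      list(pos = pos, ref = v$ref[i], alt = v$alt[i], row = i)
    } else if (v$kind[i] == "deletion") {
      anchor <- substring(ref, pos - 1L, pos - 1L)
      if (substring(ref, pos, pos + nchar(v$ref[i]) - 1L) != v$ref[i])
        stop("allele inconsistent with reference at position ", pos)
      list(pos = pos - 1L, ref = paste0(anchor, v$ref[i]), alt = anchor,
           row = i)
    } else {
      anchor <- substring(ref, pos, pos)
      list(pos = pos, ref = anchor, alt = paste0(anchor, v$alt[i]), row = i)
    }
  })
  vt_code <- c(transition = "TS", transversion = "TV",
               insertion = "INS", deletion = "DEL")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", refId(reference), length(reference)),
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Carrier individuals\">",
    "##INFO=<ID=MDP,Number=A,Type=Float,Description=\"Mean supporting depth per carrier\">",
    "##INFO=<ID=VT,Number=A,Type=String,Description=\"Variant class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (!length(recs)) {
    writeLines(header, path)
    return(invisible(path))
  }

  rec_pos <- vapply(recs, `[[`, numeric(1), "pos")
  rec_ref <- vapply(recs, `[[`, character(1), "ref")
  ## merge records sharing (pos); normalize REF to the longest one
  keys <- split(seq_along(recs), rec_pos)
  lines <- character(0)
  for (kk in keys[order(as.numeric(names(keys)))]) {
    pos <- rec_pos[kk[1L]]
    reflens <- nchar(rec_ref[kk])
    REF <- rec_ref[kk][which.max(reflens)]
    alts <- character(0); ns <- integer(0); mdp <- numeric(0)
    vts <- character(0); ids <- character(0)
    for (j in kk) {
      pad <- substring(REF, nchar(rec_ref[j]) + 1L)
      alts <- c(alts, paste0(recs[[j]]$alt, pad))
      row <- recs[[j]]$row
      ids <- c(ids, v$variant_id[row])
      evi <- ev[ev$variant_id == v$variant_id[row] &
                  ev$status %in% c("pass_full", "pass_rescue"), ,
                drop = FALSE]
      ns <- c(ns, nrow(evi))
      mdp <- c(mdp, round(mean(evi$fwd + evi$rev), 1))
      vts <- c(vts, vt_code[[v$class[row]]])
    }
    info <- sprintf("NS=%d;MDP=%s;VT=%s", max(ns),
                    paste(mdp, collapse = ","),
                    paste(vts, collapse = ","))
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                              refId(reference), pos,
                              paste(ids, collapse = ";"), REF,
                              paste(alts, collapse = ","), info))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Per-region map of validated variants
#'
#' Ordered positions per region with alleles and a novel/known flag taken
#' from an optional prior panel (data.frame or TSV path with columns pos,
#' ref, alt).
#'
#' @param vcs a [VariantCallSet-class]
#' @param panel an [AmpliconPanel-class]
#' @param prior optional prior variant panel
#' @return data.frame: region, amplicon, pos, ref, alt, class, status
#' @export
snpMap <- function(vcs, panel, prior = NULL) {
  v <- validatedVariants(vcs)
  a <- ampliconTable(panel)
  v$region <- a$region[match(v$amplicon, a$index)]
  if (is.character(prior)) prior <- read.delim(prior,
                                               stringsAsFactors = FALSE)
  known_key <- if (!is.null(prior) && nrow(prior))
    paste(prior$pos, prior$ref, prior$alt) else character(0)
  v$status <- ifelse(paste(v$pos, v$ref, v$alt) %in% known_key,
                     "known", "novel")
  v <- v[order(v$pos), c("region", "amplicon", "pos", "ref", "alt",
                         "class", "status")]
  rownames(v) <- NULL
  v
}
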