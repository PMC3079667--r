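## Ground-truth haplotype and 454-like read simulation.

#' Coverage model for simulated reads
#'
#' Per-(individual, amplicon) read depths are drawn as a rounded normal
#' truncated at zero - the study design reports depth only as mean +/- SD
#' (27.3 +/- 11.74 reads supporting a SNP per individual), which these
#' defaults reproduce.
#'
#' @param mean_depth expected reads per (individual, amplicon)
#' @param sd_depth standard deviation of depth
#' @param fwd_fraction expected fraction of forward-orientation reads
#' @return classed list
#' @export
coverageModel <- function(mean_depth = 27.3, sd_depth = 11.74,
                          fwd_fraction = 0.5) {
  stopifnot(mean_depth > 0, sd_depth >= 0,
            fwd_fraction > 0, fwd_fraction < 1)
  structure(list(mean_depth = mean_depth, sd_depth = sd_depth,
                 fwd_fraction = fwd_fraction), class = "coverageModel")
}

#' 454-like error model for simulated reads
#'
#' Emulates the artifact classes the validation cascade must reject:
#' random substitutions, homopolymer under-reads (a 1-base deletion in a
#' run of `min_hp_len` or more identical bases), carry-forward events (a
#' spurious single-base insertion duplicating a nearby upstream base) and
#' read truncations that remove one terminal MID.
#'
#' @param substitution_rate per-base substitution probability
#' @param hp_underread_rate per-homopolymer-run probability of a 1-base
#'   under-read
#' @param carry_forward_rate per-read probability of one carry-forward
#'   insertion
#' @param truncation_rate per-read probability of losing one MID end
#' @param min_hp_len minimum run length at risk of under-reads (default 3)
#' @return classed list
#' @export
errorModel <- function(substitution_rate = 0.005, hp_underread_rate = 0.1,
                       carry_forward_rate = 0.05, truncation_rate = 0.015,
                       min_hp_len = 3L) {
  p <- c(substitution_rate, hp_underread_rate, carry_forward_rate,
         truncation_rate)
  stopifnot(all(p >= 0), all(p <= 1), min_hp_len >= 2L)
  structure(list(substitution_rate = substitution_rate,
                 hp_underread_rate = hp_underread_rate,
                 carry_forward_rate = carry_forward_rate,
                 truncation_rate = truncation_rate,
                 min_hp_len = as.integer(min_hp_len)),
            class = "errorModel")
}

#' Plant ground-truth variants in a design
#'
#' Draws unique reference positions inside amplicon inserts and assigns
#' each variant an alternate allele (substitution, or a 1-2 bp indel with
#' probability `indel_fraction`) and a carrier set among the design's
#' analysis-species samples.  Indels are left-normalized at creation so
#' the truth table is directly comparable with called variants.  Output is
#' reproducible for a fixed seed.
#'
#' @param design an [ExperimentDesign-class]
#' @param n_variants number of variants to plant
#' @param carrier_counts carriers per variant: a single integer, an
#'   integer vector sampled uniformly, or a function of n
#' @param indel_fraction fraction of variants planted as indels
#' @param seed optional RNG seed
#' @param species carrier pool (default "Salmo salar")
#' @param min_spacing minimum distance between planted positions
#' @param edge_buffer distance kept from insert edges
#' @return data.frame: variant_id, amplicon, pos, ref, alt, kind, carriers
#'   (comma-separated sample ids)
#' @export
simulateHaplotypes <- function(design, n_variants, carrier_counts = 2L,
                               indel_fraction = 0.1, seed = NULL,
                               species = "Salmo salar",
                               min_spacing = 6L, edge_buffer = 4L) {
  if (!is.null(seed)) set.seed(seed)
  at <- ampliconTable(design)
  ref <- refBases(design@panel)
  s <- designSamples(design)
  pool <- s$sample_id[s$species == species]
  if (!length(pool)) stop("no samples of species ", species)

  cand <- unlist(lapply(seq_len(nrow(at)), function(k) {
    (at$ref_start[k] + edge_buffer):(at$ref_end[k] - edge_buffer)
  }))
  if (n_variants == 0L)
    return(data.frame(variant_id = character(), amplicon = integer(),
                      pos = integer(), ref = character(),
                      alt = character(), kind = character(),
                      carriers = character(), stringsAsFactors = FALSE))
  # greedy spaced sampling of positions
  pos <- integer(0)
  cand <- sample(cand)
  for (p in cand) {
    if (!length(pos) || all(abs(pos - p) >= min_spacing)) pos <- c(pos, p)
    if (length(pos) == n_variants) break
  }
  if (length(pos) < n_variants)
    stop("more variants requested than available spaced positions")
  pos <- sort(pos)

  amp_of <- function(p) at$index[at$ref_start <= p & at$ref_end >= p][1L]
  draw_carriers <- function() {
    k <- if (is.function(carrier_counts)) carrier_counts(1L)
    else if (length(carrier_counts) > 1L) sample(carrier_counts, 1L)
    else carrier_counts
    paste(sample(pool, min(k, length(pool))), collapse = ",")
  }
  bases <- c("A", "C", "G", "T")

  rows <- lapply(pos, function(p) {
    amp <- amp_of(p)
    k <- match(amp, at$index)
    if (runif(1) < indel_fraction) {
      len <- sample(1:2, 1L)
      if (runif(1) < 0.5) {                       # deletion
        local <- p - at$ref_start[k] + 1L
        nst <- .leftNormalizeDeletion(at$insert_seq[k], local, len)
        gpos <- at$ref_start[k] - 1L + nst
        data.frame(amplicon = amp, pos = gpos,
                   ref = substring(ref, gpos, gpos + len - 1L), alt = "",
                   kind = "deletion", carriers = draw_carriers(),
                   stringsAsFactors = FALSE)
      } else {                                    # insertion
        seqv <- paste(sample(bases, len, replace = TRUE), collapse = "")
        local <- p - at$ref_start[k] + 1L
        nm <- .leftNormalizeInsertion(at$insert_seq[k], local, seqv)
        data.frame(amplicon = amp, pos = at$ref_start[k] - 1L + nm$pos,
                   ref = "", alt = nm$seq, kind = "insertion",
                   carriers = draw_carriers(), stringsAsFactors = FALSE)
      }
    } else {                                      # substitution
      rb <- substring(ref, p, p)
      data.frame(amplicon = amp, pos = p,
                 ref = rb, alt = sample(setdiff(bases, rb), 1L),
                 kind = "substitution", carriers = draw_carriers(),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  # normalization may have moved an anchor; drop rare collisions
  out <- out[!duplicated(paste(out$amplicon, out$pos)), , drop = FALSE]
  out$variant_id <- sprintf("%d:%d:%s>%s", out$amplicon, out$pos,
                            ifelse(out$ref == "", "-", out$ref),
                            ifelse(out$alt == "", "-", out$alt))
  rownames(out) <- NULL
  out[, c("variant_id", "amplicon", "pos", "ref", "alt", "kind", "carriers")]
}

## apply one sample's variants to an amplicon insert; returns the haplotype
.applyVariants <- function(insert_seq, ref_start, vars) {
  if (!nrow(vars)) return(insert_seq)
  vars <- vars[order(-vars$pos), , drop = FALSE]
  s <- insert_seq
  for (i in seq_len(nrow(vars))) {
    local <- vars$pos[i] - ref_start + 1L
    if (vars$kind[i] == "substitution") {
      substr(s, local, local) <- vars$alt[i]
    } else if (vars$kind[i] == "deletion") {
      s <- paste0(substr(s, 1L, local - 1L),
                  substr(s, local + nchar(vars$ref[i]), nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, local), vars$alt[i],
                  substr(s, local + 1L, nchar(s)))
    }
  }
  s
}

## homopolymer under-reads: each run of >= min_hp_len identical bases
## loses one base with probability `rate`; returns seq and event count
.applyHpUnderread <- function(seq, rate, min_hp_len) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  r <- rle(strsplit(seq, "")[[1L]])
  hit <- r$lengths >= min_hp_len & runif(length(r$lengths)) < rate
  n <- sum(hit)
  if (n) r$lengths[hit] <- r$lengths[hit] - 1L
  list(seq = paste(rep.int(r$values, r$lengths), collapse = ""), n = n)
}

## carry-forward: with probability `rate` insert a duplicate of the base
## 1-2 positions upstream of a chosen site, preferring a different
## intervening base (the flow-order signature)
.applyCarryForward <- function(seq, rate) {
  if (rate <= 0 || runif(1) >= rate || nchar(seq) < 4L)
    return(list(seq = seq, n = 0L))
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  site <- NA_integer_
  for (try in 1:8) {                      # bias toward X Y | X patterns
    i <- sample(2:(n - 1L), 1L)
    if (chars[i - 1L] != chars[i]) { site <- i; break }
  }
  if (is.na(site)) site <- sample(2:(n - 1L), 1L)
  ins <- chars[site - 1L]
  list(seq = paste(c(chars[1:site], ins, chars[(site + 1L):n]),
                   collapse = ""), n = 1L)
}

## random substitutions over the whole read
.applySubstitutions <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(list(seq = seq, n = 0L))
  chars <- strsplit(seq, "")[[1L]]
  at <- sample.int(n, k)
  for (i in at) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  list(seq = paste(chars, collapse = ""), n = k)
}

## truncation: lose one MID end (the MID plus a random slice of primer)
.applyTruncation <- function(seq, rate) {
  if (rate <= 0 || runif(1) >= rate)
    return(list(seq = seq, n = 0L))
  cut <- 10L + sample(0:12, 1L)
  if (runif(1) < 0.5) list(seq = substr(seq, cut + 1L, nchar(seq)), n = 1L)
  else list(seq = substr(seq, 1L, nchar(seq) - cut), n = 1L)
}

#' Simulate tagged amplicon reads with ground-truth provenance
#'
#' Every read is MID + forward primer + insert (with the sample's planted
#' alleles and sampled errors) + reverse primer + reverse-complemented
#' reverse MID, emitted on the forward or reverse strand per the coverage
#' model's strand balance.  Per-(individual, amplicon) read counts follow
#' the coverage model; truncated reads lose one MID end.  Each read
#' carries exactly one provenance record.
#'
#' @param design an [ExperimentDesign-class]
#' @param variants truth table from [simulateHaplotypes()] (may have 0 rows)
#' @param coverage a [coverageModel()]
#' @param errors an [errorModel()]
#' @param seed optional RNG seed
#' @param samples optional subset of sample ids to sequence
#' @return a [SimulatedRun-class]
#' @export
simulateReads <- function(design, variants, coverage = coverageModel(),
                          errors = errorModel(), seed = NULL,
                          samples = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(coverage, "coverageModel"),
            inherits(errors, "errorModel"))
  s <- designSamples(design)
  if (!is.null(samples)) s <- s[s$sample_id %in% samples, , drop = FALSE]
  at <- ampliconTable(design)
  m <- designMids(design)
  midseq <- setNames(m$sequence, m$id)

  carriers <- strsplit(variants$carriers, ",", fixed = TRUE)

  reads <- character(0); groups <- integer(0)
  prov <- list()
  rid <- 0L
  for (si in seq_len(nrow(s))) {
    mine <- if (nrow(variants))
      vapply(carriers, function(cc) s$sample_id[si] %in% cc, logical(1L))
    else logical(0)
    fmid <- midseq[[s$fwd_mid[si]]]
    rmid_rc <- revComp(midseq[[s$rev_mid[si]]])
    for (k in seq_len(nrow(at))) {
      depth <- max(0L, as.integer(round(
        rnorm(1L, coverage$mean_depth, coverage$sd_depth))))
      if (depth == 0L) next
      vamp <- variants[mine & variants$amplicon == at$index[k], ,
                       drop = FALSE]
      hap <- .applyVariants(at$insert_seq[k], at$ref_start[k], vamp)
      for (d in seq_len(depth)) {
        rid <- rid + 1L
        hp <- .applyHpUnderread(hap, errors$hp_underread_rate,
                                errors$min_hp_len)
        cf <- .applyCarryForward(hp$seq, errors$carry_forward_rate)
        read <- paste0(fmid, at$fwd_primer[k], cf$seq,
                       revComp(at$rev_primer[k]), rmid_rc)
        sub <- .applySubstitutions(read, errors$substitution_rate)
        n_bases <- nchar(sub$seq)
        tr <- .applyTruncation(sub$seq, errors$truncation_rate)
        strand <- if (runif(1) < coverage$fwd_fraction) "+" else "-"
        out <- if (strand == "+") tr$seq else revComp(tr$seq)
        id <- sprintf("r%07d", rid)
        reads[id] <- out
        groups <- c(groups, s$group_id[si])
        prov[[rid]] <- data.frame(
          read_id = id, group_id = s$group_id[si],
          sample_id = s$sample_id[si], amplicon = at$index[k],
          strand = strand, n_sub = sub$n, n_hp_del = hp$n, n_cf = cf$n,
          truncated = tr$n, n_bases = n_bases, stringsAsFactors = FALSE)
      }
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov)
  else data.frame(read_id = character(), group_id = integer(),
                  sample_id = character(), amplicon = integer(),
                  strand = character(), n_sub = integer(),
                  n_hp_del = integer(), n_cf = integer(),
                  truncated = integer(), n_bases = integer(),
                  stringsAsFactors = FALSE)
  new("SimulatedRun", reads = reads, groups = as.integer(groups),
      provenance = prov, truth = variants,
      models = list(coverage = coverage, errors = errors))
}

#' Write simulated reads as FASTQ
#'
#' Constant Q30 placeholder qualities: the pipeline's filters are
#' count-based, not quality-based.
#'
#' @param run a [SimulatedRun-class]
#' @param path output file
#' @export
writeReadsFastq <- function(run, path) {
  reads <- simReads(run)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+",
                 strrep("?", nchar(reads[[i]]))), con)
  }
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path FASTQ file
#' @return named character vector of read sequences
#' @export
loadReadsFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
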