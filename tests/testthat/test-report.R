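# Panel statistics, sharing summaries, VCF output, SNP maps.

test_that("published panel counts reproduce the per-region densities", {
  panel <- fixturePanel()
  pub <- read.delim(ampliSNPExample("published_panel_summary.tsv"))
  stats <- regionDensity(panel, setNames(pub$n_variants, pub$index),
                         extra = pub[, c("multiallelic", "transitions",
                                         "transversions", "indels")])
  amp <- stats[stats$level == "amplicon", ]
  expect_equal(amp$snps_per_base[amp$amplicon == 1], 0.055118)  # DLOOPB
  expect_equal(amp$snps_per_base[amp$amplicon == 10], 0.022508)
  tot <- stats[stats$level == "total", ]
  expect_equal(tot$n_variants, 218L)
  expect_equal(tot$snps_per_base, round(218 / 7215, 6))  # 0.030215
  expect_equal(tot$transitions, 196L)
  expect_equal(tot$transversions, 20L)
  expect_equal(tot$indels, 2L)
  # totals row equals column-wise sums of the amplicon rows
  for (cc in c("n_variants", "insert_length", "transitions",
               "transversions", "indels", "multiallelic"))
    expect_equal(tot[[cc]], sum(amp[[cc]]))
})

test_that("region stats aggregate a call set with coverage moments", {
  nf <- deskNoiseFree()
  stats <- regionStats(nf$vcs, nf$design@panel)
  amp <- stats[stats$level == "amplicon", ]
  expect_equal(sum(amp$n_variants), nrow(validatedVariants(nf$vcs)))
  expect_equal(amp$transitions + amp$transversions + amp$insertions +
                 amp$deletions, amp$n_variants)
  expect_equal(amp$snps_per_base,
               round(amp$n_variants / amp$insert_length, 6))
  # coverage moments cross-checked with a direct two-pass computation
  ev <- variantEvidence(nf$vcs)
  ev <- ev[ev$status %in% c("pass_full", "pass_rescue"), ]
  v <- validatedVariants(nf$vcs)
  ev <- ev[ev$variant_id %in% v$variant_id, ]
  sup <- ev$fwd + ev$rev
  tot <- stats[stats$level == "total", ]
  expect_equal(tot$mean_support, round(mean(sup), 1))
  expect_equal(tot$sd_support, round(sqrt(sum((sup - mean(sup))^2) /
                                            (length(sup) - 1)), 1))
})

test_that("sharing summary fractions come from per-variant location counts", {
  nf <- deskNoiseFree()
  sh <- sharingSummary(nf$vcs, nf$design)
  # direct recount over ground-truth carriers
  s <- designSamples(nf$design)
  truth <- nf$truth
  for (i in seq_len(nrow(truth))) {
    carriers <- strsplit(truth$carriers[i], ",")[[1]]
    expected <- length(unique(s$location_id[match(carriers, s$sample_id)]))
    got <- sh$per_variant$n_locations[
      sh$per_variant$variant_id == truth$variant_id[i]]
    expect_equal(got, expected)
  }
  sm <- sh$summary[sh$summary$denominator == "all_variants", ]
  pv <- sh$per_variant
  expect_equal(sm$pct_single_location,
               round(100 * mean(pv$n_locations == 1), 1))
  expect_equal(sm$pct_lt10_locations,
               round(100 * mean(pv$n_locations < 10), 1))
})

test_that("VCF output is anchored, multiallelic-merged and re-readable", {
  skip_if_not_installed("vcfR")
  nf <- deskNoiseFree()
  ref <- nf$design@panel@reference
  tmp <- tempfile(fileext = ".vcf")
  writeVcf(nf$vcs, ref, tmp)
  vcf <- vcfR::read.vcfR(tmp, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  v <- validatedVariants(nf$vcs)

  # round trip: reconstruct (pos, ref, alt) in pipeline convention
  back <- do.call(rbind, lapply(seq_len(nrow(fix)), function(i) {
    pos <- as.integer(fix$POS[i]); REF <- fix$REF[i]
    do.call(rbind, lapply(strsplit(fix$ALT[i], ",")[[1]], function(al) {
      if (nchar(REF) == 1 && nchar(al) == 1)
        data.frame(pos = pos, ref = REF, alt = al)
      else if (nchar(al) < nchar(REF))   # deletion
        data.frame(pos = pos + 1L,
                   ref = substring(REF, 2, nchar(REF) - (nchar(al) - 1L)),
                   alt = "")
      else                               # insertion
        data.frame(pos = pos, ref = "",
                   alt = substring(al, 2, nchar(al) - (nchar(REF) - 1L)))
    }))
  }))
  key <- function(df) sort(paste(df$pos, df$ref, df$alt))
  expect_equal(key(back), key(v))

  # REF fields agree with the reference sequence
  for (i in seq_len(nrow(fix))) {
    pos <- as.integer(fix$POS[i])
    expect_equal(substring(refBases(ref), pos,
                           pos + nchar(fix$REF[i]) - 1L), fix$REF[i])
  }
})

test_that("a constructed multiallelic site emits one record, two ALTs", {
  skip_if_not_installed("vcfR")
  d <- tinyHpDesign(4)
  a <- ampliconTable(d)
  ins <- a$insert_seq[1]
  p_local <- 17L
  ref_b <- substr(ins, p_local, p_local)
  alts <- setdiff(c("A", "C", "G", "T"), ref_b)[1:2]
  mk <- function(alt) { x <- ins; substr(x, p_local, p_local) <- alt; x }
  inserts <- c(rep(mk(alts[1]), 24), rep(mk(alts[2]), 24))
  sample_ids <- rep(c("T01", "T02", "T03", "T04"), each = 12)
  dx <- manualDemux(inserts, sample_ids, rep(1L, 48),
                    rep(c("+", "-"), 24))
  vcs <- callVariants(dx, d)
  expect_equal(nrow(validatedVariants(vcs)), 2L)
  tmp <- tempfile(fileext = ".vcf")
  writeVcf(vcs, d@panel@reference, tmp)
  body <- grep("^#", readLines(tmp), invert = TRUE, value = TRUE)
  expect_equal(length(body), 1L)
  alt_field <- strsplit(body, "\t")[[1]][5]
  expect_setequal(strsplit(alt_field, ",")[[1]], alts)
})

test_that("SNP maps flag novelty against a prior panel", {
  nf <- deskNoiseFree()
  v <- validatedVariants(nf$vcs)
  m0 <- snpMap(nf$vcs, nf$design@panel)
  expect_true(all(m0$status == "novel"))
  prior <- v[, c("pos", "ref", "alt")]
  m1 <- snpMap(nf$vcs, nf$design@panel, prior)
  expect_true(all(m1$status == "known"))
  m2 <- snpMap(nf$vcs, nf$design@panel, prior[1:5, ])
  expect_equal(sum(m2$status == "known") + sum(m2$status == "novel"),
               nrow(v))
  expect_equal(sum(m2$status == "known"), 5L)
  expect_false(is.unsorted(m2$pos))
})
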