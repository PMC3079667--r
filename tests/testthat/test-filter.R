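# The validation cascade: per-stage rules and end-to-end behaviour.

mkEvidence <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(variant_id = r[[1]], sample_id = r[[2]], fwd = r[[3]],
               rev = r[[4]], depth = r[[5]], stringsAsFactors = FALSE)))
}

test_that("double-strand support is required per sample", {
  ev <- mkEvidence(list("v1", "s1", 5L, 0L, 10L),
                   list("v1", "s2", 1L, 1L, 10L),
                   list("v1", "s3", 0L, 0L, 10L))
  out <- filterBothStrands(ev)
  expect_equal(out$both_strand, c(FALSE, TRUE, FALSE))
})

test_that("support thresholds and the rescue clause follow the criteria", {
  th <- filterThresholds()
  # 27 of 28 reads (14 fwd + 13 rev): outright pass
  ev <- mkEvidence(list("v1", "s1", 14L, 13L, 28L))
  expect_equal(filterSupport(ev, th)$status, "pass_full")
  # 9 of 10 (0.90) alone: not enough reads, no rescuer
  ev <- mkEvidence(list("v2", "s1", 5L, 4L, 10L))
  expect_equal(filterSupport(ev, th)$status, "fail")
  # same sample rescued by another passing with 30 of 30
  ev <- mkEvidence(list("v2", "s1", 5L, 4L, 10L),
                   list("v2", "s2", 15L, 15L, 30L))
  expect_equal(filterSupport(ev, th)$status,
               c("pass_rescue", "pass_full"))
  # 8 of 10 (0.80): fails regardless of other samples
  ev <- mkEvidence(list("v3", "s1", 4L, 4L, 10L),
                   list("v3", "s2", 15L, 15L, 30L))
  expect_equal(filterSupport(ev, th)$status, c("fail", "pass_full"))
  # zero covering depth: excluded, not failed
  ev <- mkEvidence(list("v4", "s1", 0L, 0L, 0L))
  expect_equal(filterSupport(ev, th)$status, "excluded")
  # exactly 11 supporting reads passes the strict > 10 rule; 10 does not
  ev <- mkEvidence(list("v5", "s1", 6L, 5L, 11L),
                   list("v6", "s1", 5L, 5L, 10L))
  expect_equal(filterSupport(ev, th)$status, c("pass_full", "fail"))
  # strict-direction mode wants > 10 in each direction separately
  th2 <- filterThresholds(strict_direction = TRUE)
  ev <- mkEvidence(list("v7", "s1", 20L, 5L, 25L),
                   list("v8", "s1", 12L, 11L, 23L))
  expect_equal(filterSupport(ev, th2)$status, c("fail", "pass_full"))
})

test_that("variants found in a single individual are rejected", {
  th <- filterThresholds()
  ev <- filterSupport(mkEvidence(list("v1", "s1", 15L, 15L, 30L)), th)
  expect_false(filterMultiIndividual(ev, th)$validated)
  ev <- filterSupport(mkEvidence(list("v1", "s1", 15L, 15L, 30L),
                                 list("v1", "s2", 14L, 14L, 28L)), th)
  mi <- filterMultiIndividual(ev, th)
  expect_true(mi$validated)
  expect_equal(mi$n_carriers, 2L)
})

test_that("artifact flags match the homopolymer and carry-forward rules", {
  d <- tinyHpDesign(2)
  panel <- d@panel
  a <- ampliconTable(panel)
  run_start <- a$ref_start[1] + 80L   # the AAAA run (insert offset 81-84)
  expect_equal(substring(refBases(panel), run_start, run_start + 3L), "AAAA")

  v <- data.frame(
    variant_id = c("d_hp", "i_cf", "i_ct", "s_sub"),
    amplicon = 1L,
    pos = c(run_start + 1L,         # 1-base deletion inside AAAA
            run_start + 4L,         # A inserted after the C following AAAA
            run_start - 10L,        # 2-bp CT insertion
            run_start + 8L),
    ref = c("A", "", "", substring(refBases(panel), run_start + 8L,
                                   run_start + 8L)),
    alt = c("", "A", "CT", "A"),
    kind = c("deletion", "insertion", "insertion", "substitution"),
    stringsAsFactors = FALSE)
  v$alt[4] <- setdiff(c("A", "C", "G", "T"), v$ref[4])[1]
  out <- flagArtifacts(v, panel, min_hp_len = 3L)
  expect_true(out$flag_hp[1])
  expect_true(out$flag_cf[2])     # inserted A equals ref 1-2 upstream
  expect_false(out$flag_hp[3] || out$flag_cf[3])  # 2-bp event never flagged
  expect_false(out$flag_hp[4] || out$flag_cf[4])
})

test_that("substitutions classify as transitions or transversions", {
  v <- data.frame(variant_id = c("a", "b", "c", "d"),
                  amplicon = 1L, pos = c(10L, 20L, 30L, 30L),
                  ref = c("A", "C", "A", "A"), alt = c("G", "A", "G", "T"),
                  kind = "substitution",
                  validated = c(TRUE, TRUE, TRUE, TRUE),
                  stringsAsFactors = FALSE)
  out <- classifyVariants(v)
  expect_equal(out$class, c("transition", "transversion", "transition",
                            "transversion"))
  # two validated alternates at one position form a multiallelic group
  expect_true(all(!is.na(out$multiallelic_group[3:4])))
  expect_equal(out$multiallelic_group[3], out$multiallelic_group[4])
  expect_true(is.na(out$multiallelic_group[1]))
})

test_that("the cascade keeps exactly the planted variants when noise-free", {
  nf <- deskNoiseFree()
  v <- validatedVariants(nf$vcs)
  expect_setequal(v$variant_id, nf$truth$variant_id)
  tr <- filterTrace(nf$vcs)
  expect_equal(tr$n[tr$stage == "candidates"], nrow(nf$truth))
  expect_true(all(diff(tr$n) <= 0))   # monotone survivor counts
  # carrier sets equal the planted carrier sets
  ev <- variantEvidence(nf$vcs)
  for (i in seq_len(nrow(nf$truth))) {
    planted <- sort(strsplit(nf$truth$carriers[i], ",")[[1]])
    called <- sort(ev$sample_id[ev$variant_id == nf$truth$variant_id[i] &
                                  ev$status %in% c("pass_full",
                                                   "pass_rescue")])
    expect_equal(called, planted)
  }
})

test_that("class counts always sum to the validated total", {
  nf <- deskNoiseFree()
  v <- validatedVariants(nf$vcs)
  expect_equal(sum(v$class == "transition") + sum(v$class == "transversion") +
                 sum(v$class == "insertion") + sum(v$class == "deletion"),
               nrow(v))
})

test_that("an empty pileup yields an empty set with an all-zero trace", {
  d <- tinyHpDesign(2)
  dx <- new("DemuxResult", assignments = data.frame(
    read_id = character(), group_id = integer(), status = character(),
    sample_id = character(), amplicon = integer(), strand = character(),
    insert = character(), mid_err_fwd = integer(),
    mid_err_rev = integer(), stringsAsFactors = FALSE))
  vcs <- callVariants(dx, d)
  expect_equal(nrow(variantTable(vcs)), 0L)
  expect_true(all(filterTrace(vcs)$n == 0L))
})

test_that("homopolymer under-read errors never survive the cascade", {
  d <- tinyHpDesign(4)
  truth <- simulateHaplotypes(d, 2, carrier_counts = 2L,
                              indel_fraction = 0, seed = 71)
  run <- simulateReads(d, truth, coverageModel(25, 0),
                       errorModel(0, 0.2, 0, 0), seed = 72)
  vcs <- callVariants(demultiplexRun(run, d), d)
  v <- validatedVariants(vcs)
  expect_true(all(v$kind == "substitution"))
  expect_setequal(v$variant_id, truth$variant_id)
  # the under-reads do appear as candidates but are flagged and rejected
  cand <- variantTable(vcs)
  dels <- cand[cand$kind == "deletion", ]
  if (nrow(dels)) {
    expect_true(all(dels$flag_hp))
    expect_true(all(dels$reason == "homopolymer-underread"))
  }
})
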