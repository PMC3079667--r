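# Dual-MID assignment, amplicon routing, trimming, reporting.

test_that("noise-free reads all assign back to their true samples", {
  nf <- deskNoiseFree()
  a <- assignments(nf$dx)
  pr <- provenance(nf$run)
  expect_true(all(a$status == "assigned"))
  expect_identical(a$sample_id, pr$sample_id)
  expect_identical(a$amplicon, pr$amplicon)
  expect_identical(a$strand, pr$strand)
  expect_equal(demuxStats(nf$dx)$rate, 100.0)
})

test_that("assignment is orientation invariant with flipped strand", {
  d <- deskDesign()
  sid <- designSamples(d)$sample_id[3]
  read <- taggedRead(d, sid, 2L)
  fwd <- assignRead(read, d, 1L)
  rev <- assignRead(revComp(read), d, 1L)
  expect_equal(fwd$sample_id, sid)
  expect_equal(rev$sample_id, sid)
  expect_equal(fwd$amplicon, rev$amplicon)
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  expect_identical(fwd$insert, rev$insert)   # reference-oriented
})

test_that("reads losing a MID end are unassigned as missing-MID", {
  d <- deskDesign()
  read <- taggedRead(d, designSamples(d)$sample_id[1], 1L)
  chopped <- substr(read, 13, nchar(read))
  expect_equal(assignRead(chopped, d, 1L)$status, "missing-MID")
  tail_chop <- substr(read, 1, nchar(read) - 13L)
  expect_equal(assignRead(tail_chop, d, 1L)$status, "missing-MID")
})

test_that("an unknown MID pair within the group is not rescued", {
  d <- deskDesign()
  s <- designSamples(d)
  # build a read with a pair absent from group 1 (group 1 keeps 12 of 36)
  m <- designMids(d)
  midseq <- setNames(m$sequence, m$id)
  a <- ampliconTable(d)
  pairs <- paste(s$fwd_mid[s$group_id == 1], s$rev_mid[s$group_id == 1])
  absent_fwd <- setdiff(m$id[m$role == "forward"],
                        s$fwd_mid[s$group_id == 1])[1]
  read <- paste0(midseq[[absent_fwd]], a$fwd_primer[1], a$insert_seq[1],
                 revComp(a$rev_primer[1]), revComp(midseq[["MID7"]]))
  expect_false(paste(absent_fwd, "MID7") %in% pairs)
  expect_equal(assignRead(read, d, 1L)$status, "unknown-pair")
})

test_that("reads whose primers match no amplicon are primer-mismatch", {
  d <- deskDesign()
  s <- designSamples(d)
  m <- designMids(d)
  midseq <- setNames(m$sequence, m$id)
  set.seed(51)
  read <- paste0(midseq[[s$fwd_mid[1]]], randSeq(380),
                 revComp(midseq[[s$rev_mid[1]]]))
  expect_equal(assignRead(read, d, 1L)$status, "primer-mismatch")
})

test_that("amplicon routing tolerates up to two primer edits", {
  design <- fixtureDesign()
  panel <- design@panel
  a <- ampliconTable(panel)
  core <- paste0(a$fwd_primer[7], a$insert_seq[7], revComp(a$rev_primer[7]))
  expect_equal(identifyAmplicon(core, panel)$index, 7L)
  set.seed(52)
  mutated <- mutateWindow(core, 3, 10, 1)   # one edit inside fwd primer
  expect_equal(identifyAmplicon(mutated, panel)$index, 7L)
  expect_null(identifyAmplicon(randSeq(400), panel))
})

test_that("trimming returns the exact reference-oriented insert", {
  d <- fixtureDesign()
  a <- ampliconTable(d)
  sid <- designSamples(d)$sample_id[1]
  r <- assignRead(taggedRead(d, sid, 1L), d, 1L)
  expect_equal(nchar(r$insert), a$insert_length[1])  # 381 for amplicon 1
  expect_identical(r$insert, a$insert_seq[1])
  # a read of only MIDs and primers has nothing left after trimming
  m <- designMids(d)
  midseq <- setNames(m$sequence, m$id)
  s <- designSamples(d)
  bare <- paste0(midseq[[s$fwd_mid[1]]], a$fwd_primer[1],
                 revComp(a$rev_primer[1]), revComp(midseq[[s$rev_mid[1]]]))
  expect_true(assignRead(bare, d, 1L)$status %in%
                c("empty-insert", "primer-mismatch"))
})

test_that("reads with up to two planted MID errors per end never misassign", {
  nf <- deskNoiseFree()
  d <- nf$design
  reads <- simReads(nf$run)[1:150]
  pr <- provenance(nf$run)[1:150, ]
  set.seed(53)
  n_checked <- 0L
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    if (pr$strand[i] == "-") r <- revComp(r)
    r <- mutateWindow(r, 1, 10, sample(1:2, 1))
    n <- nchar(r)
    r <- mutateWindow(r, n - 9, n, sample(1:2, 1))
    if (pr$strand[i] == "-") r <- revComp(r)
    got <- assignRead(r, d, pr$group_id[i])
    expect_equal(got$status, "assigned")
    expect_equal(got$sample_id, pr$sample_id[i])
    expect_equal(got$amplicon, pr$amplicon[i])
    expect_true(all(got$mid_errors <= 2L))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 150L)
})

test_that("demux reports partition every read into exactly one category", {
  d <- deskDesign()
  run <- simulateReads(d, simulateHaplotypes(d, 0, seed = 54),
                       coverageModel(8, 2),
                       errorModel(0.002, 0.05, 0.02, 0.1), seed = 55)
  dx <- demultiplexRun(run, d)
  st <- demuxStats(dx)
  expect_equal(st$assigned + st$unassigned, st$total)
  expect_equal(st$assigned + sum(st$by_reason), st$total)
  expect_equal(st$rate, round(100 * st$assigned / st$total, 1))
  # no assigned read contradicts its provenance
  a <- assignments(dx)
  pr <- provenance(run)
  ok <- a$status == "assigned"
  expect_identical(a$sample_id[ok],
                   pr$sample_id[match(a$read_id[ok], pr$read_id)])
})

test_that("an empty read set yields a flagged zero-rate report", {
  dx <- demultiplexReads(character(0), deskDesign(), 1L)
  st <- demuxStats(dx)
  expect_equal(st$total, 0L)
  expect_equal(st$rate, 0)
  expect_true(st$rate_undefined)
})
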