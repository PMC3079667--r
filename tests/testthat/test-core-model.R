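# Domain types, fixture I/O and design validation.

test_that("reference loading validates and normalizes its single record", {
  ref <- fixtureReference()
  expect_s4_class(ref, "ReferenceSequence")
  expect_equal(length(ref), 16700L)
  expect_false(grepl("[^ACGT]", refBases(ref)))

  two <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), two)
  expect_error(loadReference(two), "multi-record")

  amb <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGNT"), amb)
  expect_error(loadReference(amb), "position 4")

  lower <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt"), lower)
  expect_equal(refBases(loadReference(lower)), "ACGT")
})

test_that("the packaged panel covers 7215 insert bp in 20 amplicons", {
  panel <- fixturePanel()
  a <- ampliconTable(panel)
  expect_equal(nrow(a), 20L)
  expect_equal(sum(a$insert_length), 7215L)
  expect_equal(length(unique(a$region)), 10L)
  expect_true(all(a$insert_length == a$ref_end - a$ref_start + 1L))
})

test_that("panel round-trips through write and re-read", {
  panel <- fixturePanel()
  tmp <- tempfile(fileext = ".tsv")
  writePanel(panel, tmp)
  again <- loadPanel(tmp, fixtureReference())
  expect_identical(ampliconTable(again), ampliconTable(panel))
})

test_that("panel loading rejects malformed configurations", {
  ref <- fixtureReference()
  base <- read.delim(ampliSNPExample("panel_synthetic.tsv"))

  bad <- base; bad$ref_end[1] <- bad$ref_start[1] - 1L
  tmp <- tempfile(); write.table(bad, tmp, sep = "\t", row.names = FALSE,
                                 quote = FALSE)
  expect_error(loadPanel(tmp, ref), "ref_end < ref_start")

  bad <- base; bad$insert_length[3] <- bad$insert_length[3] + 1L
  write.table(bad, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadPanel(tmp, ref), "mismatch")

  bad <- base; bad$index[2] <- 1L
  write.table(bad, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadPanel(tmp, ref), "duplicate")

  bad <- base; bad$ref_end[20] <- length(ref) + 10L
  write.table(bad, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadPanel(tmp, ref), "out of reference range")
})

test_that("the sample sheet yields 16 groups of 36 with unique MID pairs", {
  design <- fixtureDesign()
  s <- designSamples(design)
  expect_equal(nrow(s), 576L)
  expect_equal(sort(unique(s$group_id)), 1:16)
  expect_true(all(table(s$group_id) == 36L))
  expect_equal(sum(s$species == "Salmo salar"), 546L)
  # MID pairs are reused across groups (separate plate regions)
  key <- paste(s$fwd_mid, s$rev_mid)
  expect_true(any(table(key) > 1L))
})

test_that("sample sheets breaking traceability are rejected", {
  s <- designSamples(fixtureDesign())
  dup <- rbind(s, within(s[1, ], sample_id <- "DUP"))
  tmp <- tempfile()
  write.table(dup, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadSampleSheet(tmp, fixturePanel(), fixtureMids()),
               "traceability")

  bad <- s; bad$fwd_mid[5] <- "MIDX"
  write.table(bad, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(loadSampleSheet(tmp, fixturePanel(), fixtureMids()),
               "unknown forward MID")
})

test_that("reaction enumeration matches the plate layout arithmetic", {
  design <- fixtureDesign()
  expect_equal(nrow(enumerateReactions(design)), 11520L)
  expect_equal(nrow(enumerateReactions(design, "Salmo salar")), 10920L)

  one <- subsetDesign(design, groups = 1, samples_per_group = 1,
                      amplicons = 1)
  expect_equal(nrow(enumerateReactions(one)), 1L)

  # sum over groups of group size x amplicon count equals the total
  s <- designSamples(design)
  expect_equal(sum(table(s$group_id) * 20L),
               nrow(enumerateReactions(design)))
})

test_that("MID sets below the error-correcting distance are rejected", {
  expect_silent(validateMidSet(fixtureMids()$sequence))
  close_set <- c("AAAAAAAAAA", "AAAAAAAATT", "GGGGGGGGGG")
  expect_error(validateMidSet(close_set), "edit distance")
  expect_error(validateMidSet(c("ACGT")), "10 bp")
  expect_error(validateMidSet(character(0)), "empty")
})
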