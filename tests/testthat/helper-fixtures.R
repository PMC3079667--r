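# Shared fixtures: packaged full-scale design, a desk-scale subset, tiny
# hand-built designs, and memoized simulation runs reused across files.

.fix <- new.env()

fixtureReference <- function() {
  if (is.null(.fix$ref))
    .fix$ref <- loadReference(ampliSNPExample("reference_synthetic.fasta"))
  .fix$ref
}

fixturePanel <- function() {
  if (is.null(.fix$panel))
    .fix$panel <- loadPanel(ampliSNPExample("panel_synthetic.tsv"),
                            fixtureReference())
  .fix$panel
}

fixtureMids <- function() {
  if (is.null(.fix$mids))
    .fix$mids <- loadMids(ampliSNPExample("mids_synthetic.tsv"))
  .fix$mids
}

fixtureDesign <- function() {
  if (is.null(.fix$design))
    .fix$design <- loadSampleSheet(
      ampliSNPExample("sample_sheet_synthetic.tsv"),
      fixturePanel(), fixtureMids())
  .fix$design
}

# desk-scale stand-in for the full 16 x 36 x 20 layout
deskDesign <- function() {
  if (is.null(.fix$desk))
    .fix$desk <- subsetDesign(fixtureDesign(), groups = 1:2,
                              samples_per_group = 12, amplicons = 1:4)
  .fix$desk
}

# noise-free desk-scale run shared by several files: 40 planted variants
# with 2-5 carriers, fixed depth 25, all error rates zero
deskNoiseFree <- function() {
  if (is.null(.fix$nf)) {
    d <- deskDesign()
    truth <- simulateHaplotypes(d, 40, carrier_counts = 2:5,
                                indel_fraction = 0.1, seed = 101)
    run <- simulateReads(d, truth, coverageModel(25, 0),
                         errorModel(0, 0, 0, 0, 3), seed = 102)
    dx <- demultiplexRun(run, d)
    pp <- buildPileup(dx, d)
    vcs <- runCascade(pp, d@panel)
    .fix$nf <- list(design = d, truth = truth, run = run, dx = dx,
                    pileup = pp, vcs = vcs)
  }
  .fix$nf
}

# A tiny single-amplicon design whose insert contains exactly one
# homopolymer run (AAAA) - everything else alternates, so homopolymer
# under-reads have a unique target.
tinyHpDesign <- function(n_samples = 4) {
  unit <- "ACGT"
  insert <- paste0(strrep(unit, 20), "AAAA", strrep("CGTA", 20))
  fwd_p <- "GTCAGTCAGTCAGTCAGTCA"
  rev_site <- "TGACTGACTGACTGACTGAC"
  pad <- strrep("GACT", 10)
  bases <- paste0(pad, fwd_p, insert, rev_site, pad)
  ref <- new("ReferenceSequence", id = "tiny_ref", bases = bases)
  start <- nchar(pad) + nchar(fwd_p) + 1L
  amp <- data.frame(index = 1L, region = "TINY",
                    fwd_primer = fwd_p, rev_primer = revComp(rev_site),
                    ref_start = start, ref_end = start + nchar(insert) - 1L,
                    insert_length = nchar(insert),
                    insert_seq = insert, stringsAsFactors = FALSE)
  panel <- new("AmpliconPanel", reference = ref, amplicons = amp)
  m <- fixtureMids()
  fwd_ids <- m$id[m$role == "forward"]
  rev_ids <- m$id[m$role == "reverse"]
  grid <- expand.grid(f = fwd_ids[1:2], r = rev_ids[1:2],
                      stringsAsFactors = FALSE)
  s <- data.frame(sample_id = sprintf("T%02d", seq_len(n_samples)),
                  species = "Salmo salar",
                  location_id = sprintf("L%02d", seq_len(n_samples)),
                  group_id = 1L,
                  fwd_mid = grid$f[seq_len(n_samples)],
                  rev_mid = grid$r[seq_len(n_samples)],
                  stringsAsFactors = FALSE)
  new("ExperimentDesign", panel = panel, samples = s, mids = m)
}

# hand-built DemuxResult from explicit inserts
manualDemux <- function(inserts, sample_ids, amplicons, strands,
                        group_id = 1L) {
  n <- length(inserts)
  new("DemuxResult", assignments = data.frame(
    read_id = sprintf("m%04d", seq_len(n)), group_id = group_id,
    status = "assigned", sample_id = sample_ids, amplicon = amplicons,
    strand = strands, insert = inserts, mid_err_fwd = 0L, mid_err_rev = 0L,
    stringsAsFactors = FALSE))
}

# the ideal tagged read for a sample's haplotype on one amplicon
taggedRead <- function(design, sample_id, amplicon, insert = NULL) {
  s <- designSamples(design)
  a <- ampliconTable(design)
  m <- designMids(design)
  midseq <- setNames(m$sequence, m$id)
  i <- match(sample_id, s$sample_id)
  k <- match(amplicon, a$index)
  if (is.null(insert)) insert <- a$insert_seq[k]
  paste0(midseq[[s$fwd_mid[i]]], a$fwd_primer[k], insert,
         revComp(a$rev_primer[k]), revComp(midseq[[s$rev_mid[i]]]))
}
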