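# Synthetic-data generator: genome determinism, locus structure, insertion
# planting, the read error channel, and SAM synthesis.

test_that("make_genome is deterministic and seed-sensitive", {
  g1 <- make_genome(5L)
  g2 <- make_genome(5L)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  g3 <- make_genome(6L)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("the synthetic locus has 9 ordered signals and close primer pairs", {
  gm <- shared_gm()
  locus <- gm$locus
  expect_length(locus$polya_signals, 9L)
  expect_equal(locus$polya_signals[[1]]$hexamer, "AATAAA")  # canonical
  ends <- vapply(locus$polya_signals, `[[`, integer(1), "end_coord")
  expect_true(all(diff(ends) > 0))
  expect_equal(locus$tag_start, ends[1] + 1L)  # tag starts after the canonical signal
  # hexamers are physically planted at their coordinates
  for (s in locus$polya_signals)
    expect_equal(ldipcr:::.subseq(gm$genome, "chr1", s$end_coord - 5L, s$end_coord),
                 s$hexamer)
  for (p in locus$primer_pairs) {
    expect_lte(p$inter_primer_distance, 51L)
    expect_gte(p$rev_start, locus$tag_start)
    expect_lte(p$fwd_end, locus$l1_interval[2])
    # primer sequences match the genome
    expect_equal(ldipcr:::.subseq(gm$genome, "chr1", p$fwd_start, p$fwd_end),
                 p$fwd_seq)
    expect_equal(revcomp(ldipcr:::.subseq(gm$genome, "chr1", p$rev_start, p$rev_end)),
                 p$rev_seq)
  }
})

test_that("plant_insertion bookkeeping is exact", {
  gm <- shared_gm()
  glen <- length(gm$genome[["chr2"]])

  # blunt, no twin-priming, no polyA: haplotype grows by the donor span
  spec <- insertion_spec("b", "chr2", 11000L, "blunt", 0L,
                         donor_start = 23001L, donor_end = 23233L,
                         polya_len = 0L, signal_index = 3L)
  pl <- plant_insertion(gm, spec)
  expect_equal(length(pl$haplotype[["chr2"]]), glen + (23233L - 23001L + 1L))
  expect_true(pl$truth$orphan)

  # a 16 bp duplication repeats the target word on both insert flanks
  spec <- insertion_spec("d", "chr2", 17000L, "duplication", 16L,
                         donor_start = 22800L, donor_end = 23230L,
                         polya_len = 25L, signal_index = 3L)
  pl <- plant_insertion(gm, spec)
  hap <- as.character(pl$haplotype[["chr2"]])
  word <- ldipcr:::.subseq(gm$genome, "chr2", 17000L - 15L, 17000L)
  ins_len <- pl$truth$insert_len
  expect_equal(substr(hap, 17000L - 15L, 17000L), word)
  expect_equal(substr(hap, 17000L + ins_len + 1L, 17000L + ins_len + 16L), word)
  expect_equal(ins_len, (23230L - 22800L + 1L) + 25L)
  expect_false(pl$truth$orphan)

  # twin-priming: the insert decomposes into an inverted and a sense donor copy
  spec <- insertion_spec("t", "chr3", 11000L, "deletion", 20L,
                         donor_start = 22650L, donor_end = 23230L,
                         strand = "+", twin_priming = TRUE,
                         inversion_point = 22900L, polya_len = 30L,
                         signal_index = 3L)
  pl <- plant_insertion(gm, spec)
  hap <- as.character(pl$haplotype[["chr3"]])
  insert <- substr(hap, 11001L, 11000L + pl$truth$insert_len)
  inv_len <- 22900L - 22650L + 1L
  expect_equal(substr(insert, 1L, inv_len),
               revcomp(ldipcr:::.subseq(gm$genome, "chr1", 22650L, 22900L)))
  expect_equal(substr(insert, inv_len + 1L, pl$truth$insert_len - 30L),
               ldipcr:::.subseq(gm$genome, "chr1", 22901L, 23230L))
  expect_equal(substr(insert, pl$truth$insert_len - 29L, pl$truth$insert_len),
               strrep("A", 30L))
  # deletion removes target bases: haplotype grows by insert - deletion
  expect_equal(length(pl$haplotype[["chr3"]]),
               length(gm$genome[["chr3"]]) + pl$truth$insert_len - 20L)
})

test_that("spec invariants are enforced", {
  expect_error(insertion_spec("x", "chr2", 5000L, "blunt", 3L,
                              donor_start = 23001L, donor_end = 23233L),
               "tsm_size")
  expect_error(insertion_spec("x", "chr2", 5000L, "duplication", 2L,
                              donor_start = 23000L, donor_end = 23200L,
                              twin_priming = TRUE, inversion_point = 23200L),
               "inversion_point")
  gm <- shared_gm()
  # donor_end outside the stop window of the declared signal
  spec <- insertion_spec("x", "chr2", 5000L, "blunt", 0L,
                         donor_start = 23001L, donor_end = 23260L,
                         signal_index = 3L)
  expect_error(plant_insertion(gm, spec), "stop window")
  # target inside the source locus
  spec2 <- insertion_spec("x", "chr1", 22000L, "blunt", 0L,
                          donor_start = 23001L, donor_end = 23233L,
                          signal_index = 3L)
  expect_error(plant_insertion(gm, spec2), "source locus")
})

test_that("the error channel has the stated rate and a total read-truth map", {
  amp <- random_dna(500)
  # error-free reads equal the amplicon or its reverse complement
  sim0 <- simulate_reads(amp, 20L, 0, seed = 3L)
  for (i in 1:20)
    expect_true(sim0$reads$sequence[i] == amp ||
                  sim0$reads$sequence[i] == revcomp(amp))
  expect_true(all(!is.na(match(sim0$reads$read_id,
                               sprintf("read_%d", 1:20)))))
  expect_equal(anyDuplicated(sim0$reads$read_id), 0L)

  # determinism
  simA <- simulate_reads(amp, 10L, 0.08, seed = 9L)
  simB <- simulate_reads(amp, 10L, 0.08, seed = 9L)
  expect_identical(simA$reads$sequence, simB$reads$sequence)

  # mean edit distance per base within 3 s.d. of the channel expectation
  n <- 150L
  sim <- simulate_reads(amp, n, 0.1, seed = 5L)
  fwd <- ifelse(sim$reads$strand == "+", sim$reads$sequence,
                vapply(sim$reads$sequence, revcomp, ""))
  d <- as.numeric(utils::adist(amp, fwd))
  rate <- mean(d) / nchar(amp)
  tol <- 3 * sqrt(0.1 * 0.9 / nchar(amp))
  expect_lt(abs(rate - 0.1), tol + 0.005)  # small allowance for adjacent-error cancellation

  # position maps are total over surviving bases and single-valued
  for (m in sim$maps[1:5]) {
    kept <- m[!is.na(m)]
    expect_true(all(diff(kept) >= 1L))
  }
})

test_that("synthesized alignments reflect the true read segmentation", {
  gm <- shared_gm()
  # native amplicon: every record within the source fragment, none elsewhere
  nat <- native_amplicon(gm, "SacI", "pp1")
  sim <- simulate_reads(nat, 4L, 0, seed = 2L, prefix = "nat")
  sam <- synthesize_alignments(sim, nat, sample = "s1", reaction = "SacI.pp1")
  recs <- read_sam(c(sam_header(gm$genome), sam))
  expect_true(all(recs$rname == "chr1"))
  expect_true(all(recs$pos >= nat$fragment[1] & recs$pos <= nat$fragment[2]))

  # twin-priming insertion: source segments of both strands plus target records
  spec <- insertion_spec("tw", "chr4", 11000L, "duplication", 8L,
                         donor_start = 22650L, donor_end = 23230L,
                         strand = "+", twin_priming = TRUE,
                         inversion_point = 22900L, polya_len = 30L,
                         signal_index = 3L)
  amp <- insertion_amplicon(gm, spec, "NsiI", "pp1")
  expect_equal(amp$status, "ok")
  sim <- simulate_reads(amp, 3L, 0, seed = 2L, prefix = "tw")
  sam <- synthesize_alignments(sim, amp, sample = "s1", reaction = "NsiI.pp1")
  groups <- read_alignment_groups(c(sam_header(gm$genome), sam))
  for (g in groups) {
    src <- g$segments[g$segments$contig == "chr1" &
                        g$segments$ref_start < 24000L, , drop = FALSE]
    tgt <- g$segments[g$segments$contig == "chr4", , drop = FALSE]
    expect_gte(nrow(src), 2L)
    expect_setequal(unique(src$strand), c("+", "-"))
    expect_gte(nrow(tgt), 1L)
  }

  # MAPQ degradation is honoured (decoy fixture for the caller's filter)
  sam_lo <- synthesize_alignments(sim, amp, sample = "s1",
                                  reaction = "NsiI.pp1", mapq = 19L)
  recs <- read_sam(c(sam_header(gm$genome), sam_lo))
  expect_true(all(recs$mapq == 19L))
})

test_that("clonal fraction maps monotonically to read support", {
  gm <- shared_gm()
  cf <- c(0.2, 0.5, 1.0)
  specs <- lapply(seq_along(cf), function(i)
    insertion_spec(paste0("cf", i), c("chr2", "chr3", "chr4")[i], 11000L,
                   "blunt", 0L, donor_start = 23001L, donor_end = 23233L,
                   polya_len = 30L, signal_index = 3L, clonal_fraction = cf[i]))
  sim <- simulate_ldi_experiment(3L, gm = gm, specs = specs, n_reads = 10L)
  expect_equal(sim$truth$n_reads, c(2L, 5L, 10L))
})

test_that("truth tables and text writers round-trip", {
  gm <- shared_gm()
  specs <- default_insertion_specs(gm, n = 4L, seed = 3L)
  sim <- simulate_ldi_experiment(3L, gm = gm, specs = specs, n_reads = 6L)
  expect_equal(nrow(sim$truth), 4L)
  expect_true(all(sim$truth$n_reads >= 1L))

  tdir <- tempfile(); dir.create(tdir)
  p <- write_truth_tsv(sim$truth, file.path(tdir, "truth.tsv"))
  lines <- readLines(p)
  expect_match(lines[1], "schema")
  back <- utils::read.delim(p, skip = 1L)
  expect_equal(nrow(back), 4L)
  write_sam(sim$sam, file.path(tdir, "aln.sam"))
  expect_gt(length(readLines(file.path(tdir, "aln.sam"))), 8L)
})
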