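# Insertion calling: hallmark detection, breakpoint extraction, clustering,
# modal coordinates, the filter cascade, crosstalk and reaction dedup.

params_for <- function(gm = NULL, ...) {
  if (is.null(gm)) caller_params(l1_interval = c(20001L, 24000L),
                                 l1_chrom = "chr1", ...)
  else caller_params_from_locus(gm$locus, ...)
}

test_that("hallmark reads need one source and one confined target locus", {
  p <- params_for()
  src <- seg_row("chr1", 22000L, 23000L, 1L, 1000L)
  # one source + one target segment: hallmark
  g1 <- make_group("r1", rbind(src, seg_row("chr5", 100L, 600L, 1001L, 1500L)))
  expect_length(find_hallmark_reads(list(g1), p), 1L)
  # target segments on two contigs: rejected
  g2 <- make_group("r2", rbind(src,
                               seg_row("chr5", 100L, 600L, 1001L, 1500L),
                               seg_row("chr7", 100L, 600L, 1501L, 2000L)))
  expect_length(find_hallmark_reads(list(g2), p), 0L)
  # target mapping quality below 20: rejected
  g3 <- make_group("r3", rbind(src, seg_row("chr5", 100L, 600L, 1001L, 1500L,
                                            mapq = 19L)))
  expect_length(find_hallmark_reads(list(g3), p), 0L)
  # two target segments 150 kb apart exceed the span cap
  g4 <- make_group("r4", rbind(src,
                               seg_row("chr5", 100L, 600L, 1001L, 1500L),
                               seg_row("chr5", 150100L, 150600L, 1501L, 2000L)))
  expect_length(find_hallmark_reads(list(g4), p), 0L)
  # source-only read: rejected
  g5 <- make_group("r5", src)
  expect_length(find_hallmark_reads(list(g5), p), 0L)
})

test_that("breakpoints sit on the target side of each alignment switch", {
  p <- params_for()
  src <- seg_row("chr1", 22000L, 23000L, 601L, 1600L)
  # target before source in query: switch at the target's query-right end
  g <- make_group("r1", rbind(seg_row("chr5", 100L, 600L, 1L, 600L), src))
  bp <- extract_breakpoints(g, p)
  expect_equal(bp$coordinate, 600L)
  expect_equal(bp$orientation, "target_to_source")
  # source before target: switch at the target's query-left end
  g <- make_group("r2", rbind(seg_row("chr1", 22000L, 23000L, 1L, 1000L),
                              seg_row("chr5", 700L, 1200L, 1001L, 1500L)))
  bp <- extract_breakpoints(g, p)
  expect_equal(bp$coordinate, 700L)
  expect_equal(bp$orientation, "source_to_target")
  # reverse-strand target: the query-adjacent end flips in reference space
  g <- make_group("r3", rbind(seg_row("chr1", 22000L, 23000L, 1L, 1000L),
                              seg_row("chr5", 700L, 1200L, 1001L, 1500L,
                                      strand = "-")))
  expect_equal(extract_breakpoints(g, p)$coordinate, 1200L)
})

test_that("single-linkage clustering respects the gap and input order", {
  bp <- data.frame(contig = "chr5", coordinate = c(7000L, 100L, 2900L),
                   orientation = "source_to_target", read_id = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  cl <- cluster_breakpoints(bp, 3000L)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(sort(cl$coordinate[cl$cluster == cl$cluster[cl$coordinate == 100L]]),
               c(100L, 2900L))
  set.seed(41)
  for (i in 1:5) {
    sh <- bp[sample(nrow(bp)), , drop = FALSE]
    cl2 <- cluster_breakpoints(sh, 3000L)
    expect_equal(cl2[order(cl2$coordinate), c("coordinate", "cluster")],
                 cl[order(cl$coordinate), c("coordinate", "cluster")])
  }
})

test_that("the called coordinate is the mode, ties to the smallest", {
  expect_equal(call_coordinate(c(rep(500L, 7), rep(503L, 2))), 500L)
  expect_equal(call_coordinate(c(rep(501L, 3), rep(500L, 3))), 500L)
  expect_equal(call_coordinate(c(rep(100L, 2), rep(99L, 5))), 99L)
})

test_that("filters are inclusive at their published boundaries", {
  p <- params_for()
  cut_maps <- list(NsiI = list(chr5 = c(1000L, 5000L), chrM = c(50L)))
  mk <- function(contig, coord, n) data.frame(
    sample = "s1", reaction = "NsiI.pp1", contig = contig, coordinate = coord,
    read_count = n, reads = paste(seq_len(n), collapse = ","),
    stringsAsFactors = FALSE)
  calls <- rbind(mk("chr5", 3000L, 4L),   # one read short of the support floor
                 mk("chr5", 3000L, 5L),   # at the support floor
                 mk("chr5", 1034L, 9L),   # 34 bp from a cut site
                 mk("chr5", 1035L, 9L),   # exactly 35 bp away
                 mk("chrM", 3000L, 9L))   # mitochondrial contig
  f <- filter_calls(calls, cut_maps, p)
  expect_equal(f$fail_support, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(f$fail_cut_distance, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(f$fail_contig, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(f$status, c("fail", "pass", "fail", "pass", "fail"))
  expect_error(filter_calls(mk("chr5", 10L, 9L), list(), p), "cut map")
})

test_that("crosstalk keeps only a >=95% majority sample", {
  p <- params_for()
  mk <- function(sample, coord, n) data.frame(
    sample = sample, reaction = "NsiI.pp1", contig = "chr5",
    coordinate = coord, read_count = n, reads = "r", status = "pass",
    stringsAsFactors = FALSE)
  # 990 vs 10: the major sample keeps the call
  r <- resolve_crosstalk(rbind(mk("A", 1000L, 990L), mk("B", 1001L, 10L)), p)
  expect_equal(r$fail_crosstalk[r$sample == "A"], FALSE)
  expect_equal(r$fail_crosstalk[r$sample == "B"], TRUE)
  # 60/40: nobody reaches the majority, both are removed
  r <- resolve_crosstalk(rbind(mk("A", 1000L, 60L), mk("B", 1001L, 40L)), p)
  expect_true(all(r$fail_crosstalk))
  # single-sample calls are untouched
  r <- resolve_crosstalk(mk("A", 1000L, 7L), p)
  expect_false(any(r$fail_crosstalk))
})

test_that("reaction dedup keeps the strongest reaction per insertion", {
  p <- params_for()
  mk <- function(reaction, n) data.frame(
    sample = "s1", reaction = reaction, contig = "chr5", coordinate = 1000L,
    read_count = n, reads = "r", status = "pass", fail_crosstalk = FALSE,
    stringsAsFactors = FALSE)
  d <- dedup_reactions(rbind(mk("PstI.pp1", 12L), mk("SacI.pp1", 55L)), p)
  expect_equal(nrow(d), 1L)
  expect_equal(d$reaction, "SacI.pp1")
  expect_equal(d$read_count, 55L)
  expect_equal(d$all_reactions, "PstI.pp1,SacI.pp1")
  # three-way tie resolves to the lexicographically first label
  d <- dedup_reactions(rbind(mk("SacI.pp1", 9L), mk("PstI.pp1", 9L),
                             mk("NsiI.pp1", 9L)), p)
  expect_equal(d$reaction, "NsiI.pp1")
  # a single-reaction call is returned as itself
  d <- dedup_reactions(mk("PstI.pp1", 7L), p)
  expect_equal(d$reaction, "PstI.pp1")
})

test_that("the pipeline is deterministic under record shuffling", {
  gm <- shared_gm()
  specs <- default_insertion_specs(gm, n = 6L, seed = 13L)
  sim <- simulate_ldi_experiment(13L, gm = gm, specs = specs, n_reads = 8L)
  p <- params_for(gm)
  cmaps <- shared_cut_maps(gm)
  header <- sim$sam[startsWith(sim$sam, "@")]
  body <- sim$sam[!startsWith(sim$sam, "@")]
  ref <- call_insertions(read_alignment_groups(c(header, body)), p, cmaps)
  set.seed(99)
  shuf <- call_insertions(read_alignment_groups(c(header, sample(body))), p, cmaps)
  rownames(ref) <- rownames(shuf) <- NULL
  expect_equal(shuf, ref)
  # every planted insertion is recovered at its exact coordinate
  hit <- vapply(seq_len(nrow(sim$truth)), function(i)
    any(ref$status == "pass" & ref$contig == sim$truth$chrom[i] &
          ref$coordinate == sim$truth$expected_call[i]), logical(1))
  expect_true(all(hit))
  expect_equal(sum(ref$status == "pass"), nrow(sim$truth))
})

test_that("pass calls always satisfy every filter", {
  gm <- shared_gm()
  specs <- default_insertion_specs(gm, n = 4L, seed = 17L)
  sim <- simulate_ldi_experiment(17L, gm = gm, specs = specs, n_reads = 6L)
  p <- params_for(gm)
  calls <- call_insertions(read_alignment_groups(sim$sam), p, shared_cut_maps(gm))
  pass <- calls[calls$status == "pass", ]
  expect_true(all(!pass$fail_support & !pass$fail_cut_distance &
                    !pass$fail_contig & !pass$fail_crosstalk))
})
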