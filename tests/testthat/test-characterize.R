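# Consensus characterization: segmentation, target-site modification,
# twin-priming, microhomology, polyadenylation-signal assignment, orphan
# classification and insertion length.

# construct a synthetic consensus from explicit pieces against two synthetic
# reference windows; returns everything needed for segment_consensus
# force seq[pos] to differ from `avoid` (kills coincidental one-base junction
# homology so the expected values of constructed fixtures are exact)
ensure_diff <- function(seq, pos, avoid) {
  if (substr(seq, pos, pos) %in% avoid)
    substr(seq, pos, pos) <- setdiff(c("A", "C", "G", "T"), avoid)[1]
  seq
}

build_case <- function(seed = 61, tsd = 10L, polya = 30L, donor_span = 400L,
                       mh5 = 0L, twin = FALSE, inv_at = 200L, mh_inv = 0L,
                       tsm_type = "duplication") {
  set.seed(seed)
  target <- random_dna(2000)
  source <- random_dna(1200)
  t_pos <- 1000L            # insertion point inside the target window
  d1 <- 301L; d2 <- d1 + donor_span - 1L   # donor interval in source coords
  r0 <- if (tsm_type == "duplication") t_pos - tsd + 1L else t_pos + tsd + 1L
  inv_abs <- d1 + inv_at - 1L
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  at <- function(s, p) substr(s, p, p)
  # pin down junction boundaries (before planting anything derived from them)
  # so homologies are exactly as planted
  if (!twin) {
    source <- ensure_diff(source, d1 - 1L, at(target, t_pos))
  } else {
    source <- ensure_diff(source, d1 - 1L, comp1(at(target, t_pos)))
    source <- ensure_diff(source, inv_abs, comp1(at(target, t_pos + 1L)))
  }
  # microhomology = junction bases matching BOTH references: make the donor's
  # first bases (in source coordinates) equal the target continuation
  if (mh5 > 0L)
    substr(source, d1, d1 + mh5 - 1L) <- substr(target, t_pos + 1L,
                                                t_pos + mh5)
  if (twin && mh_inv > 0L)
    # the sense segment's first bases also extend the inverted segment:
    # they must equal the reverse complement of the bases preceding the donor
    substr(source, inv_abs + 1L, inv_abs + mh_inv) <-
      revcomp(substr(source, d1 - mh_inv, d1 - 1L))
  # and the bases just past each homology word must break the match
  if (!twin) {
    source <- ensure_diff(source, d1 + mh5, at(target, t_pos + mh5 + 1L))
  } else {
    source <- ensure_diff(source, inv_abs + 1L + mh_inv,
                          comp1(at(source, d1 - mh_inv - 1L)))
  }
  # polyA boundaries on both sides
  source <- ensure_diff(source, d2, "A")
  source <- ensure_diff(source, d2 + 1L, "A")
  target <- ensure_diff(target, r0 - 1L, "A")
  target <- ensure_diff(target, r0, "A")
  left <- substr(target, 1, t_pos)
  right <- substr(target, r0, 2000L)
  donor <- substr(source, d1, d2)
  insert <- if (twin)
    paste0(revcomp(substr(donor, 1L, inv_at)),
           substr(donor, inv_at + 1L, nchar(donor)))
  else donor
  insert <- paste0(insert, strrep("A", polya))
  consensus <- paste0(left, insert, right)
  list(consensus = consensus,
       target_window = list(chrom = "chrT", offset = 1L, seq = target),
       source_window = list(chrom = "chrS", offset = 1L, seq = source),
       t_pos = t_pos, d1 = d1, d2 = d2, tsd = tsd, polya = polya,
       inv_at = inv_abs)
}

linear_params <- characterize_params()

test_that("a simple TPRT insertion segments into the canonical four parts", {
  cs <- build_case(seed = 61, tsd = 16L)
  seg <- segment_consensus(cs$consensus, cs$target_window, cs$source_window,
                           linear_params)
  expect_equal(seg$status, "ok")
  expect_equal(seg$segments$label,
               c("target5", "donor", "polyA", "target3"))
  tsm <- call_tsm(seg)
  expect_equal(tsm$tsm_type, "duplication")
  expect_equal(tsm$tsm_size, 16L)
  d <- seg$segments[seg$segments$label == "donor", ]
  expect_equal(c(d$ref_start, d$ref_end), c(cs$d1, cs$d2))
  il <- insertion_length(seg, linear_params)
  expect_equal(il$insertion_len, (cs$d2 - cs$d1 + 1L) + cs$polya)
  expect_true(il$complete)
})

test_that("twin-priming yields two donor orientations and the split point", {
  cs <- build_case(seed = 62, tsd = 8L, twin = TRUE, inv_at = 180L)
  seg <- segment_consensus(cs$consensus, cs$target_window, cs$source_window,
                           linear_params)
  expect_equal(seg$status, "ok")
  d <- seg$segments[seg$segments$label == "donor", ]
  expect_equal(nrow(d), 2L)
  expect_setequal(d$strand, c("+", "-"))
  tp <- detect_twin_priming(seg)
  expect_true(tp$twin_priming)
  expect_equal(tp$strand, "+")
  expect_equal(tp$inversion_point, cs$inv_at)
  expect_false(tp$complex)
})

test_that("a single-orientation donor is not twin-priming", {
  cs <- build_case(seed = 63)
  seg <- segment_consensus(cs$consensus, cs$target_window, cs$source_window,
                           linear_params)
  tp <- detect_twin_priming(seg)
  expect_false(tp$twin_priming)
  expect_true(is.na(tp$inversion_point))
})

test_that("target-site modification calls follow the junction geometry", {
  mkseg <- function(t5_end, t3_start) make_segmentation(rbind(
    seg_row("chrT", 500L, t5_end, 1L, 400L),
    seg_row("chrT", t3_start, 2000L, 501L, 1500L)) |>
      transform(label = c("target5", "target3"), chrom = contig))
  expect_equal(call_tsm(mkseg(1000L, 1001L))$tsm_type, "blunt")
  expect_equal(call_tsm(mkseg(1000L, 1001L))$tsm_size, 0L)
  expect_equal(call_tsm(mkseg(1000L, 985L)),
               list(tsm_type = "duplication", tsm_size = 16L,
                    t5 = 1000L, t3 = 985L))
  expect_equal(call_tsm(mkseg(1000L, 1094L)),
               list(tsm_type = "deletion", tsm_size = 93L,
                    t5 = 1000L, t3 = 1094L))
  # classification is a partition: exactly one type for any geometry
  set.seed(64)
  for (k in 1:40) {
    t3 <- 1000L + sample(-50:50, 1L)
    tsm <- call_tsm(mkseg(1000L, t3))
    expect_length(tsm$tsm_type, 1L)
    expect_true(tsm$tsm_type %in% c("duplication", "blunt", "deletion"))
    expect_equal(tsm$tsm_size == 0L, tsm$tsm_type == "blunt")
  }
})

test_that("deletions of planted size are recovered end to end", {
  cs <- build_case(seed = 65, tsd = 93L, tsm_type = "deletion")
  seg <- segment_consensus(cs$consensus, cs$target_window, cs$source_window,
                           linear_params)
  tsm <- call_tsm(seg)
  expect_equal(tsm$tsm_type, "deletion")
  expect_equal(tsm$tsm_size, 93L)
})

test_that("microhomology is the junction overlap, clipped to the scan cap", {
  # disjoint query intervals give zero
  cs0 <- build_case(seed = 66, mh5 = 0L)
  seg0 <- segment_consensus(cs0$consensus, cs0$target_window, cs0$source_window,
                            linear_params)
  expect_equal(measure_microhomology(seg0, "5prime", linear_params), 0L)
  # planted 3 bp of shared sequence at the 5' junction
  cs3 <- build_case(seed = 67, mh5 = 3L)
  seg3 <- segment_consensus(cs3$consensus, cs3$target_window, cs3$source_window,
                            linear_params)
  expect_equal(measure_microhomology(seg3, "5prime", linear_params), 3L)
  # 13 bp, the top of the observed range
  cs13 <- build_case(seed = 68, mh5 = 13L)
  seg13 <- segment_consensus(cs13$consensus, cs13$target_window,
                             cs13$source_window, linear_params)
  expect_equal(measure_microhomology(seg13, "5prime", linear_params), 13L)
  # inversion-point microhomology in a twin-priming insertion
  cst <- build_case(seed = 69, twin = TRUE, inv_at = 190L, mh_inv = 4L)
  segt <- segment_consensus(cst$consensus, cst$target_window, cst$source_window,
                            linear_params)
  expect_equal(measure_microhomology(segt, "inversion", linear_params), 4L)
})

test_that("polyadenylation-signal windows are inclusive with nearest fallback", {
  signals <- lapply(1:9, function(k)
    polya_signal(k, if (k == 1) "AATAAA" else "ATTAAA", 1000L + 80L * (k - 1L)))
  p <- characterize_params()
  asn <- function(x) assign_polya_signal(x, signals = signals, direction = 1L,
                                         params = p)
  # exhaustive sweep over every coordinate around all nine windows
  for (k in 1:9) {
    e <- signals[[k]]$end_coord
    for (d in 10:30) {
      r <- asn(e + d)
      expect_equal(r$signal_index, k)
      expect_true(r$in_window)
      expect_equal(r$distance, 0L)
    }
    r <- asn(e + 9L)   # one short of the window
    expect_false(r$in_window)
    expect_equal(r$distance, 1L)
  }
  # beyond the last window: nearest edge, distance reported
  r <- asn(signals[[9]]$end_coord + 39L)
  expect_equal(r$signal_index, 9L)
  expect_false(r$in_window)
  expect_equal(r$distance, 9L)
  # between windows 5 and 6: 2 bp from window 6, 7 bp from window 5
  e5 <- signals[[5]]$end_coord
  x <- e5 + 37L  # window5 ends e5+30, window6 starts e5+80+10
  expect_equal(asn(x)$signal_index, 5L)
  x6 <- signals[[6]]$end_coord + 8L  # 2 bp before window 6; 58 past window 5
  expect_equal(asn(x6)$signal_index, 6L)
  # translation invariance
  shifted <- lapply(signals, function(s)
    polya_signal(s$index, s$hexamer, s$end_coord + 10000L))
  r1 <- asn(signals[[4]]$end_coord + 22L)
  r2 <- assign_polya_signal(signals[[4]]$end_coord + 10000L + 22L,
                            signals = shifted, direction = 1L, params = p)
  expect_equal(r1, r2)
  expect_error(assign_polya_signal(5L, signals = list(), direction = 1L,
                                   params = p), "empty")
})

test_that("orphan classification is a boundary on the tag start", {
  gm <- shared_gm()
  expect_true(classify_orphan(gm$locus$tag_start, gm$locus))
  expect_true(classify_orphan(gm$locus$tag_start + 50L, gm$locus))
  expect_false(classify_orphan(gm$locus$tag_start - 1L, gm$locus))
})

test_that("a missing 3' flank yields a lower-bound length", {
  segs <- rbind(seg_row("chrT", 500L, 1000L, 1L, 501L),
                seg_row("chrS", 301L, 700L, 502L, 901L))
  segs$label <- c("target5", "donor")
  segs$chrom <- segs$contig
  seg <- make_segmentation(segs, status = "ok")
  il <- insertion_length(seg, linear_params)
  expect_equal(il$insertion_len, 400L)
  expect_false(il$complete)
})

test_that("native consensus is classified native", {
  gm <- shared_gm()
  nat <- native_amplicon(gm, "SacI", "pp1")
  tw <- list(chrom = "chr2", offset = 9000L,
             seq = ldipcr:::.subseq(gm$genome, "chr2", 9000L, 13000L))
  sw <- list(chrom = "chr1", offset = 20001L,
             seq = ldipcr:::.subseq(gm$genome, "chr1", 20001L, 24000L))
  seg <- segment_consensus(nat$sequence, tw, sw, linear_params)
  expect_equal(seg$status, "native")
})

test_that("characterize_insertion recovers a planted insertion exactly", {
  gm <- shared_gm()
  # pick junction-unambiguous parameters so exact recovery is well defined
  spec <- NULL
  for (strand in c("-", "+")) for (tsm in 10L:20L) {
    for (inv in seq(22850L, 22990L, by = 10L)) for (de in 23230L:23250L) {
      cand <- insertion_spec("cx", "chr2", 23000L, "duplication", tsm,
                             donor_start = 22650L, donor_end = de,
                             strand = strand, twin_priming = TRUE,
                             inversion_point = inv, polya_len = 34L,
                             signal_index = 3L)
      if (ldipcr:::.junctions_clean(gm, cand)) { spec <- cand; break }
    }
    if (!is.null(spec)) break
  }
  expect_false(is.null(spec))
  if (is.null(spec)) skip("no junction-clean twin specification at this locus")
  amp <- insertion_amplicon(gm, spec, "PstI", "pp1")
  expect_equal(amp$status, "ok")
  call <- data.frame(sample = "s1", contig = "chr2",
                     coordinate = min(amp$junction5, amp$junction3),
                     read_count = 10L, stringsAsFactors = FALSE)
  ch <- characterize_insertion(amp$sequence, call, gm$genome, gm$locus,
                               characterize_params(target_halfwidth = 3000L))
  expect_equal(ch$status, "ok")
  expect_equal(ch$tsm_type, "duplication")
  expect_equal(ch$tsm_size, spec$tsm_size)
  expect_equal(ch$strand, spec$strand)
  expect_true(ch$twin_priming)
  expect_equal(ch$inversion_point, spec$inversion_point)
  expect_equal(ch$donor_start, 22650L)
  expect_equal(ch$donor_end, spec$donor_end)
  expect_equal(ch$polya_len, 34L)
  expect_equal(ch$signal_index, 3L)
  expect_false(ch$orphan)
  expect_true(ch$complete)
  expect_equal(ch$insertion_len, (spec$donor_end - 22650L + 1L) + 34L)
})
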