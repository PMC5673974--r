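# Insertion characterization: realign a polished consensus amplicon to the
# source-locus and target windows, decompose it into labelled segments
# (target flanks, donor, polyA), and derive the retrotransposition hallmarks:
# target-site modification, twin-priming inversion point, junction
# microhomology, polyA tail and terminating polyadenylation signal, orphan
# status, and insertion length.

#' Characterization parameters
#'
#' @param target_halfwidth half-width of the target reference window centered
#'   on the call coordinate (default 10 kb).
#' @param polya_min_len,polya_min_frac a polyA (or polyT, for minus-strand
#'   inserts) run must be at least `polya_min_len` bases with at least
#'   `polya_min_frac` of the dominant base after strand normalization.
#' @param stop_lo,stop_hi polyadenylation stop window: transcript cleavage
#'   occurs `stop_lo`--`stop_hi` bp downstream of the signal (default 10--30,
#'   both edges inclusive).
#' @param mh_max maximum microhomology scan in bp.
#' @param min_segment_score,min_segment_len local-alignment acceptance
#'   thresholds for consensus segmentation.
#' @param merge_gap maximum reference gap when merging colinear donor segments
#'   (bridges the unsequenced inter-primer gap; default 80 bp).
#' @param max_unexplained maximum internal unaligned run for an insertion to
#'   still count as completely resolved.
#' @param seg_match,seg_mismatch,seg_gap_open,seg_gap_extend segmentation
#'   local-alignment scores. The mismatch cost is deliberately severe so that
#'   unrelated sequence is never crossed diagonally: an alignment spanning two
#'   segments must do so through a long gap, which the block decomposition
#'   then splits at segment boundaries.
#' @param refine_window junction-refinement window in bp: each segment end
#'   facing a junction is reset to its maximal perfect-match extension within
#'   this many bases (0 disables refinement).
#' @return An object of class `characterize_params`.
#' @export
characterize_params <- function(target_halfwidth = 10000L, polya_min_len = 10L,
                                polya_min_frac = 0.9, stop_lo = 10L,
                                stop_hi = 30L, mh_max = 50L,
                                min_segment_score = 40L, min_segment_len = 20L,
                                merge_gap = 80L, max_unexplained = 25L,
                                seg_match = 2L, seg_mismatch = -8L,
                                seg_gap_open = 5L, seg_gap_extend = 2L,
                                refine_window = 25L) {
  stopifnot(stop_lo >= 10L, stop_lo < stop_hi)
  structure(as.list(environment()), class = "characterize_params")
}

.subst_matrix_n <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- mismatch - 1L; m[, "N"] <- mismatch - 1L
  m
}

.local_align <- function(piece, refseq, params) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(piece), Biostrings::DNAString(refseq),
    type = "local",
    substitutionMatrix = .subst_matrix_n(params$seg_match, params$seg_mismatch),
    gapOpening = params$seg_gap_open, gapExtension = params$seg_gap_extend)
  p <- Biostrings::pattern(pa); s <- Biostrings::subject(pa)
  list(score = Biostrings::score(pa),
       q_start = Biostrings::start(p), q_end = Biostrings::end(p),
       s_start = Biostrings::start(s), s_end = Biostrings::end(s),
       aligned_p = as.character(Biostrings::alignedPattern(pa)),
       aligned_s = as.character(Biostrings::alignedSubject(pa)))
}

# Decompose a local alignment into well-supported blocks. A single alignment
# can legitimately bridge an unrelated insert when the flanking matches pay
# for crossing it (through gaps and chance matches), so the alignment is
# re-read as a chain of anchors -- runs of at least `anchor` consecutive match
# columns -- and split wherever the stretch between anchors spans at least
# `split_gap` query or subject bases. The bridged query stretches are
# reported separately for re-segmentation. Coordinates are 1-based
# pattern/subject positions.
.alignment_blocks <- function(al, split_gap, anchor = 10L) {
  pc <- strsplit(al$aligned_p, "")[[1]]
  sc <- strsplit(al$aligned_s, "")[[1]]
  n <- length(pc)
  qc <- pc != "-"; scons <- sc != "-"
  qpos <- al$q_start - 1L + cumsum(qc)
  spos <- al$s_start - 1L + cumsum(scons)
  is_match <- qc & scons & pc == sc
  # anchor runs of consecutive matches
  r <- rle(is_match)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  anchors <- which(r$values & r$lengths >= anchor)
  if (length(anchors) == 0L)
    return(list(blocks = list(), gaps = list()))
  blocks <- list(); gaps <- list()
  cur <- c(start = run_start[anchors[1]], end = run_end[anchors[1]])
  if (length(anchors) > 1L) for (k in anchors[-1]) {
    between_q <- qpos[run_start[k] - 1L] - qpos[cur["end"]]
    between_s <- spos[run_start[k] - 1L] - spos[cur["end"]]
    if (max(between_q, between_s) >= split_gap) {
      blocks[[length(blocks) + 1L]] <- cur
      if (between_q > 0L)
        gaps[[length(gaps) + 1L]] <- c(qpos[cur["end"]] + 1L,
                                       qpos[cur["end"]] + between_q)
      cur <- c(start = run_start[k], end = run_end[k])
    } else cur["end"] <- run_end[k]
  }
  blocks[[length(blocks) + 1L]] <- cur
  blocks <- lapply(blocks, function(b) {
    i <- b[["start"]]; j <- b[["end"]]
    c(q1 = qpos[i], q2 = qpos[j], s1 = spos[i], s2 = spos[j])
  })
  list(blocks = blocks, gaps = gaps)
}

# longest window of `x` (a character vector of bases) with at least `frac` of
# base `b` and length >= min_len; returns c(start, end) or NULL
.best_homopolymer_run <- function(x, b, min_len, frac) {
  n <- length(x)
  if (n < min_len) return(NULL)
  is_b <- as.integer(x == b)
  best <- NULL; lo <- 1L; cnt <- 0L
  for (hi in seq_len(n)) {
    cnt <- cnt + is_b[hi]
    while (cnt < frac * (hi - lo + 1L)) { cnt <- cnt - is_b[lo]; lo <- lo + 1L }
    if (hi - lo + 1L >= min_len && (is.null(best) || hi - lo > best[2] - best[1]))
      best <- c(lo, hi)
  }
  # trim to the dominant base at both ends
  if (!is.null(best)) {
    while (best[1] < best[2] && x[best[1]] != b) best[1] <- best[1] + 1L
    while (best[2] > best[1] && x[best[2]] != b) best[2] <- best[2] - 1L
  }
  best
}

# Query->reference offset of a segment near one of its ends. The segment's
# own end coordinates can be corrupted by spurious alignment extension, so the
# offset is chosen among candidates derived from both ends (each +/- 3) by
# scoring matches over an interior probe region adjacent to the refined side.
.local_offset <- function(sg, side, rf, base_at, window) {
  # offset convention: "+": ref = q + o;  "-": ref = o - q
  if (sg$strand == "+") {
    o1 <- sg$ref_start - sg$q_start; o2 <- sg$ref_end - sg$q_end
  } else {
    o1 <- sg$ref_end + sg$q_start; o2 <- sg$ref_start + sg$q_end
  }
  prefer <- if (side == "start") o1 else o2
  cands <- unique(c(prefer, o1 + -6:6, o2 + -6:6))
  # probe immediately inside the refined end: further in, a genuine internal
  # indel (e.g. the bridged inter-primer gap) would shift the offset
  probe <- if (side == "start")
    seq(sg$q_start, min(sg$q_end, sg$q_start + window - 1L))
  else
    seq(max(sg$q_start, sg$q_end - window + 1L), sg$q_end)
  exp_base <- function(q, o) {
    pos <- if (sg$strand == "+") q + o else o - q
    idx <- pos - rf$offset + 1L
    if (idx < 1L || idx > nchar(rf$seq)) return("!")
    b <- substr(rf$seq, idx, idx)
    if (sg$strand == "-") .comp1(b) else b
  }
  scores <- vapply(cands, function(o)
    mean(vapply(probe, function(q) base_at(q) == exp_base(q, o), logical(1))),
    numeric(1))
  list(offset = cands[which.max(scores)], exp_base = exp_base)
}

.refine_junctions <- function(segs, seq, L, refs, window = 25L) {
  base_at <- function(q) substr(seq, ((q - 1L) %% L) + 1L, ((q - 1L) %% L) + 1L)
  ref_of <- function(label) {
    for (r in refs) if (r$name == label) return(r)
    NULL
  }
  # maximal perfect extension of segment i on one side; returns the refined
  # junction-side query coordinate and the matching reference coordinate
  extend <- function(i, side) {
    sg <- segs[i, ]
    if (sg$label == "polyA") {
      b <- if (sg$strand == "+") "A" else "T"
      if (side == "end") {
        q <- max(sg$q_start, sg$q_end - window); e <- q - 1L
        while (q <= sg$q_end + window && base_at(q) == b) { e <- q; q <- q + 1L }
        if (e >= sg$q_start) segs$q_end[i] <<- e
      } else {
        q <- min(sg$q_end, sg$q_start + window); s <- q + 1L
        while (q >= sg$q_start - window && base_at(q) == b) { s <- q; q <- q - 1L }
        if (s <= sg$q_end) segs$q_start[i] <<- s
      }
      return(invisible())
    }
    rf <- ref_of(sg$label)
    if (is.null(rf)) return(invisible())
    lo <- .local_offset(sg, side, rf, base_at, window)
    if (side == "end") {
      q <- max(sg$q_start, sg$q_end - window); e <- q - 1L
      while (q <= sg$q_end + window &&
             base_at(q) == lo$exp_base(q, lo$offset)) { e <- q; q <- q + 1L }
      if (e >= sg$q_start) {
        segs$q_end[i] <<- e
        if (sg$strand == "+") segs$ref_end[i] <<- e + lo$offset
        else segs$ref_start[i] <<- lo$offset - e
      }
    } else {
      q <- min(sg$q_end, sg$q_start + window); s <- q + 1L
      while (q >= sg$q_start - window &&
             base_at(q) == lo$exp_base(q, lo$offset)) { s <- q; q <- q - 1L }
      if (s <= sg$q_end) {
        segs$q_start[i] <<- s
        if (sg$strand == "+") segs$ref_start[i] <<- s + lo$offset
        else segs$ref_end[i] <<- lo$offset - s
      }
    }
    invisible()
  }
  for (i in seq_len(nrow(segs) - 1L)) {
    if (segs$q_start[i + 1L] - segs$q_end[i] - 1L > window) next  # not a junction
    extend(i, "end")
    extend(i + 1L, "start")
  }
  segs
}

#' Segment a consensus amplicon against its reference windows
#'
#' Greedy chaining of best local alignments of the consensus against the
#' target window and the source-locus window (both strands), followed by polyA
#' / polyT homopolymer recognition in the unaligned remainder. The consensus
#' is orientation-normalized so target segments sit on the plus strand, the
#' amplicon's circular permutation (the ligation junction lies inside the
#' read) is resolved by rotating the segmentation so the 5' target flank comes
#' first, and donor segments that are colinear across the unsequenced
#' inter-primer gap are merged.
#'
#' @param consensus a `consensus_seq` or a plain sequence.
#' @param target_window list: `chrom`, `offset` (reference coordinate of the
#'   window's first base) and `seq`.
#' @param source_window same shape, for the source-locus window.
#' @param params a [characterize_params()].
#' @return An object of class `segmentation`: `status` (`"ok"`, `"native"`,
#'   or `"uncharacterizable"`), `segments` (ordered data.frame with `label`
#'   in `target5`/`donor`/`polyA`/`target3`/`target`/`source`, query and
#'   reference intervals, `strand`), `length`, `flipped`, `unexplained`
#'   (internal unaligned query bases between the flanks).
#' @export
segment_consensus <- function(consensus, target_window, source_window,
                              params = characterize_params()) {
  seq <- if (inherits(consensus, "consensus_seq")) consensus$sequence else consensus
  seq <- toupper(seq)
  L <- nchar(seq)
  refs <- list(
    list(name = "target", chrom = target_window$chrom,
         offset = target_window$offset, seq = toupper(target_window$seq)),
    list(name = "source", chrom = source_window$chrom,
         offset = source_window$offset, seq = toupper(source_window$seq)))
  for (i in seq_along(refs)) refs[[i]]$rc <- .revcomp(refs[[i]]$seq)

  margin <- 20L
  work <- list(c(1L, L))
  segs <- list()
  unexplained <- list()
  iter <- 0L
  while (length(work) > 0L && iter < 40L) {
    iter <- iter + 1L
    iv <- work[[1]]; work <- work[-1]
    if (iv[2] - iv[1] + 1L < params$min_segment_len) { unexplained <- c(unexplained, list(iv)); next }
    ext <- c(max(1L, iv[1] - margin), min(L, iv[2] + margin))
    piece <- substr(seq, ext[1], ext[2])
    best <- NULL
    for (rf in refs) for (strand in c("+", "-")) {
      al <- .local_align(piece, if (strand == "+") rf$seq else rf$rc, params)
      if (is.null(best) || al$score > best$al$score)
        best <- list(al = al, ref = rf, strand = strand)
    }
    if (is.null(best) || best$al$score < params$min_segment_score) {
      unexplained <- c(unexplained, list(iv)); next
    }
    al <- best$al; rf <- best$ref
    bl <- .alignment_blocks(al, split_gap = 60L)
    cand <- list(); novel <- 0L
    for (b in bl$blocks) {
      q1 <- ext[1] + b[["q1"]] - 1L; q2 <- ext[1] + b[["q2"]] - 1L
      if (q2 - q1 + 1L < params$min_segment_len) next
      if (best$strand == "+") {
        r1 <- rf$offset + b[["s1"]] - 1L; r2 <- rf$offset + b[["s2"]] - 1L
      } else {
        w <- nchar(rf$seq)
        r1 <- rf$offset + (w - b[["s2"]]); r2 <- rf$offset + (w - b[["s1"]])
      }
      cand[[length(cand) + 1L]] <- data.frame(
        label = rf$name, chrom = rf$chrom, ref_start = r1, ref_end = r2,
        strand = best$strand, q_start = q1, q_end = q2, stringsAsFactors = FALSE)
      novel <- novel + max(0L, min(q2, iv[2]) - max(q1, iv[1]) + 1L)
    }
    if (novel < params$min_segment_len) { unexplained <- c(unexplained, list(iv)); next }
    segs <- c(segs, cand)
    qlo <- min(vapply(cand, `[[`, integer(1), "q_start"))
    qhi <- max(vapply(cand, `[[`, integer(1), "q_end"))
    if (qlo - 1L >= iv[1]) work <- c(work, list(c(iv[1], qlo - 1L)))
    if (iv[2] >= qhi + 1L) work <- c(work, list(c(qhi + 1L, iv[2])))
    for (gp in bl$gaps) {
      g1 <- ext[1] + gp[1] - 1L; g2 <- ext[1] + gp[2] - 1L
      if (g2 >= g1) work <- c(work, list(c(g1, g2)))
    }
  }
  unexplained <- c(unexplained, work)  # anything left when the iteration cap hit

  if (length(segs) == 0L)
    return(structure(list(status = "uncharacterizable",
                          reason = "no reference alignment",
                          segments = NULL, length = L),
                     class = "segmentation"))
  segs <- do.call(rbind, segs)

  # polyA / polyT runs in the unaligned remainder
  for (iv in unexplained) {
    if (iv[2] - iv[1] + 1L < params$polya_min_len) next
    x <- strsplit(substr(seq, iv[1], iv[2]), "")[[1]]
    runs <- list(A = .best_homopolymer_run(x, "A", params$polya_min_len, params$polya_min_frac),
                 T = .best_homopolymer_run(x, "T", params$polya_min_len, params$polya_min_frac))
    pick <- if (!is.null(runs$A) && (is.null(runs$T) ||
                                     diff(runs$A) >= diff(runs$T))) "A"
            else if (!is.null(runs$T)) "T" else next
    run <- runs[[pick]]
    segs <- rbind(segs, data.frame(
      label = "polyA", chrom = NA_character_, ref_start = NA_integer_,
      ref_end = NA_integer_, strand = if (pick == "A") "+" else "-",
      q_start = iv[1] + run[1] - 1L, q_end = iv[1] + run[2] - 1L,
      stringsAsFactors = FALSE))
  }
  segs <- segs[order(segs$q_start, segs$q_end), , drop = FALSE]

  tgt <- segs$label == "target"
  if (!any(tgt)) {
    status <- if (any(segs$label == "source")) "native" else "uncharacterizable"
    return(structure(list(status = status, segments = segs, length = L,
                          reason = if (status != "native") "no target-flank alignment" else NULL),
                     class = "segmentation"))
  }

  # orientation-normalize: target segments should be plus-strand
  flipped <- FALSE
  if (sum((segs$q_end - segs$q_start + 1L)[tgt & segs$strand == "-"]) >
      sum((segs$q_end - segs$q_start + 1L)[tgt & segs$strand == "+"])) {
    flipped <- TRUE
    qs <- L - segs$q_end + 1L; qe <- L - segs$q_start + 1L
    segs$q_start <- qs; segs$q_end <- qe
    segs$strand <- ifelse(segs$strand == "+", "-", "+")
    segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  }

  if (sum(tgt) < 2L)
    return(structure(list(status = "uncharacterizable",
                          reason = "only one target-flank alignment",
                          segments = segs, length = L, flipped = flipped),
                     class = "segmentation"))

  # resolve the circular permutation: rotate so the 5' flank (the target
  # segment reaching furthest left on the reference) comes first
  t_idx <- which(segs$label == "target")
  t5 <- t_idx[which.min(segs$ref_start[t_idx])]
  rho <- segs$q_start[t5]
  rot <- function(x) ((x - rho) %% L) + 1L
  segs$q_start <- rot(segs$q_start); segs$q_end <- rot(segs$q_end)
  wrap <- segs$q_end < segs$q_start
  segs$q_end[wrap] <- segs$q_end[wrap] + L
  segs <- segs[order(segs$q_start, segs$q_end), , drop = FALSE]
  # rotate the (orientation-normalized) sequence to match the new coordinates
  seq_rot <- if (flipped) .revcomp(seq) else seq
  if (rho > 1L)
    seq_rot <- paste0(substr(seq_rot, rho, L), substr(seq_rot, 1L, rho - 1L))

  # merge donor segments colinear across the inter-primer gap
  keep <- rep(TRUE, nrow(segs))
  i <- 1L
  while (i < nrow(segs)) {
    j <- i + 1L
    while (j <= nrow(segs) && !keep[j]) j <- j + 1L
    if (j > nrow(segs)) break
    a <- segs[i, ]; b <- segs[j, ]
    if (keep[i] && a$label == "source" && b$label == "source" &&
        a$strand == b$strand &&
        b$q_start - a$q_end - 1L <= 10L) {
      ref_gap <- if (a$strand == "+") b$ref_start - a$ref_end - 1L
                 else a$ref_start - b$ref_end - 1L
      if (!is.na(ref_gap) && ref_gap >= 0L && ref_gap <= params$merge_gap) {
        segs$ref_start[i] <- min(a$ref_start, b$ref_start)
        segs$ref_end[i] <- max(a$ref_end, b$ref_end)
        segs$q_end[i] <- b$q_end
        keep[j] <- FALSE
        next  # try to merge further segments into i
      }
    }
    i <- j
  }
  segs <- segs[keep, , drop = FALSE]

  # refine junctions: local alignments can extend a few bases past a true
  # junction (a mismatch followed by matches still gains score), so each
  # segment end facing a junction is reset to its maximal perfect-match
  # extension, anchored inside the segment. Overlapping refined ends are
  # genuine junction microhomology (bases attributable to both sides).
  if ((params$refine_window %||% 25L) > 0L)
    segs <- .refine_junctions(segs, seq_rot, L, refs,
                              window = params$refine_window %||% 25L)

  # final labels
  t_idx <- which(segs$label == "target")
  t5 <- t_idx[which.min(segs$ref_start[t_idx])]
  t3 <- t_idx[which.max(segs$ref_end[t_idx])]
  segs$label[segs$label == "source"] <- "donor"
  segs$label[t5] <- "target5"
  segs$label[t3] <- "target3"
  rownames(segs) <- NULL

  inner <- segs$label %in% c("donor", "polyA")
  covered <- sum(segs$q_end[inner] - segs$q_start[inner] + 1L)
  span <- if (segs$q_start[t3] > segs$q_end[t5])
    segs$q_start[t3] - segs$q_end[t5] - 1L else 0L
  structure(list(status = "ok", segments = segs, length = L, flipped = flipped,
                 unexplained = max(0L, span - covered)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("segmentation:", x$status, "\n")
  if (!is.null(x$segments)) print(x$segments)
  invisible(x)
}

#' Call the target-site modification from a segmentation
#'
#' With `t5` the 5'-flank reference end and `t3` the 3'-flank reference start
#' (both on the target plus strand): `t5 >= t3` is a duplication of size
#' `t5 - t3 + 1`; `t5 == t3 - 1` is blunt; otherwise a deletion of size
#' `t3 - t5 - 1`.
#'
#' @param seg a `segmentation` with both target flanks.
#' @return A list: `tsm_type`, `tsm_size`, `t5`, `t3`.
#' @export
call_tsm <- function(seg) {
  s <- seg$segments
  i5 <- which(s$label == "target5"); i3 <- which(s$label == "target3")
  if (length(i5) != 1L || length(i3) != 1L)
    stop("both target flanks are required to call the target-site modification")
  if (s$chrom[i5] != s$chrom[i3]) stop("target flanks on different contigs")
  t5 <- s$ref_end[i5]; t3 <- s$ref_start[i3]
  if (t5 >= t3) list(tsm_type = "duplication", tsm_size = t5 - t3 + 1L, t5 = t5, t3 = t3)
  else if (t5 == t3 - 1L) list(tsm_type = "blunt", tsm_size = 0L, t5 = t5, t3 = t3)
  else list(tsm_type = "deletion", tsm_size = t3 - t5 - 1L, t5 = t5, t3 = t3)
}

#' Detect twin-priming from a segmentation
#'
#' Twin-priming shows as donor segments of both orientations. The overall
#' insertion strand is the orientation of the donor segment adjacent to the
#' polyA tail; the inversion point is the reference end of the inverted (other
#' orientation) donor segment. More than two orientation switches are flagged
#' complex.
#'
#' @param seg a `segmentation`.
#' @return A list: `twin_priming`, `inversion_point`, `strand`, `complex`.
#' @export
detect_twin_priming <- function(seg) {
  s <- seg$segments
  d <- s[s$label == "donor", , drop = FALSE]
  if (nrow(d) == 0L) stop("no donor segment")
  pa <- which(s$label == "polyA")
  if (length(pa) >= 1L) {
    # donor segment adjacent to the polyA tail in query order
    di <- which(s$label == "donor")
    adj <- di[which.min(vapply(di, function(i)
      min(abs(s$q_start[pa[1]] - s$q_end[i]), abs(s$q_end[pa[1]] - s$q_start[i])),
      numeric(1)))]
    strand <- s$strand[adj]
  } else strand <- d$strand[nrow(d)]
  orient <- d$strand
  switches <- sum(orient[-1] != orient[-length(orient)])
  if (switches > 2L)
    return(list(twin_priming = TRUE, inversion_point = NA_integer_,
                strand = strand, complex = TRUE))
  twin <- length(unique(orient)) == 2L
  inv <- if (twin) max(d$ref_end[d$strand != strand]) else NA_integer_
  list(twin_priming = twin, inversion_point = inv, strand = strand,
       complex = FALSE)
}

#' Measure junction microhomology
#'
#' Microhomology is the overlap of the query intervals of the two segments
#' flanking a junction -- consensus bases the aligner attributes to both sides
#' -- clipped to `mh_max`; disjoint intervals give 0.
#'
#' @param seg a `segmentation`.
#' @param junction `"5prime"` (between the 5' target flank and the first
#'   insert segment) or `"inversion"` (between the two donor segments of
#'   opposite orientation).
#' @param params a [characterize_params()].
#' @return Microhomology length in bp (`NA` if the junction is absent).
#' @export
measure_microhomology <- function(seg, junction = c("5prime", "inversion"),
                                  params = characterize_params()) {
  junction <- match.arg(junction)
  s <- seg$segments
  if (junction == "5prime") {
    i <- which(s$label == "target5")
    if (length(i) != 1L || i == nrow(s)) return(NA_integer_)
    j <- i + 1L
  } else {
    d <- which(s$label == "donor")
    if (length(d) < 2L) return(NA_integer_)
    sw <- which(s$strand[d][-1] != s$strand[d][-length(d)])
    if (length(sw) != 1L) return(NA_integer_)
    i <- d[sw]; j <- d[sw + 1L]
  }
  ov <- s$q_end[i] - s$q_start[j] + 1L
  max(0L, min(ov, params$mh_max))
}

#' Assign the terminating polyadenylation signal
#'
#' Transcript cleavage occurs in the stop window `[end + stop_lo, end +
#' stop_hi]` downstream (along the transcription direction) of the used
#' signal. A donor 3' terminus inside exactly one window is assigned to it; a
#' terminus inside none is assigned to the signal with the nearest window edge
#' (distance reported); inside overlapping windows, the nearer signal end wins.
#'
#' @param donor_end reference coordinate of the transduction's 3' terminus.
#' @param locus a [source_locus()] (or a list of [polya_signal()] via
#'   `signals`).
#' @param params a [characterize_params()].
#' @param signals optional explicit signal list (overrides `locus`).
#' @param direction transcription direction (+1/-1), default from `locus`.
#' @return A list: `signal_index`, `in_window`, `distance` (0 when inside).
#' @export
assign_polya_signal <- function(donor_end, locus = NULL,
                                params = characterize_params(),
                                signals = NULL, direction = NULL) {
  if (is.null(signals)) signals <- locus$polya_signals
  if (is.null(direction)) direction <- if (is.null(locus)) 1L else locus$transcription_direction
  if (length(signals) == 0L) stop("empty polyadenylation-signal list")
  ends <- vapply(signals, `[[`, integer(1), "end_coord")
  lo <- ends + params$stop_lo * direction
  hi <- ends + params$stop_hi * direction
  wlo <- pmin(lo, hi); whi <- pmax(lo, hi)
  inside <- which(donor_end >= wlo & donor_end <= whi)
  if (length(inside) >= 1L) {
    k <- inside[which.min(abs(donor_end - ends[inside]))]
    return(list(signal_index = signals[[k]]$index, in_window = TRUE, distance = 0L))
  }
  d <- pmin(abs(donor_end - wlo), abs(donor_end - whi))
  k <- which.min(d)
  list(signal_index = signals[[k]]$index, in_window = FALSE,
       distance = as.integer(d[k]))
}

#' Classify an insertion as an orphan transduction
#'
#' An orphan transduction carries only transduced 3'-flank sequence and no L1
#' body: its donor start lies at or beyond the unique-tag start.
#'
#' @param donor_start 5'-most donor reference coordinate.
#' @param locus a [source_locus()].
#' @return `TRUE` for orphan transductions.
#' @export
classify_orphan <- function(donor_start, locus) {
  donor_start >= locus$tag_start
}

#' Measure the insertion length from a segmentation
#'
#' Length = donor reference span (which bridges the unsequenced inter-primer
#' gap) + polyA run length + any unaligned consensus bases between the target
#' flanks. Complete means both flanks are present and the unaligned remainder
#' is at most `max_unexplained`; otherwise the value is a lower bound.
#'
#' @param seg a `segmentation`.
#' @param params a [characterize_params()].
#' @return A list: `insertion_len`, `complete`.
#' @export
insertion_length <- function(seg, params = characterize_params()) {
  s <- seg$segments
  d <- s[s$label == "donor", , drop = FALSE]
  pa <- s[s$label == "polyA", , drop = FALSE]
  len <- sum(d$ref_end - d$ref_start + 1L) +
    sum(pa$q_end - pa$q_start + 1L) +
    (seg$unexplained %||% 0L)
  both <- sum(s$label == "target5") == 1L && sum(s$label == "target3") == 1L
  complete <- both && (seg$unexplained %||% 0L) <= params$max_unexplained &&
    seg$status == "ok"
  list(insertion_len = as.integer(len), complete = complete)
}

#' Characterize one insertion call from its consensus
#'
#' Cuts the reference windows around the call, segments the consensus, and
#' derives the full hallmark row: target-site modification, donor interval and
#' strand, twin-priming and inversion point, junction microhomologies, polyA
#' tail and terminating signal, orphan status, insertion length.
#'
#' @param consensus `consensus_seq` (or sequence) of the call's amplicon.
#' @param call one-row call data.frame (needs `contig`, `coordinate`).
#' @param genome reference genome.
#' @param locus a [source_locus()].
#' @param params a [characterize_params()].
#' @return A one-row data.frame (`insertion_characterization`).
#' @export
characterize_insertion <- function(consensus, call, genome, locus,
                                   params = characterize_params()) {
  genome <- .as_genome(genome)
  clen <- length(genome[[call$contig]])
  tw_lo <- max(1L, call$coordinate - params$target_halfwidth)
  tw_hi <- min(clen, call$coordinate + params$target_halfwidth)
  target_window <- list(chrom = call$contig, offset = tw_lo,
                        seq = .subseq(genome, call$contig, tw_lo, tw_hi))
  sig_ends <- vapply(locus$polya_signals, `[[`, integer(1), "end_coord")
  sw_lo <- min(locus$l1_interval[1], min(sig_ends) - 200L)
  sw_hi <- max(locus$l1_interval[2], max(sig_ends) + 200L)
  source_window <- list(chrom = locus$chrom, offset = sw_lo,
                        seq = .subseq(genome, locus$chrom, sw_lo, sw_hi))
  seg <- segment_consensus(consensus, target_window, source_window, params)

  base <- data.frame(
    call_id = if (inherits(consensus, "consensus_seq")) consensus$call_id else NA_character_,
    sample = call$sample %||% NA_character_,
    contig = call$contig, coordinate = call$coordinate,
    status = seg$status, tsm_type = NA_character_, tsm_size = NA_integer_,
    junction5 = NA_integer_, junction3 = NA_integer_,
    donor_start = NA_integer_, donor_end = NA_integer_,
    strand = NA_character_, twin_priming = NA, inversion_point = NA_integer_,
    complex = NA, mh_5prime = NA_integer_, mh_inversion = NA_integer_,
    polya_len = NA_integer_, signal_index = NA_integer_, in_window = NA,
    signal_distance = NA_integer_, orphan = NA, insertion_len = NA_integer_,
    complete = FALSE, read_count = call$read_count %||% NA_integer_,
    stringsAsFactors = FALSE)
  if (seg$status != "ok") return(base)

  s <- seg$segments
  tsm <- call_tsm(seg)
  base$tsm_type <- tsm$tsm_type; base$tsm_size <- tsm$tsm_size
  base$junction5 <- tsm$t5; base$junction3 <- tsm$t3
  d <- s[s$label == "donor", , drop = FALSE]
  if (nrow(d) > 0L) {
    tp <- detect_twin_priming(seg)
    base$strand <- tp$strand
    base$twin_priming <- tp$twin_priming
    base$inversion_point <- tp$inversion_point
    base$complex <- tp$complex
    base$donor_start <- min(d$ref_start)
    # the transduction's 3' terminus: polyA-side end of the sense donor segment
    sense <- d[d$strand == tp$strand, , drop = FALSE]
    term <- if (nrow(sense) > 0L) max(sense$ref_end) else max(d$ref_end)
    base$donor_end <- max(d$ref_end)
    sig <- assign_polya_signal(term, locus, params)
    base$signal_index <- sig$signal_index
    base$in_window <- sig$in_window
    base$signal_distance <- sig$distance
    base$orphan <- classify_orphan(min(d$ref_start), locus)
    base$mh_5prime <- measure_microhomology(seg, "5prime", params)
    if (isTRUE(tp$twin_priming))
      base$mh_inversion <- measure_microhomology(seg, "inversion", params)
  }
  pa <- s[s$label == "polyA", , drop = FALSE]
  if (nrow(pa) > 0L) base$polya_len <- sum(pa$q_end - pa$q_start + 1L)
  il <- insertion_length(seg, params)
  base$insertion_len <- il$insertion_len
  base$complete <- il$complete
  base
}
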