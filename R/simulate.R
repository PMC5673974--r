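# Synthetic LDI-PCR experiments: genomes with a source-L1 locus, planted
# 3' transductions with TPRT hallmarks, restriction/circularization/inverse-PCR
# amplicon construction with exact reference bookkeeping, a seeded Nanopore-like
# error channel, and synthesized SAM alignments. Everything is deterministic
# given its seed; truth tables make every downstream stage testable.

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# Fixed structural layout of the synthetic locus contig (positions constant
# across seeds; only the random background sequence varies).
.locus_layout <- function(locus_start = 20001L) {
  body_len <- 3000L
  body <- c(locus_start, locus_start + body_len - 1L)         # L1 body
  tag_start <- body[2] + 1L                                   # first base after canonical signal
  sig_ends <- c(body[2],                                      # canonical, ends with the body
                tag_start + 139L + 80L * 0:7)                  # signals 2..9, 80 bp apart
  list(
    body = body,
    tag_start = tag_start,
    l1_interval = c(body[1], tag_start + 999L),
    l1_3prime_end = c(body[2] - 200L, tag_start + 799L),
    signal_ends = as.integer(sig_ends),
    signal_hexamers = c("AATAAA", rep(c("ATTAAA", "AATAAA"), 4L)),
    # primer footprints (rev left of fwd, both inside the tag)
    pp1 = c(rev_start = tag_start + 29L, rev_end = tag_start + 48L,
            fwd_start = tag_start + 79L, fwd_end = tag_start + 98L),
    pp2 = c(rev_start = tag_start + 319L, rev_end = tag_start + 338L,
            fwd_start = tag_start + 389L, fwd_end = tag_start + 408L),
    # planted native restriction sites (site start positions)
    native_sites = list(PstI = c(locus_start + 1499L, locus_start + 4499L),
                        NsiI = c(locus_start + 999L, locus_start + 4799L),
                        SacI = c(locus_start + 1799L, locus_start + 4199L)),
    protected = c(locus_start - 1100L, locus_start + 5500L))
}

.default_enzymes <- function() list(
  restriction_enzyme("PstI", "CTGCAG", 5L),
  restriction_enzyme("NsiI", "ATGCAT", 5L),
  restriction_enzyme("SacI", "GAGCTC", 5L))

# Default target slots: positions where insertions may be planted. Each slot
# gets a guaranteed pair of restriction sites (one enzyme, rotating) so that a
# sub-8.2 kb amplifiable target fragment always exists, whatever the seed.
.default_target_slots <- function(n_contigs, contig_length, locus_contig_length) {
  slots <- list()
  for (i in seq_len(n_contigs - 1L)) {
    chrom <- paste0("chr", i + 1L)
    pos <- seq(5000L, contig_length - 5000L, by = 6000L)
    for (p in pos) slots[[length(slots) + 1L]] <- list(chrom = chrom, pos = p)
  }
  for (p in seq(35000L, locus_contig_length - 5000L, by = 6000L))
    slots[[length(slots) + 1L]] <- list(chrom = "chr1", pos = as.integer(p))
  for (i in seq_along(slots)) slots[[i]]$enzyme <- c("PstI", "NsiI", "SacI")[(i - 1L) %% 3L + 1L]
  slots
}

.scrub_sites <- function(seqs, windows, enzymes) {
  # remove every enzyme-site occurrence overlapping the protected windows;
  # mutating a middle base may create a new site, so iterate to a fixed point
  repeat {
    hit <- FALSE
    for (w in windows) {
      chrom <- w$chrom
      lo <- max(1L, w$start); hi <- min(nchar(seqs[[chrom]]), w$end)
      region <- substr(seqs[[chrom]], lo, hi)
      for (enz in enzymes) {
        m <- gregexpr(enz$recognition_site, region, fixed = TRUE)[[1]]
        if (m[1] == -1L) next
        hit <- TRUE
        for (s in as.integer(m)) {
          pos <- lo + s - 1L + 2L  # middle-ish base of the 6-mer
          old <- substr(seqs[[chrom]], pos, pos)
          substr(seqs[[chrom]], pos, pos) <- c(A = "C", C = "G", G = "T", T = "A")[[old]]
        }
      }
    }
    if (!hit) return(seqs)
  }
}

#' Generate a synthetic genome carrying a source L1 locus
#'
#' Builds a small multi-contig genome whose first contig carries an L1 stub
#' followed by a unique 3' tag with nine planted polyadenylation-signal
#' hexamers (signal 1 = the element's canonical signal) and two inverse primer
#' pairs with inter-primer gaps under the 51 bp cap. Restriction sites for
#' PstI, NsiI and SacI are planted so that each enzyme yields a native fragment
#' containing the full tag, and every target slot (where insertions may later
#' be planted) is flanked by guaranteed sites of one enzyme. A small
#' mitochondrial contig (`chrM`) and an unplaced scaffold (`chrUn_1`) are
#' appended for contig-filter testing. Output is byte-identical for a given
#' seed.
#'
#' @param seed integer seed.
#' @param n_contigs number of nuclear contigs (`chr1` carries the locus).
#' @param contig_length length of the non-locus nuclear contigs; the locus
#'   contig is at least 60 kb.
#' @param locus_params optional overrides: `locus_contig_length`,
#'   `target_slots`.
#' @return A list with `genome` (`DNAStringSet`), `locus` ([source_locus()]),
#'   `layout` (planted structural coordinates, native fragment intervals per
#'   enzyme) and `target_slots`.
#' @export
make_genome <- function(seed, n_contigs = 4L, contig_length = 40000L,
                        locus_params = list()) {
  locus_len <- locus_params$locus_contig_length %||% max(60000L, contig_length)
  if (locus_len < 50000L) stop("locus contig must be at least 50 kb")
  lay <- .locus_layout()
  if (lay$l1_interval[2] + 6000L > locus_len) stop("locus does not fit the contig")
  enzymes <- .default_enzymes()
  slots <- locus_params$target_slots %||%
    .default_target_slots(n_contigs, contig_length, locus_len)

  set.seed(seed)
  seqs <- c(list(chr1 = .rand_dna(locus_len)),
            stats::setNames(lapply(seq_len(n_contigs - 1L), function(i) .rand_dna(contig_length)),
                            paste0("chr", seq_len(n_contigs - 1L) + 1L)),
            list(chrM = .rand_dna(6000L), chrUn_1 = .rand_dna(5000L)))

  # scrub competing enzyme sites around the locus and every target slot
  windows <- c(list(list(chrom = "chr1", start = lay$protected[1], end = lay$protected[2])),
               lapply(slots, function(s) list(chrom = s$chrom, start = s$pos - 1000L,
                                              end = s$pos + 1000L)))
  seqs <- .scrub_sites(seqs, windows, enzymes)

  put <- function(chrom, start, word) {
    substr(seqs[[chrom]], start, start + nchar(word) - 1L) <<- word
  }
  # native restriction sites
  for (enz in enzymes)
    for (s in lay$native_sites[[enz$name]]) put("chr1", s, enz$recognition_site)
  # polyadenylation signal hexamers (end coordinate = last base of hexamer)
  for (k in seq_along(lay$signal_ends))
    put("chr1", lay$signal_ends[k] - 5L, lay$signal_hexamers[k])
  # per-slot guaranteed sites
  enz_by_name <- stats::setNames(enzymes, vapply(enzymes, `[[`, "", "name"))
  for (s in slots) {
    site <- enz_by_name[[s$enzyme]]$recognition_site
    put(s$chrom, s$pos - 450L, site)
    put(s$chrom, s$pos + 600L, site)
  }

  pp <- function(name, fp) {
    primer_pair(name,
                fwd_seq = substr(seqs$chr1, fp["fwd_start"], fp["fwd_end"]),
                rev_seq = .revcomp(substr(seqs$chr1, fp["rev_start"], fp["rev_end"])),
                fwd_start = fp[["fwd_start"]], fwd_end = fp[["fwd_end"]],
                rev_start = fp[["rev_start"]], rev_end = fp[["rev_end"]])
  }
  locus <- source_locus(
    chrom = "chr1", l1_interval = lay$l1_interval,
    l1_3prime_end = lay$l1_3prime_end, tag_start = lay$tag_start,
    polya_signals = lapply(seq_along(lay$signal_ends), function(k)
      polya_signal(k, lay$signal_hexamers[k], lay$signal_ends[k])),
    primer_pairs = list(pp("pp1", lay$pp1), pp("pp2", lay$pp2)),
    enzymes = enzymes)

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  # native fragment intervals per enzyme (between the planted sites)
  native_frags <- lapply(enzymes, function(e) {
    s <- lay$native_sites[[e$name]]
    c(start = s[1] + e$cut_offset, end = s[2] + e$cut_offset - 1L)
  })
  names(native_frags) <- vapply(enzymes, `[[`, "", "name")
  list(genome = genome, locus = locus,
       layout = c(lay, list(native_fragments = native_frags)),
       target_slots = slots)
}

# ---- insertion specifications ---------------------------------------------

.comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

# One-base extension-ambiguity check at every junction of the inserted allele.
# If the base continuing a segment along its reference equals the first base
# of the next segment (or vice versa), a local aligner can attribute junction
# bases to either side and the planted coordinates are not uniquely
# recoverable; the default spec generator redraws until all junctions are
# unambiguous.
.junctions_clean <- function(gm, spec) {
  genome <- .as_genome(gm$genome); locus <- gm$locus
  g1 <- function(chrom, pos) .subseq(genome, chrom, pos, pos)
  t <- spec$target_pos
  r0 <- switch(spec$tsm_type,
               duplication = t - spec$tsm_size + 1L,
               blunt = t + 1L,
               deletion = t + spec$tsm_size + 1L)
  ctx <- function(p) {
    if (p$label == "polyA") {
      b <- if (p$strand == "+") "A" else "T"
      return(list(first = b, last = b, extL = b, extR = b))
    }
    s <- .piece_seq(p, genome)
    if (p$strand == "+")
      list(first = substr(s, 1L, 1L), last = substr(s, nchar(s), nchar(s)),
           extL = g1(p$chrom, p$start - 1L), extR = g1(p$chrom, p$end + 1L))
    else
      list(first = substr(s, 1L, 1L), last = substr(s, nchar(s), nchar(s)),
           extL = .comp1(g1(p$chrom, p$end + 1L)),
           extR = .comp1(g1(p$chrom, p$start - 1L)))
  }
  pieces <- c(list(list(first = NA, last = g1(spec$target_chrom, t),
                        extL = NA, extR = g1(spec$target_chrom, t + 1L))),
              lapply(.insert_pieces(spec, locus), ctx),
              list(list(first = g1(spec$target_chrom, r0), last = NA,
                        extL = g1(spec$target_chrom, r0 - 1L), extR = NA)))
  for (i in seq_len(length(pieces) - 1L)) {
    a <- pieces[[i]]; b <- pieces[[i + 1L]]
    if (identical(a$extR, b$first) || identical(b$extL, a$last)) return(FALSE)
  }
  TRUE
}

#' Specification of one planted 3'-transduction insertion
#'
#' Describes a somatic insertion with TPRT hallmarks: the target coordinate,
#' target-site modification (duplication / deletion / blunt), the transduced
#' donor interval in source-locus coordinates, insertion strand, optional
#' twin-priming with an inversion point, polyA-tail length and the
#' polyadenylation signal whose 10--30 bp stop window contains `donor_end`.
#'
#' @param id identifier used in read names and truth tables.
#' @param target_chrom,target_pos insertion point: the insert is placed after
#'   reference base `target_pos`.
#' @param tsm_type `"duplication"`, `"deletion"` or `"blunt"`.
#' @param tsm_size target-site modification size in bp (0 for blunt).
#' @param donor_start,donor_end transduced interval on the locus contig.
#' @param strand insertion strand on the target (`"+"` or `"-"`).
#' @param twin_priming logical; when `TRUE` the donor is split at
#'   `inversion_point` and its 5' part is strand-flipped.
#' @param inversion_point donor coordinate of the orientation switch
#'   (strictly inside the donor interval).
#' @param polya_len polyA-tail length in bp.
#' @param signal_index index of the terminating polyadenylation signal.
#' @param sample sample label.
#' @param clonal_fraction fraction of cells carrying the insertion (scales
#'   simulated read support).
#' @return An object of class `insertion_spec`.
#' @export
insertion_spec <- function(id, target_chrom, target_pos, tsm_type, tsm_size,
                           donor_start, donor_end, strand = "+",
                           twin_priming = FALSE, inversion_point = NA_integer_,
                           polya_len = 30L, signal_index = NA_integer_,
                           sample = "s1", clonal_fraction = 1) {
  tsm_type <- match.arg(tsm_type, c("duplication", "deletion", "blunt"))
  stopifnot(tsm_size >= 0L, donor_start <= donor_end,
            strand %in% c("+", "-"),
            clonal_fraction > 0, clonal_fraction <= 1)
  if (tsm_type == "blunt" && tsm_size != 0L) stop("blunt implies tsm_size = 0")
  if (tsm_type != "blunt" && tsm_size < 1L) stop(tsm_type, " requires tsm_size >= 1")
  if (twin_priming) {
    if (is.na(inversion_point) || inversion_point <= donor_start ||
        inversion_point >= donor_end)
      stop("inversion_point must lie strictly inside the donor interval")
  }
  structure(list(id = id, target_chrom = target_chrom,
                 target_pos = as.integer(target_pos), tsm_type = tsm_type,
                 tsm_size = as.integer(tsm_size),
                 donor_start = as.integer(donor_start),
                 donor_end = as.integer(donor_end), strand = strand,
                 twin_priming = isTRUE(twin_priming),
                 inversion_point = as.integer(inversion_point),
                 polya_len = as.integer(polya_len),
                 signal_index = as.integer(signal_index), sample = sample,
                 clonal_fraction = clonal_fraction),
            class = "insertion_spec")
}

.validate_spec_against_locus <- function(spec, locus) {
  if (spec$target_chrom == locus$chrom &&
      spec$target_pos >= locus$l1_interval[1] - 1000L &&
      spec$target_pos <= locus$l1_interval[2] + 1000L)
    stop("target coordinate must not lie inside (or adjacent to) the source locus")
  if (!is.na(spec$signal_index)) {
    sig <- locus$polya_signals[[spec$signal_index]]
    w <- sig$end_coord + c(10L, 30L) * locus$transcription_direction
    if (spec$donor_end < min(w) || spec$donor_end > max(w))
      stop(sprintf("donor_end %d outside the stop window of signal %d [%d, %d]",
                   spec$donor_end, spec$signal_index, min(w), max(w)))
  }
  invisible(TRUE)
}

#' Default insertion specifications for a synthetic experiment
#'
#' Draws `n` insertion specifications over the genome's guaranteed target
#' slots, emulating the hallmark spectrum of somatic L1 3' transductions:
#' mostly target-site duplications (sizes 1--28 bp) with some deletions
#' (1--50 bp), both strands, twin-priming in roughly 45% of events, a
#' predominance of orphan transductions (no L1 body sequence), polyA tails of
#' 20--60 bp, and termination 10--30 bp downstream of polyadenylation signals
#' 2--9. Deterministic given the seed.
#'
#' @param gm output of [make_genome()].
#' @param n number of insertions (at most the number of target slots).
#' @param seed integer seed.
#' @param sample sample label.
#' @return List of [insertion_spec()] objects.
#' @export
default_insertion_specs <- function(gm, n = 20L, seed = 1L, sample = "s1") {
  slots <- gm$target_slots
  locus <- gm$locus
  if (n > length(slots)) stop("not enough target slots for ", n, " insertions")
  set.seed(seed)
  use <- sort(sample(seq_along(slots), n))
  sig_ends <- vapply(locus$polya_signals, `[[`, integer(1), "end_coord")
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    slot <- slots[[use[i]]]
    twin <- stats::runif(1) < 0.45
    orphan <- !twin && stats::runif(1) < 0.7
    cf <- stats::runif(1, 0.5, 1)
    for (attempt in 1:500) {
      strand <- sample(c("+", "-"), 1L)
      tsm_type <- sample(c("duplication", "deletion", "blunt"), 1L,
                         prob = c(0.6, 0.25, 0.15))
      tsm_size <- switch(tsm_type,
                         duplication = sample(1:28, 1L),
                         deletion = sample(1:50, 1L),
                         blunt = 0L)
      sig_k <- sample(2:9, 1L)
      donor_end <- sig_ends[sig_k] + sample(10:30, 1L)
      if (twin) {
        donor_start <- sample(22600:22700, 1L)
        inv <- sample(22800:22990, 1L)
      } else {
        # orphans keep >= 30 bp of donor upstream of the reverse primer's 5'
        # end so the 5' junction stays mappable, plus margin over the tag start
        donor_start <- if (orphan) sample(23005:23020, 1L) else sample(22500:22990, 1L)
        inv <- NA_integer_
      }
      cand <- insertion_spec(
        id = sprintf("ins%02d", i), target_chrom = slot$chrom,
        target_pos = slot$pos, tsm_type = tsm_type, tsm_size = tsm_size,
        donor_start = donor_start, donor_end = donor_end,
        strand = strand, twin_priming = twin,
        inversion_point = inv, polya_len = sample(20:60, 1L),
        signal_index = sig_k, sample = sample, clonal_fraction = cf)
      if (.junctions_clean(gm, cand)) break
    }
    specs[[i]] <- cand
  }
  specs
}

# ---- planting and amplicon bookkeeping -------------------------------------

# oriented pieces of the inserted sequence, left to right on the target + strand
.insert_pieces <- function(spec, locus) {
  sense <- if (spec$twin_priming) {
    list(list(label = "donor", chrom = locus$chrom, start = spec$donor_start,
              end = spec$inversion_point, strand = "-"),
         list(label = "donor", chrom = locus$chrom, start = spec$inversion_point + 1L,
              end = spec$donor_end, strand = "+"),
         list(label = "polyA", chrom = NA_character_, start = NA_integer_,
              end = NA_integer_, strand = "+", len = spec$polya_len))
  } else {
    list(list(label = "donor", chrom = locus$chrom, start = spec$donor_start,
              end = spec$donor_end, strand = "+"),
         list(label = "polyA", chrom = NA_character_, start = NA_integer_,
              end = NA_integer_, strand = "+", len = spec$polya_len))
  }
  if (spec$strand == "+") return(sense)
  rev(lapply(sense, function(p) { p$strand <- if (p$strand == "+") "-" else "+"; p }))
}

.piece_seq <- function(p, genome) {
  if (p$label == "polyA") {
    base <- if (p$strand == "+") "A" else "T"
    return(strrep(base, p$len))
  }
  s <- .subseq(genome, p$chrom, p$start, p$end)
  if (p$strand == "-") .revcomp(s) else s
}

.piece_len <- function(p) if (p$label == "polyA") p$len else p$end - p$start + 1L

#' Plant a 3'-transduction insertion into a genome
#'
#' Builds the inserted-allele haplotype: the donor segment (split and
#' strand-flipped at the inversion point under twin-priming) plus a polyA
#' tail, placed after `target_pos` with the requested target-site modification
#' (duplication repeats `tsm_size` target bases on both flanks; deletion
#' removes `tsm_size` bases from the right flank).
#'
#' @param gm output of [make_genome()] (or a list with `genome` and `locus`).
#' @param spec an [insertion_spec()].
#' @return A list with `haplotype` (`DNAStringSet` with the target contig
#'   modified) and `truth` (a one-row data.frame of realized coordinates: the
#'   5' junction `junction5` = `target_pos`, the 3' junction `junction3` =
#'   first right-flank reference base, insert length, orphan flag).
#' @export
plant_insertion <- function(gm, spec) {
  genome <- .as_genome(gm$genome); locus <- gm$locus
  .validate_spec_against_locus(spec, locus)
  t <- spec$target_pos
  contig <- .contig_seq(genome, spec$target_chrom)
  n <- nchar(contig)
  d <- spec$tsm_size
  if (spec$tsm_type == "duplication" && d > t)
    stop("duplication size exceeds the left flank")
  r0 <- switch(spec$tsm_type,
               duplication = t - d + 1L,
               blunt = t + 1L,
               deletion = t + d + 1L)
  if (t < 1L || r0 > n) stop("insertion does not fit the contig")
  pieces <- .insert_pieces(spec, locus)
  insert <- paste(vapply(pieces, .piece_seq, character(1), genome = genome),
                  collapse = "")
  hap <- paste0(substr(contig, 1L, t), insert, substr(contig, r0, n))
  out <- as.character(genome)
  out[spec$target_chrom] <- hap
  truth <- data.frame(
    id = spec$id, sample = spec$sample, chrom = spec$target_chrom,
    junction5 = t, junction3 = r0, tsm_type = spec$tsm_type,
    tsm_size = spec$tsm_size, donor_start = spec$donor_start,
    donor_end = spec$donor_end, strand = spec$strand,
    twin_priming = spec$twin_priming, inversion_point = spec$inversion_point,
    polya_len = spec$polya_len, signal_index = spec$signal_index,
    orphan = spec$donor_start >= locus$tag_start,
    insert_len = nchar(insert), stringsAsFactors = FALSE)
  list(haplotype = Biostrings::DNAStringSet(out), truth = truth)
}

# assemble an amplicon from an ordered list of circle pieces, starting after
# the inter-primer gap; returns sequence + segment table with query intervals
.assemble_amplicon <- function(pieces, genome) {
  seqs <- vapply(pieces, .piece_seq, character(1), genome = genome)
  lens <- nchar(seqs)
  q2 <- cumsum(lens); q1 <- q2 - lens + 1L
  segments <- data.frame(
    label = vapply(pieces, `[[`, character(1), "label"),
    chrom = vapply(pieces, function(p) p$chrom %||% NA_character_, character(1)),
    ref_start = vapply(pieces, function(p) p$start %||% NA_integer_, integer(1)),
    ref_end = vapply(pieces, function(p) p$end %||% NA_integer_, integer(1)),
    strand = vapply(pieces, `[[`, character(1), "strand"),
    q_start = q1, q_end = q2, stringsAsFactors = FALSE)
  list(sequence = paste(seqs, collapse = ""), segments = segments)
}

# split the primer-carrying piece at the inter-primer gap and rotate the
# circular piece list so the amplicon starts right after the gap
.open_circle_at_primers <- function(pieces, pair, locus_chrom) {
  pr1 <- pair$rev_start; pr2 <- pair$rev_end
  pf1 <- pair$fwd_start; pf2 <- pair$fwd_end
  carrier <- which(vapply(pieces, function(p)
    p$label != "polyA" && !is.na(p$start) &&
      identical(p$chrom, locus_chrom) && p$label %in% c("donor", "source") &&
      p$start <= pr1 && p$end >= pf2,
    logical(1)))
  if (length(carrier) != 1L) return(NULL)
  p <- pieces[[carrier]]
  low <- p; low$end <- pr2     # ref [start .. rev primer 5' end]
  high <- p; high$start <- pf1 # ref [fwd primer 5' end .. end]
  rest <- if (carrier < length(pieces))
    c(pieces[(carrier + 1L):length(pieces)], pieces[seq_len(carrier - 1L)])
  else pieces[seq_len(carrier - 1L)]
  if (p$strand == "+") c(list(high), rest, list(low))
  else c(list(low), rest, list(high))
}

.enzyme_by_name <- function(locus, name) {
  for (e in locus$enzymes) if (e$name == name) return(e)
  stop("unknown enzyme: ", name)
}
.pair_by_name <- function(locus, name) {
  for (p in locus$primer_pairs) if (p$name == name) return(p)
  stop("unknown primer pair: ", name)
}

#' Construct the insertion-specific inverse-PCR amplicon
#'
#' Models restriction digestion of the inserted-allele haplotype, self
#' circularization of the fragment carrying the insertion, and inverse PCR
#' from the primer pair sitting in the inserted tag copy -- with exact
#' bookkeeping of which reference (or donor) interval each amplicon base comes
#' from. The amplicon is reported as the circular top-strand arc excluding the
#' inter-primer gap, beginning right after the gap.
#'
#' @param gm output of [make_genome()].
#' @param spec an [insertion_spec()].
#' @param enzyme_name,pair_name reaction: restriction enzyme and primer pair.
#' @param max_fragment maximum PCR-amplifiable fragment length (annotation
#'   and amplifiability gate for the simulator; default 8200 bp).
#' @return A list with `status` (`"ok"` / `"not_amplifiable"`), `sequence`,
#'   `segments` (labelled query/reference intervals: `target5`, `donor`,
#'   `polyA`, `target3`), `junction5`, `junction3`, `fragment` (interval of the
#'   digested target fragment in reference coordinates), `fragment_len`,
#'   `cut_distances` (junction distance to the bounding cuts), `enzyme`,
#'   `pair`, `reaction`.
#' @export
insertion_amplicon <- function(gm, spec, enzyme_name, pair_name = "pp1",
                               max_fragment = 8200L) {
  genome <- .as_genome(gm$genome); locus <- gm$locus
  .validate_spec_against_locus(spec, locus)
  enzyme <- .enzyme_by_name(locus, enzyme_name)
  pair <- .pair_by_name(locus, pair_name)
  t <- spec$target_pos
  r0 <- switch(spec$tsm_type,
               duplication = t - spec$tsm_size + 1L,
               blunt = t + 1L,
               deletion = t + spec$tsm_size + 1L)
  cuts <- cut_sites(genome, enzyme)[[spec$target_chrom]]
  cL <- suppressWarnings(max(cuts[cuts < t]))
  cR <- suppressWarnings(min(cuts[cuts >= r0]))
  fail <- list(status = "not_amplifiable", sequence = NULL)
  if (!is.finite(cL) || !is.finite(cR)) return(fail)
  pieces <- c(list(list(label = "target5", chrom = spec$target_chrom,
                        start = cL + 1L, end = t, strand = "+")),
              .insert_pieces(spec, locus),
              list(list(label = "target3", chrom = spec$target_chrom,
                        start = r0, end = cR, strand = "+")))
  frag_len <- sum(vapply(pieces, .piece_len, integer(1)))
  if (frag_len > max_fragment) return(fail)
  opened <- .open_circle_at_primers(pieces, pair, locus$chrom)
  if (is.null(opened)) return(fail)  # no intact primer pair inside the insert
  amp <- .assemble_amplicon(opened, genome)
  c(list(status = "ok"), amp,
    list(junction5 = t, junction3 = r0,
         fragment = c(cL + 1L, cR), fragment_len = frag_len,
         cut_distances = c(left = t - cL, right = cR - r0 + 1L),
         enzyme = enzyme_name, pair = pair_name,
         reaction = paste0(enzyme_name, ".", pair_name)))
}

#' Construct the native inverse-PCR amplicon of the source locus
#'
#' The native product arises from the un-transposed source locus itself: the
#' restriction fragment containing the unique tag is circularized and
#' amplified by the inverse primers.
#'
#' @inheritParams insertion_amplicon
#' @return Same shape as [insertion_amplicon()] with all segments labelled
#'   `"source"`.
#' @export
native_amplicon <- function(gm, enzyme_name, pair_name = "pp1",
                            max_fragment = 8200L) {
  genome <- .as_genome(gm$genome); locus <- gm$locus
  enzyme <- .enzyme_by_name(locus, enzyme_name)
  pair <- .pair_by_name(locus, pair_name)
  cuts <- cut_sites(genome, enzyme)[[locus$chrom]]
  cL <- suppressWarnings(max(cuts[cuts < pair$rev_start]))
  cR <- suppressWarnings(min(cuts[cuts >= pair$fwd_end]))
  fail <- list(status = "not_amplifiable", sequence = NULL)
  if (!is.finite(cL) || !is.finite(cR)) return(fail)
  if (cR - cL > max_fragment) return(fail)
  pieces <- list(list(label = "source", chrom = locus$chrom,
                      start = cL + 1L, end = cR, strand = "+"))
  opened <- .open_circle_at_primers(pieces, pair, locus$chrom)
  if (is.null(opened)) return(fail)
  amp <- .assemble_amplicon(opened, genome)
  c(list(status = "ok"), amp,
    list(junction5 = NA_integer_, junction3 = NA_integer_,
         fragment = c(cL + 1L, cR), fragment_len = cR - cL,
         cut_distances = c(left = NA_integer_, right = NA_integer_),
         enzyme = enzyme_name, pair = pair_name,
         reaction = paste0(enzyme_name, ".", pair_name)))
}

# ---- read simulation -------------------------------------------------------

#' Simulate noisy amplicon reads
#'
#' Each read covers the whole amplicon (amplicon sequencing, not shotgun) on a
#' uniformly chosen strand, with independent per-base errors at `error_rate`
#' split 1:1:1 between substitutions, single-base insertions (a random base
#' inserted before the template base) and deletions. Deterministic given the
#' seed. The returned position maps record, for every amplicon base, its
#' position in the mutated forward-orientation read (`NA` when deleted), which
#' lets [synthesize_alignments()] place segment boundaries exactly.
#'
#' @param amplicon amplicon sequence (character) or the list returned by
#'   [insertion_amplicon()] / [native_amplicon()].
#' @param n_reads number of reads.
#' @param error_rate per-base error probability in `[0, 0.3]`.
#' @param seed integer seed.
#' @param prefix read-name prefix; reads are named `<prefix>_<i>`.
#' @return A list with `reads` (data.frame: `read_id`, `strand`, `sequence`)
#'   and `maps` (list of integer vectors).
#' @export
simulate_reads <- function(amplicon, n_reads, error_rate = 0, seed = 1L,
                           prefix = "read") {
  seq <- if (is.list(amplicon)) amplicon$sequence else amplicon
  stopifnot(is.character(seq), nchar(seq) > 0L,
            error_rate >= 0, error_rate <= 0.3)
  set.seed(seed)
  tmpl <- strsplit(seq, "")[[1]]
  L <- length(tmpl)
  bases <- c("A", "C", "G", "T")
  reads <- vector("list", n_reads)
  maps <- vector("list", n_reads)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  for (r in seq_len(n_reads)) {
    if (error_rate == 0) {
      mut <- tmpl
      map <- seq_len(L)
    } else {
      err <- stats::runif(L) < error_rate
      type <- ifelse(err, sample(c("sub", "ins", "del"), L, replace = TRUE), "none")
      out <- character(L + sum(type == "ins"))
      map <- integer(L)
      j <- 0L
      for (i in seq_len(L)) {
        ti <- type[i]
        if (ti == "del") { map[i] <- NA_integer_; next }
        if (ti == "ins") { j <- j + 1L; out[j] <- sample(bases, 1L) }
        j <- j + 1L
        out[j] <- if (ti == "sub") sample(setdiff(bases, tmpl[i]), 1L) else tmpl[i]
        map[i] <- j
      }
      mut <- out[seq_len(j)]
    }
    fwd <- paste(mut, collapse = "")
    reads[[r]] <- fwd
    maps[[r]] <- map
  }
  df <- data.frame(read_id = sprintf("%s_%d", prefix, seq_len(n_reads)),
                   strand = strands,
                   sequence = vapply(seq_len(n_reads), function(r)
                     if (strands[r] == "+") reads[[r]] else .revcomp(reads[[r]]),
                     character(1)),
                   stringsAsFactors = FALSE)
  list(reads = df, maps = maps)
}

# ---- SAM synthesis ---------------------------------------------------------

#' SAM header for a genome
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param sort_order value for the `SO` field.
#' @return Character vector of header lines.
#' @export
sam_header <- function(genome, sort_order = "unsorted") {
  genome <- .as_genome(genome)
  c(sprintf("@HD\tVN:1.6\tSO:%s", sort_order),
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)),
    "@PG\tID:ldipcr\tPN:ldipcr")
}

.mid_cigar <- function(ql, rl) {
  if (ql == rl) return(sprintf("%dM", ql))
  if (ql > rl) {
    a <- rl %/% 2L
    return(sprintf("%dM%dI%dM", a, ql - rl, rl - a))
  }
  a <- ql %/% 2L
  sprintf("%dM%dD%dM", a, rl - ql, ql - a)
}

#' Synthesize SAM alignment records for simulated reads
#'
#' Emits the alignments an idealized long-read aligner would produce, straight
#' from the simulator's truth: one record per alignable amplicon segment
#' (polyA runs and segments shorter than `min_segment` get none), with exact
#' query intervals derived from the per-read error maps, correct strands,
#' supplementary flags (0x800) on all but the longest segment, `SA` tags
#' cross-referencing the rest, and configurable MAPQ.
#'
#' @param sim output of [simulate_reads()].
#' @param amplicon the amplicon the reads were simulated from.
#' @param sample,reaction labels encoded into read names as
#'   `sample~reaction~name`.
#' @param mapq mapping quality for every record (default 60).
#' @param min_segment minimum segment reference span to receive a record.
#' @return Character vector of SAM alignment lines (no header).
#' @export
synthesize_alignments <- function(sim, amplicon, sample = "s1",
                                  reaction = "NsiI.pp1", mapq = 60L,
                                  min_segment = 25L) {
  segs <- amplicon$segments
  segs <- segs[!is.na(segs$chrom) &
                 (segs$ref_end - segs$ref_start + 1L) >= min_segment, , drop = FALSE]
  if (nrow(segs) == 0L) return(character(0))
  out <- character(0)
  for (r in seq_len(nrow(sim$reads))) {
    map <- sim$maps[[r]]
    strand <- sim$reads$strand[r]
    read_seq <- sim$reads$sequence[r]
    L <- nchar(read_seq)
    qname <- paste(sample, reaction, sim$reads$read_id[r], sep = "~")
    recs <- list()
    for (i in seq_len(nrow(segs))) {
      sub <- map[segs$q_start[i]:segs$q_end[i]]
      sub <- sub[!is.na(sub)]
      if (length(sub) < 2L) next
      m1 <- sub[1]; m2 <- sub[length(sub)]
      if (strand == "+") { rq1 <- m1; rq2 <- m2; sstr <- segs$strand[i] }
      else { rq1 <- L - m2 + 1L; rq2 <- L - m1 + 1L
             sstr <- if (segs$strand[i] == "+") "-" else "+" }
      ql <- rq2 - rq1 + 1L
      rl <- segs$ref_end[i] - segs$ref_start[i] + 1L
      lead <- if (sstr == "+") rq1 - 1L else L - rq2
      trail <- L - lead - ql
      cigar <- paste0(if (lead > 0L) sprintf("%dS", lead) else "",
                      .mid_cigar(ql, rl),
                      if (trail > 0L) sprintf("%dS", trail) else "")
      recs[[length(recs) + 1L]] <- list(
        rname = segs$chrom[i], pos = segs$ref_start[i], strand = sstr,
        cigar = cigar, ql = ql)
    }
    if (length(recs) == 0L) next
    primary <- which.max(vapply(recs, `[[`, integer(1), "ql"))
    sa_all <- vapply(recs, function(x)
      sprintf("%s,%d,%s,%s,%d,0;", x$rname, x$pos, x$strand, x$cigar, mapq), character(1))
    for (k in seq_along(recs)) {
      x <- recs[[k]]
      flag <- (if (x$strand == "-") 16L else 0L) + (if (k != primary) 2048L else 0L)
      seq_field <- if (x$strand == "-") .revcomp(read_seq) else read_seq
      sa <- paste(sa_all[-k], collapse = "")
      fields <- c(qname, flag, x$rname, x$pos, mapq, x$cigar, "*", 0L, 0L,
                  seq_field, "*",
                  if (length(recs) > 1L) sprintf("SA:Z:%s", sa) else NULL)
      out <- c(out, paste(fields, collapse = "\t"))
    }
  }
  out
}

# ---- experiment driver -----------------------------------------------------

#' Simulate a complete LDI-PCR / Nanopore experiment
#'
#' For each insertion specification, selects an amplifiable reaction (the
#' enzyme giving the smallest target fragment under `max_fragment`, with both
#' junction-to-cut distances of at least `min_cut_margin`), simulates reads
#' from the insertion-specific amplicon (support scaled by the spec's clonal
#' fraction) and from the native amplicons, synthesizes SAM records, and
#' optionally injects barcode crosstalk by relabelling a fraction of each
#' insertion's reads into another sample.
#'
#' @param seed master seed; all randomness derives from it.
#' @param gm output of [make_genome()]; built from `seed` when `NULL`.
#' @param specs list of [insertion_spec()]; defaults to
#'   [default_insertion_specs()] when `NULL`.
#' @param n_reads reads per insertion at clonal fraction 1.
#' @param n_native_reads native-amplicon reads per reaction.
#' @param error_rate per-base read error rate.
#' @param pair_name primer pair used.
#' @param max_fragment amplifiability cap in bp.
#' @param min_cut_margin minimum junction-to-cut distance for the chosen
#'   reaction (keeps planted calls clear of the cut-distance filter).
#' @param crosstalk `NULL`, or `list(to = <sample>, fraction = <0..1>)`.
#' @return A list: `gm` (genome + locus), `truth` (one row per planted
#'   insertion, incl. realized junctions, the expected called coordinate,
#'   chosen reaction and read count), `sam` (header + records), `amplicons`.
#' @export
simulate_ldi_experiment <- function(seed, gm = NULL, specs = NULL,
                                    n_reads = 10L, n_native_reads = 8L,
                                    error_rate = 0, pair_name = "pp1",
                                    max_fragment = 8200L, min_cut_margin = 50L,
                                    crosstalk = NULL) {
  if (is.null(gm)) gm <- make_genome(seed)
  if (is.null(specs)) specs <- default_insertion_specs(gm, seed = seed)
  locus <- gm$locus
  enzymes <- vapply(locus$enzymes, `[[`, "", "name")
  sam <- character(0)
  amps <- list()
  truth <- list()
  sub_seed <- function(i, j)
    as.integer((as.numeric(seed) * 131 + i * 17 + j) %% 2000000000)

  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    cands <- list()
    for (e in enzymes) {
      a <- insertion_amplicon(gm, spec, e, pair_name, max_fragment)
      if (a$status == "ok" && min(a$cut_distances) >= min_cut_margin)
        cands[[length(cands) + 1L]] <- a
    }
    if (length(cands) == 0L)
      stop("no amplifiable reaction for insertion ", spec$id)
    amp <- cands[[which.min(vapply(cands, `[[`, integer(1), "fragment_len"))]]
    nr <- max(1L, as.integer(round(n_reads * spec$clonal_fraction)))
    sim <- simulate_reads(amp, nr, error_rate, seed = sub_seed(i, 1L),
                          prefix = spec$id)
    samples <- rep(spec$sample, nr)
    if (!is.null(crosstalk) && crosstalk$fraction > 0) {
      k <- floor(nr * crosstalk$fraction)
      if (k >= 1L) samples[seq_len(k)] <- crosstalk$to
    }
    for (s in unique(samples)) {
      keep <- samples == s
      sub <- list(reads = sim$reads[keep, , drop = FALSE], maps = sim$maps[keep])
      sam <- c(sam, synthesize_alignments(sub, amp, sample = s,
                                          reaction = amp$reaction))
    }
    amps[[spec$id]] <- amp
    truth[[i]] <- data.frame(
      id = spec$id, sample = spec$sample, reaction = amp$reaction,
      chrom = spec$target_chrom, junction5 = amp$junction5,
      junction3 = amp$junction3,
      expected_call = min(amp$junction5, amp$junction3),
      tsm_type = spec$tsm_type, tsm_size = spec$tsm_size,
      donor_start = spec$donor_start, donor_end = spec$donor_end,
      strand = spec$strand, twin_priming = spec$twin_priming,
      inversion_point = spec$inversion_point, polya_len = spec$polya_len,
      signal_index = spec$signal_index,
      orphan = spec$donor_start >= locus$tag_start,
      insert_len = spec$donor_end - spec$donor_start + 1L + spec$polya_len,
      n_reads = sum(samples == spec$sample), stringsAsFactors = FALSE)
  }

  samples_used <- unique(vapply(specs, `[[`, "", "sample"))
  for (s in samples_used) for (j in seq_along(enzymes)) {
    nat <- native_amplicon(gm, enzymes[j], pair_name, max_fragment = 16000L)
    if (nat$status != "ok") next
    sim <- simulate_reads(nat, n_native_reads, error_rate,
                          seed = sub_seed(1000L + j, match(s, samples_used)),
                          prefix = paste0("native_", enzymes[j]))
    sam <- c(sam, synthesize_alignments(sim, nat, sample = s,
                                        reaction = nat$reaction))
    amps[[paste0("native_", enzymes[j], "_", s)]] <- nat
  }

  list(gm = gm, truth = do.call(rbind, truth),
       sam = c(sam_header(gm$genome), sam), amplicons = amps)
}

# ---- text-format writers ---------------------------------------------------

#' Write simulator outputs to standard text formats
#'
#' `write_sim_fasta()` writes a genome or amplicon set as FASTA;
#' `write_sim_fastq()` writes simulated reads as FASTQ (constant quality);
#' `write_sam()` writes SAM lines; `write_truth_tsv()` writes a truth table
#' with a schema-version header line.
#'
#' @param x object to write (genome, `sim$reads` data.frame, SAM character
#'   vector, or truth data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim_fasta <- function(x, path) {
  Biostrings::writeXStringSet(.as_genome(x), path)
  invisible(path)
}

#' @rdname write_sim_fasta
#' @export
write_sim_fastq <- function(x, path) {
  qual <- vapply(x$sequence, function(s) strrep("I", nchar(s)), character(1))
  writeLines(paste0("@", x$read_id, "\n", x$sequence, "\n+\n", qual), path)
  invisible(path)
}

#' @rdname write_sim_fasta
#' @export
write_sam <- function(x, path) {
  writeLines(x, path)
  invisible(path)
}

#' @rdname write_sim_fasta
#' @export
write_truth_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#ldipcr_truth_schema=1", con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
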