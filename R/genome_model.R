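#' @useDynLib ldipcr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---- internal sequence helpers -------------------------------------------

.as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) {
    if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == ""))
      stop("genome must be a named character vector or DNAStringSet")
    return(Biostrings::DNAStringSet(genome))
  }
  stop("unsupported genome representation: ", class(genome)[1])
}

.contig_seq <- function(genome, chrom) {
  genome <- .as_genome(genome)
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
  as.character(genome[[chrom]])
}

.subseq <- function(genome, chrom, start, end) {
  s <- .contig_seq(genome, chrom)
  if (start < 1L || end > nchar(s) || start > end)
    stop(sprintf("interval %s:%d-%d out of bounds", chrom, start, end))
  substr(s, start, end)
}

.revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# ---- domain types ---------------------------------------------------------

#' Polyadenylation signal
#'
#' One polyadenylation signal in the 3' flank of the source L1. Signal 1 is
#' the element's canonical (weak) signal; transductions terminate 10--30 bp
#' downstream of whichever signal the transcription machinery used.
#'
#' @param index ordinal position along the transcription direction (1 = canonical).
#' @param hexamer 6-mer signal motif (e.g. `"AATAAA"`, `"ATTAAA"`).
#' @param end_coord 1-based genomic coordinate of the signal's last base.
#' @return An object of class `polya_signal`.
#' @export
polya_signal <- function(index, hexamer, end_coord) {
  stopifnot(is.numeric(index), index >= 1, nchar(hexamer) == 6L, is.numeric(end_coord))
  structure(list(index = as.integer(index), hexamer = toupper(hexamer),
                 end_coord = as.integer(end_coord)),
            class = "polya_signal")
}

#' Restriction enzyme
#'
#' Only palindromic recognition sites are accepted: scanning the top strand is
#' then lossless, and the enzymes used for LDI-PCR on L1 source loci (PstI,
#' NsiI, SacI) are all palindromic cutters.
#'
#' @param name enzyme name.
#' @param recognition_site unambiguous DNA word (A/C/G/T only).
#' @param cut_offset cut position within the site on the top strand: the cut
#'   falls after base `cut_offset` of the site (0 = before the site's first base).
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("NsiI", "ATGCAT", 5)
#' @export
restriction_enzyme <- function(name, recognition_site, cut_offset) {
  recognition_site <- toupper(recognition_site)
  if (grepl("[^ACGT]", recognition_site))
    stop("recognition site must contain only A/C/G/T: ", recognition_site)
  if (.revcomp(recognition_site) != recognition_site)
    stop("non-palindromic recognition site rejected: ", recognition_site)
  if (cut_offset < 0 || cut_offset > nchar(recognition_site))
    stop("cut_offset outside the recognition site")
  structure(list(name = name, recognition_site = recognition_site,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' Inverse primer pair
#'
#' A pair of outward-facing primers on the unique tag. On the linear reference
#' the primers point away from each other; on a self-ligated circular template
#' they converge, so everything except the short inter-primer gap is amplified.
#' Coordinates are 1-based inclusive genomic positions of the primer footprints;
#' `rev` lies upstream (left) of `fwd` and anneals to the minus strand.
#'
#' @param name label used in reaction identifiers.
#' @param fwd_seq,rev_seq primer sequences, 5'->3'. `fwd_seq` equals the plus
#'   strand at `fwd_start..fwd_end`; `rev_seq` is the reverse complement of the
#'   plus strand at `rev_start..rev_end`.
#' @param fwd_start,fwd_end,rev_start,rev_end primer footprints.
#' @param max_gap maximum allowed inter-primer gap in bp (default 51).
#' @return An object of class `primer_pair` with computed `inter_primer_distance`.
#' @export
primer_pair <- function(name, fwd_seq, rev_seq, fwd_start, fwd_end,
                        rev_start, rev_end, max_gap = 51L) {
  fwd_seq <- toupper(fwd_seq); rev_seq <- toupper(rev_seq)
  if (grepl("[^ACGT]", paste0(fwd_seq, rev_seq)))
    stop("ambiguous bases in primers are not allowed")
  stopifnot(fwd_end - fwd_start + 1L == nchar(fwd_seq),
            rev_end - rev_start + 1L == nchar(rev_seq),
            rev_end < fwd_start)
  gap <- fwd_start - rev_end - 1L
  if (gap > max_gap)
    stop(sprintf("inter-primer distance %d exceeds the %d bp cap", gap, max_gap))
  structure(list(name = name, fwd_seq = fwd_seq, rev_seq = rev_seq,
                 fwd_start = as.integer(fwd_start), fwd_end = as.integer(fwd_end),
                 rev_start = as.integer(rev_start), rev_end = as.integer(rev_end),
                 inter_primer_distance = as.integer(gap)),
            class = "primer_pair")
}

#' Source L1 locus model
#'
#' Holds every genomic constant of the assay: the source element interval, its
#' 3' end region, the unique tag start (first base after the canonical
#' polyadenylation signal), the ordered polyadenylation signals, the inverse
#' primer pairs on the tag, and the restriction enzymes used for digestion.
#'
#' @param chrom contig carrying the source element.
#' @param l1_interval length-2 integer vector, 1-based inclusive interval of the
#'   L1 plus its captured 3' flank.
#' @param l1_3prime_end length-2 integer vector, the element's 3' end region
#'   (the transduced-tag neighbourhood); must lie within `l1_interval`.
#' @param tag_start coordinate of the first base of the unique tag.
#' @param polya_signals list of [polya_signal()], ordered along the
#'   transcription direction with signal 1 (canonical) first.
#' @param primer_pairs list of [primer_pair()]; both primers must lie in the tag.
#' @param enzymes list of [restriction_enzyme()].
#' @param transcription_direction `+1` if the element transcribes toward
#'   increasing coordinates, `-1` otherwise.
#' @return An object of class `source_locus`.
#' @export
source_locus <- function(chrom, l1_interval, l1_3prime_end, tag_start,
                         polya_signals, primer_pairs, enzymes,
                         transcription_direction = 1L) {
  l1_interval <- as.integer(l1_interval); l1_3prime_end <- as.integer(l1_3prime_end)
  stopifnot(length(l1_interval) == 2L, length(l1_3prime_end) == 2L,
            l1_interval[1] <= l1_interval[2],
            transcription_direction %in% c(-1L, 1L))
  if (l1_3prime_end[1] < l1_interval[1] || l1_3prime_end[2] > l1_interval[2])
    stop("l1_3prime_end must be contained in l1_interval")
  if (tag_start < l1_interval[1] || tag_start > l1_interval[2] + 1000L)
    stop("tag_start must lie inside l1_interval or at most 1 kb downstream")
  idx <- vapply(polya_signals, `[[`, integer(1), "index")
  if (!identical(idx, seq_along(polya_signals)))
    stop("polya_signals must be numbered 1..n in list order")
  ends <- vapply(polya_signals, `[[`, integer(1), "end_coord")
  if (any(diff(ends) * transcription_direction <= 0))
    stop("polya_signals must be strictly ordered along the transcription direction")
  structure(list(chrom = chrom, l1_interval = l1_interval,
                 l1_3prime_end = l1_3prime_end, tag_start = as.integer(tag_start),
                 polya_signals = polya_signals, primer_pairs = primer_pairs,
                 enzymes = enzymes,
                 transcription_direction = as.integer(transcription_direction)),
            class = "source_locus")
}

#' @export
print.source_locus <- function(x, ...) {
  cat(sprintf("source_locus %s:%d-%d (tag from %d, %d polyA signals, %d primer pairs, %d enzymes)\n",
              x$chrom, x$l1_interval[1], x$l1_interval[2], x$tag_start,
              length(x$polya_signals), length(x$primer_pairs), length(x$enzymes)))
  invisible(x)
}

#' Read or write a locus configuration
#'
#' The locus configuration is a YAML file whose keys mirror the fields of
#' [source_locus()]; all coordinates are 1-based inclusive.
#'
#' @param path file path.
#' @return `read_locus_config()` returns a `source_locus`;
#'   `write_locus_config()` returns `path` invisibly.
#' @export
read_locus_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  source_locus(
    chrom = cfg$chrom,
    l1_interval = unlist(cfg$l1_interval),
    l1_3prime_end = unlist(cfg$l1_3prime_end),
    tag_start = cfg$tag_start,
    polya_signals = lapply(cfg$polya_signals, function(s)
      polya_signal(s$index, s$hexamer, s$end_coord)),
    primer_pairs = lapply(cfg$primer_pairs, function(p)
      primer_pair(p$name, p$fwd_seq, p$rev_seq, p$fwd_start, p$fwd_end,
                  p$rev_start, p$rev_end)),
    enzymes = lapply(cfg$enzymes, function(e)
      restriction_enzyme(e$name, e$recognition_site, e$cut_offset)),
    transcription_direction = cfg$transcription_direction %||% 1L)
}

#' @rdname read_locus_config
#' @param locus a `source_locus`.
#' @export
write_locus_config <- function(locus, path) {
  stopifnot(inherits(locus, "source_locus"))
  cfg <- list(
    chrom = locus$chrom,
    l1_interval = as.list(locus$l1_interval),
    l1_3prime_end = as.list(locus$l1_3prime_end),
    tag_start = locus$tag_start,
    transcription_direction = locus$transcription_direction,
    polya_signals = lapply(locus$polya_signals, unclass),
    primer_pairs = lapply(locus$primer_pairs, unclass),
    enzymes = lapply(locus$enzymes, unclass))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- digestion ------------------------------------------------------------

#' Restriction cut positions
#'
#' Returns, per contig, the top-strand cut positions of an enzyme: a cut at
#' position `c` severs the phosphodiester bond between bases `c` and `c + 1`.
#' Recognition sites containing an ambiguous reference base never match.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param enzyme a [restriction_enzyme()].
#' @return Named list of sorted integer vectors (possibly empty), one per contig.
#' @export
cut_sites <- function(genome, enzyme) {
  genome <- .as_genome(genome)
  if (length(genome) == 0L) stop("empty genome")
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  site <- enzyme$recognition_site
  res <- lapply(seq_along(genome), function(i) {
    m <- Biostrings::matchPattern(site, genome[[i]], fixed = TRUE)
    cuts <- Biostrings::start(m) + enzyme$cut_offset - 1L
    len <- length(genome[[i]])
    sort(unique(cuts[cuts >= 1L & cuts < len]))  # cut at contig end is a no-op
  })
  names(res) <- names(genome)
  res
}

#' In-silico restriction digestion
#'
#' Cuts every contig at all occurrences of the enzyme's recognition site. The
#' returned fragments tile each contig exactly, in coordinate order.
#'
#' @inheritParams cut_sites
#' @param with_sequence attach fragment sequences (column `sequence`).
#' @return A data.frame with columns `chrom`, `start`, `end` (1-based inclusive)
#'   and attribute `"enzyme"` set to the enzyme name.
#' @examples
#' gen <- c(chrA = "AAGCTAGAATTCAAGAATTCAA")
#' ecoRI <- restriction_enzyme("EcoRI", "GAATTC", 1)
#' digest(gen, ecoRI)
#' @export
digest <- function(genome, enzyme, with_sequence = FALSE) {
  genome <- .as_genome(genome)
  cuts <- cut_sites(genome, enzyme)
  frags <- do.call(rbind, lapply(names(genome), function(chrom) {
    len <- length(genome[[chrom]])
    bounds <- c(0L, cuts[[chrom]], len)
    data.frame(chrom = chrom,
               start = head(bounds, -1L) + 1L,
               end = bounds[-1L],
               stringsAsFactors = FALSE)
  }))
  rownames(frags) <- NULL
  if (with_sequence)
    frags$sequence <- vapply(seq_len(nrow(frags)), function(i)
      .subseq(genome, frags$chrom[i], frags$start[i], frags$end[i]), character(1))
  attr(frags, "enzyme") <- enzyme$name
  frags
}

#' Locate the fragment containing an interval
#'
#' @param fragments output of [digest()].
#' @param chrom,start,end query interval (1-based inclusive).
#' @return A list with `status` either `"contained"` (plus the one-row
#'   `fragment`) or `"split"` (plus all overlapping `fragments`) when the
#'   interval straddles a cut site.
#' @export
fragment_containing <- function(fragments, chrom, start, end) {
  hit <- fragments[fragments$chrom == chrom & fragments$start <= start &
                     fragments$end >= end, , drop = FALSE]
  if (nrow(hit) == 1L) return(list(status = "contained", fragment = hit))
  ovl <- fragments[fragments$chrom == chrom & fragments$start <= end &
                     fragments$end >= start, , drop = FALSE]
  if (nrow(ovl) == 0L) stop(sprintf("interval %s:%d-%d not on a digested contig",
                                    chrom, start, end))
  list(status = "split", fragments = ovl)
}

#' Export digestion fragments as BED
#'
#' BED is 0-based half-open; the conversion from the package's 1-based
#' inclusive fragments happens here.
#'
#' @param fragments output of [digest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(chrom = fragments$chrom, start = fragments$start - 1L,
                    end = fragments$end,
                    name = sprintf("%s_frag%d", attr(fragments, "enzyme") %||% "fragment",
                                   seq_len(nrow(fragments))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- circularization and amplicon prediction ------------------------------

#' Self-ligate a fragment into a circular template
#'
#' @param fragment either a fragment sequence or a one-row fragment data.frame
#'   from [digest()] together with `genome`.
#' @param genome genome, required when `fragment` is a data.frame row.
#' @return An object of class `circular_template`: the stored linear rotation,
#'   its length, and the origin of the stored rotation. Any rotation represents
#'   the same circle; the ligation junction sits between the last and first
#'   base of the stored rotation.
#' @export
circularize <- function(fragment, genome = NULL) {
  if (is.data.frame(fragment)) {
    stopifnot(nrow(fragment) == 1L, !is.null(genome))
    seq <- .subseq(genome, fragment$chrom, fragment$start, fragment$end)
    origin <- list(chrom = fragment$chrom, start = fragment$start, end = fragment$end)
  } else {
    seq <- toupper(as.character(fragment))
    origin <- NULL
  }
  if (nchar(seq) < 1L) stop("cannot circularize an empty fragment")
  structure(list(sequence = seq, length = nchar(seq), origin = origin),
            class = "circular_template")
}

#' Rotate a circular template
#'
#' Returns an equivalent representation of the same circle whose stored linear
#' sequence starts `by` bases later.
#'
#' @param template a `circular_template`.
#' @param by rotation offset in bases (any integer).
#' @return A `circular_template`.
#' @export
rotate_circle <- function(template, by) {
  stopifnot(inherits(template, "circular_template"))
  n <- template$length
  by <- ((by %% n) + n) %% n
  if (by == 0L) return(template)
  s <- template$sequence
  template$sequence <- paste0(substr(s, by + 1L, n), substr(s, 1L, by))
  template$origin <- NULL  # rotation loses the junction bookkeeping
  template
}

#' Linearize a circular template
#'
#' @param template a `circular_template`.
#' @return The stored linear rotation as a character string.
#' @export
linearize <- function(template) {
  stopifnot(inherits(template, "circular_template"))
  template$sequence
}

# all circular occurrences of `pattern` (start positions 1..n on the circle)
.circular_matches <- function(circle_seq, pattern) {
  n <- nchar(circle_seq)
  k <- nchar(pattern)
  if (k > n) return(integer(0))
  doubled <- paste0(circle_seq, substr(circle_seq, 1L, min(k - 1L, n)))
  m <- Biostrings::start(Biostrings::matchPattern(pattern, Biostrings::DNAString(doubled),
                                                  fixed = TRUE))
  sort(unique(m[m <= n]))
}

.circular_substr <- function(circle_seq, from, to) {
  n <- nchar(circle_seq)
  from <- ((from - 1L) %% n) + 1L
  to <- ((to - 1L) %% n) + 1L
  if (from <= to) substr(circle_seq, from, to)
  else paste0(substr(circle_seq, from, n), substr(circle_seq, 1L, to))
}

#' Predict the inverse-PCR amplicon of a circular template
#'
#' The amplicon runs from the forward primer's 5' end around the circle --
#' through the ligation junction -- to the reverse primer's 5' end, leaving
#' only the short inter-primer gap unamplified. Both strands of the circle are
#' searched; the returned sequence reads 5'->3' from the forward primer.
#'
#' @param template a `circular_template`.
#' @param pair a [primer_pair()].
#' @return A list with `status` (`"ok"`, `"no_amplicon"` or `"ambiguous"`),
#'   `sequence` (when `status == "ok"`), `length`, and `strand` (the circle
#'   strand the forward primer annealed to).
#' @export
predict_amplicon <- function(template, pair) {
  stopifnot(inherits(template, "circular_template"), inherits(pair, "primer_pair"))
  for (strand in c("+", "-")) {
    circ <- if (strand == "+") template$sequence else .revcomp(template$sequence)
    f <- .circular_matches(circ, pair$fwd_seq)
    r <- .circular_matches(circ, .revcomp(pair$rev_seq))
    if (length(f) > 1L || length(r) > 1L)
      return(list(status = "ambiguous", sequence = NULL, length = NA_integer_,
                  strand = strand))
    if (length(f) == 0L || length(r) == 0L) next
    amp <- .circular_substr(circ, f, r + nchar(pair$rev_seq) - 1L)
    return(list(status = "ok", sequence = amp, length = nchar(amp), strand = strand))
  }
  list(status = "no_amplicon", sequence = NULL, length = NA_integer_, strand = NA_character_)
}
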