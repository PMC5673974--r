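# Independent oracles and shared fixtures for the test suite. The oracles are
# deliberately naive (plain loops, brute force) so they cannot share a defect
# with the implementation they check.

# one synthetic experiment genome shared across test files (seed fixed)
shared_gm <- local({
  gm <- NULL
  function() {
    if (is.null(gm)) gm <<- make_genome(101L)
    gm
  }
})

shared_cut_maps <- function(gm) {
  cm <- lapply(gm$locus$enzymes, function(e) cut_sites(gm$genome, e))
  names(cm) <- vapply(gm$locus$enzymes, `[[`, "", "name")
  cm
}

# textbook Needleman-Wunsch global alignment score, linear gap
nw_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- matrix(0, length(a) + 1L, length(b) + 1L)
  m[, 1] <- gap * (0:length(a)); m[1, ] <- gap * (0:length(b))
  for (i in seq_along(a)) for (j in seq_along(b))
    m[i + 1, j + 1] <- max(m[i, j] + if (a[i] == b[j]) match else mismatch,
                           m[i, j + 1] + gap, m[i + 1, j] + gap)
  m[length(a) + 1, length(b) + 1]
}

# brute-force digestion: scan for every site occurrence with a character loop
scan_cuts <- function(seq, site, cut_offset) {
  n <- nchar(seq); k <- nchar(site)
  cuts <- integer(0)
  for (s in seq_len(max(0L, n - k + 1L)))
    if (substr(seq, s, s + k - 1L) == site) cuts <- c(cuts, s + cut_offset - 1L)
  cuts[cuts >= 1L & cuts < n]
}

# brute-force CIGAR walk, one operation at a time
walk_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ref <- 0L; q <- 0L; lead <- 0L; seen_aln <- FALSE; clip <- 0L
  for (o in ops) {
    len <- as.integer(sub("[A-Z=]$", "", o))
    op <- sub("^[0-9]+", "", o)
    if (op %in% c("M", "=", "X")) { ref <- ref + len; q <- q + len; seen_aln <- TRUE }
    else if (op == "I") { q <- q + len; seen_aln <- TRUE }
    else if (op %in% c("D", "N")) ref <- ref + len
    else if (op %in% c("S", "H")) {
      clip <- clip + len
      if (!seen_aln) lead <- lead + len
    }
  }
  list(ref_span = ref, q_start = lead + 1L, q_end = lead + q, q_len = q + clip)
}

random_cigar <- function() {
  lead <- sample(0:20, 1)
  trail <- sample(0:20, 1)
  n_ops <- sample(1:7, 1)
  mid <- character(0)
  last <- ""
  for (i in seq_len(n_ops)) {
    op <- sample(setdiff(c("M", "I", "D"), last), 1)
    # indels must be separated by aligned blocks to keep the CIGAR plausible
    if (op != "M" && (length(mid) == 0 || last != "M")) op <- "M"
    mid <- c(mid, paste0(sample(1:50, 1), op))
    last <- op
  }
  paste0(if (lead > 0) paste0(lead, "S") else "",
         paste(mid, collapse = ""),
         if (trail > 0) paste0(trail, "S") else "")
}

# brute-force Mann-Whitney U: count pairs
brute_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# build a read_alignment_group directly from a segment table
make_group <- function(read_id, segments, read_length = 1000L,
                       sample = "s1", reaction = "NsiI.pp1") {
  structure(list(read_id = read_id, read_length = read_length,
                 sample = sample, reaction = reaction,
                 segments = segments),
            class = "read_alignment_group")
}

seg_row <- function(contig, ref_start, ref_end, query_start, query_end,
                    strand = "+", mapq = 60L, supplementary = FALSE) {
  data.frame(contig = contig, ref_start = ref_start, ref_end = ref_end,
             query_start = query_start, query_end = query_end,
             strand = strand, mapq = mapq, supplementary = supplementary,
             stringsAsFactors = FALSE)
}

# minimal segmentation object for unit tests of downstream operations;
# accepts the read-segment column names from seg_row() and renames them
make_segmentation <- function(segments, status = "ok", length = NULL,
                              unexplained = 0L) {
  nm <- names(segments)
  nm[nm == "query_start"] <- "q_start"
  nm[nm == "query_end"] <- "q_end"
  names(segments) <- nm
  if (!"chrom" %in% nm && "contig" %in% nm) segments$chrom <- segments$contig
  structure(list(status = status, segments = segments,
                 length = length %||% max(segments$q_end),
                 unexplained = unexplained),
            class = "segmentation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
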