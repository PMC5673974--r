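# SAM ingestion: parse alignment records into per-read grouped segment models
# with exact query/reference interval geometry derived from CIGAR strings.

.CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

.parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", ops)),
       op = sub("^[0-9]+", "", ops))
}

#' CIGAR interval arithmetic
#'
#' Computes, from a CIGAR string, the reference span, the query interval of
#' the aligned portion in the orientation stored in the record (1-based,
#' clips excluded), and the full query length including soft and hard clips.
#'
#' @param cigar a CIGAR string.
#' @return A list with `ref_span`, `q_start`, `q_end`, `q_len`.
#' @examples
#' cigar_spans("10S90M")   # query 11..100 on a 100-base read
#' @export
cigar_spans <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !grepl(.CIGAR_RE, cigar))
    stop("malformed CIGAR: ", cigar)
  p <- .parse_cigar(cigar)
  ref <- sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  qcons <- p$op %in% c("M", "I", "=", "X")
  clip <- p$op %in% c("S", "H")
  lead <- 0L
  for (i in seq_along(p$op)) {
    if (clip[i]) lead <- lead + p$len[i] else break
  }
  qaln <- sum(p$len[qcons])
  qlen <- qaln + sum(p$len[clip])
  if (qaln == 0L) stop("CIGAR consumes no query: ", cigar)
  list(ref_span = ref, q_start = lead + 1L, q_end = lead + qaln, q_len = qlen)
}

#' Read SAM alignment records
#'
#' A minimal text-SAM reader: unmapped records are dropped, malformed CIGARs
#' are skipped with a warning, and per-reason drop counts are attached as the
#' `"diagnostics"` attribute.
#'
#' @param x path to a SAM file, or a character vector of SAM lines.
#' @return A data.frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`.
#' @export
read_sam <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[!startsWith(lines, "@")]
  diag <- c(unmapped = 0L, malformed_cigar = 0L, truncated = 0L)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) { diag["truncated"] <- diag["truncated"] + 1L; next }
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag) || bitwAnd(flag, 4L) != 0L || f[3] == "*") {
      diag["unmapped"] <- diag["unmapped"] + 1L; next
    }
    if (f[6] == "*" || !grepl(.CIGAR_RE, f[6])) {
      diag["malformed_cigar"] <- diag["malformed_cigar"] + 1L; next
    }
    rows[[i]] <- data.frame(qname = f[1], flag = flag, rname = f[3],
                            pos = as.integer(f[4]), mapq = as.integer(f[5]),
                            cigar = f[6], seq = f[10], stringsAsFactors = FALSE)
  }
  if (diag["malformed_cigar"] > 0L)
    warning(diag["malformed_cigar"], " record(s) skipped: malformed CIGAR")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(qname = character(0), flag = integer(0), rname = character(0),
                      pos = integer(0), mapq = integer(0), cigar = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- diag
  out
}

#' Group SAM records into per-read alignment-segment models
#'
#' Converts each mapped record into an alignment segment with 1-based
#' inclusive reference and query intervals, where query coordinates are
#' expressed in the *original read orientation* (reverse-strand records are
#' reflected through the read length). Records sharing a read name form one
#' group, sorted by query start. Sample and reaction labels are taken from
#' read names of the form `sample~reaction~name` (both `NA` otherwise).
#'
#' @param sam a SAM path, SAM lines, or the data.frame from [read_sam()].
#' @return A list of `read_alignment_group` objects: each has `read_id`,
#'   `read_length`, `sample`, `reaction` and a `segments` data.frame
#'   (`contig`, `ref_start`, `ref_end`, `query_start`, `query_end`, `strand`,
#'   `mapq`, `supplementary`).
#' @export
read_alignment_groups <- function(sam) {
  recs <- if (is.data.frame(sam)) sam else read_sam(sam)
  if (nrow(recs) == 0L) return(list())
  segs <- lapply(seq_len(nrow(recs)), function(i) {
    sp <- cigar_spans(recs$cigar[i])
    rev <- bitwAnd(recs$flag[i], 16L) != 0L
    L <- sp$q_len
    if (rev) { qs <- L - sp$q_end + 1L; qe <- L - sp$q_start + 1L }
    else { qs <- sp$q_start; qe <- sp$q_end }
    data.frame(qname = recs$qname[i], contig = recs$rname[i],
               ref_start = recs$pos[i], ref_end = recs$pos[i] + sp$ref_span - 1L,
               query_start = qs, query_end = qe,
               strand = if (rev) "-" else "+", mapq = recs$mapq[i],
               supplementary = bitwAnd(recs$flag[i], 2048L) != 0L,
               read_length = L, stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  lapply(split(segs, segs$qname), function(g) {
    g <- g[order(g$query_start, g$query_end), , drop = FALSE]
    lab <- strsplit(g$qname[1], "~", fixed = TRUE)[[1]]
    structure(list(read_id = g$qname[1],
                   read_length = max(g$read_length),
                   sample = if (length(lab) >= 3L) lab[1] else NA_character_,
                   reaction = if (length(lab) >= 3L) lab[2] else NA_character_,
                   segments = g[, c("contig", "ref_start", "ref_end", "query_start",
                                    "query_end", "strand", "mapq", "supplementary")]),
              class = "read_alignment_group")
  })
}

#' Assign a read group to its restriction reaction
#'
#' Compares the outermost reference ends of the read's amplicon footprint with
#' the digestion fragment boundaries of each enzyme: a self-ligated circular
#' template yields an amplicon whose alignment footprint on each involved
#' contig ends at fragment boundaries. The enzyme whose boundaries lie within
#' `tolerance_bp` of every footprint end is assigned; ties are broken by the
#' smaller total end distance.
#'
#' @param group a `read_alignment_group`.
#' @param locus a [source_locus()] (provides the enzymes).
#' @param genome the reference genome (for cut maps), or a precomputed named
#'   list of cut maps via `cut_maps`.
#' @param tolerance_bp maximum end-to-boundary distance (default 10).
#' @param cut_maps optional named list `enzyme -> cut_sites()` output.
#' @return A single reaction label: the enzyme name, `"unassigned"` or
#'   `"ambiguous"`.
#' @export
assign_reaction <- function(group, locus, genome = NULL, tolerance_bp = 10L,
                            cut_maps = NULL) {
  stopifnot(inherits(group, "read_alignment_group"))
  if (is.null(cut_maps)) {
    if (is.null(genome)) stop("provide genome or cut_maps")
    cut_maps <- lapply(locus$enzymes, function(e) cut_sites(genome, e))
    names(cut_maps) <- vapply(locus$enzymes, `[[`, "", "name")
  }
  segs <- group$segments
  # footprint clusters: per contig, segments within 5 kb belong to one locus
  # (the circularized fragment); the fragment's footprint must end at
  # digestion boundaries, other clusters (e.g. the donor segments inside an
  # insertion read) need not
  foot <- do.call(rbind, lapply(split(segs, segs$contig), function(s) {
    s <- s[order(s$ref_start), , drop = FALSE]
    grp <- cumsum(c(1L, diff(s$ref_start) > 5000L))
    do.call(rbind, lapply(split(s, grp), function(cl)
      data.frame(contig = cl$contig[1], lo = min(cl$ref_start),
                 hi = max(cl$ref_end), stringsAsFactors = FALSE)))
  }))
  scores <- vapply(names(cut_maps), function(enz) {
    cuts <- cut_maps[[enz]]
    best <- Inf
    for (i in seq_len(nrow(foot))) {
      cc <- cuts[[foot$contig[i]]]
      if (is.null(cc) || length(cc) == 0L) next
      # fragment starts sit at cut+1, fragment ends at cut
      d_lo <- min(abs(foot$lo[i] - (cc + 1L)))
      d_hi <- min(abs(foot$hi[i] - cc))
      if (d_lo <= tolerance_bp && d_hi <= tolerance_bp)
        best <- min(best, d_lo + d_hi)
    }
    best
  }, numeric(1))
  ok <- scores[is.finite(scores)]
  if (length(ok) == 0L) return("unassigned")
  best <- min(ok)
  winners <- names(ok)[ok == best]
  if (length(winners) > 1L) return("ambiguous")
  winners
}
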