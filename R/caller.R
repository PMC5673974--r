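# Insertion calling from chimeric LDI-PCR reads: hallmark detection,
# breakpoint extraction at alignment switch points, single-linkage clustering,
# modal-coordinate calling, and the filter cascade (support, cut-site
# distance, contig whitelist, cross-sample crosstalk, per-reaction dedup).

#' Caller parameters
#'
#' Thresholds of the calling filter cascade. Defaults follow the assay's
#' published operating point: mapping quality at least 20, target segments
#' confined to one locus within 100 kb, breakpoints clustered with a maximum
#' gap of 3 kb, calls supported by at least 5 reads, at least 35 bp from the
#' closest cut site of the reaction's enzyme, and a 95% read-share majority to
#' resolve barcode crosstalk between samples. All boundary comparisons are
#' inclusive.
#'
#' @param l1_interval source-element interval (from the locus model).
#' @param l1_chrom contig of the source element.
#' @param min_mapq minimum mapping quality.
#' @param max_target_span maximum pairwise distance between target segments.
#' @param cluster_max_gap single-linkage clustering gap in bp.
#' @param min_support minimum distinct supporting reads.
#' @param min_cut_distance minimum call-to-cut-site distance in bp.
#' @param crosstalk_majority read-share a sample must hold to keep a call
#'   observed in several samples.
#' @param contig_whitelist contigs on which calls are reportable.
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(l1_interval, l1_chrom, min_mapq = 20L,
                          max_target_span = 100000L, cluster_max_gap = 3000L,
                          min_support = 5L, min_cut_distance = 35L,
                          crosstalk_majority = 0.95,
                          contig_whitelist = paste0("chr", c(1:22, "X", "Y"))) {
  stopifnot(min_mapq > 0, max_target_span > 0, cluster_max_gap > 0,
            min_support > 0, min_cut_distance > 0,
            crosstalk_majority > 0.5, crosstalk_majority <= 1)
  structure(list(l1_interval = as.integer(l1_interval), l1_chrom = l1_chrom,
                 min_mapq = as.integer(min_mapq),
                 max_target_span = as.integer(max_target_span),
                 cluster_max_gap = as.integer(cluster_max_gap),
                 min_support = as.integer(min_support),
                 min_cut_distance = as.integer(min_cut_distance),
                 crosstalk_majority = crosstalk_majority,
                 contig_whitelist = contig_whitelist),
            class = "caller_params")
}

#' @rdname caller_params
#' @param locus a [source_locus()].
#' @param ... overrides passed to `caller_params()`.
#' @export
caller_params_from_locus <- function(locus, ...) {
  caller_params(l1_interval = locus$l1_interval, l1_chrom = locus$chrom, ...)
}

.is_source_seg <- function(segments, params) {
  segments$contig == params$l1_chrom &
    segments$ref_start <= params$l1_interval[2] &
    segments$ref_end >= params$l1_interval[1]
}

#' Identify hallmark LDI-PCR reads
#'
#' A hallmark read is the evidence unit of an insertion-specific LDI-PCR
#' product: among its segments with mapping quality at least `min_mapq`, it
#' has at least one alignment overlapping the source-element interval, at
#' least one alignment outside it, and all outside alignments fall on a single
#' contig with pairwise distance at most `max_target_span`.
#'
#' @param groups list of `read_alignment_group` (see
#'   [read_alignment_groups()]).
#' @param params a [caller_params()].
#' @return The hallmark subset of `groups` (possibly empty).
#' @export
find_hallmark_reads <- function(groups, params) {
  Filter(function(g) {
    s <- g$segments[g$segments$mapq >= params$min_mapq, , drop = FALSE]
    if (nrow(s) == 0L) return(FALSE)
    src <- .is_source_seg(s, params)
    if (!any(src)) return(FALSE)
    tgt <- s[!src, , drop = FALSE]
    if (nrow(tgt) == 0L) return(FALSE)
    if (length(unique(tgt$contig)) != 1L) return(FALSE)
    max(tgt$ref_end) - min(tgt$ref_start) <= params$max_target_span
  }, groups)
}

#' Extract insertion breakpoints from a hallmark read
#'
#' Walks the read's segments in query order and, at every switch between a
#' source-element segment and a target segment, records the target-side
#' reference coordinate adjacent to the switch (the target segment's reference
#' end facing the source segment in query space).
#'
#' @param group a hallmark `read_alignment_group`.
#' @param params a [caller_params()].
#' @return A data.frame of breakpoints: `contig`, `coordinate`, `orientation`
#'   (`"source_to_target"` / `"target_to_source"`), `read_id`.
#' @export
extract_breakpoints <- function(group, params) {
  s <- group$segments[group$segments$mapq >= params$min_mapq, , drop = FALSE]
  s <- s[order(s$query_start, s$query_end), , drop = FALSE]
  src <- .is_source_seg(s, params)
  out <- list()
  for (i in seq_len(nrow(s) - 1L)) {
    if (src[i] == src[i + 1L]) next
    tgt <- if (src[i]) i + 1L else i
    # query-adjacent end of the target segment: its start-side in query space
    # when the source precedes it, its end-side when it precedes the source
    left_end <- src[i]  # target is the right member -> use its query-left end
    coord <- if (left_end == (s$strand[tgt] == "+")) s$ref_start[tgt] else s$ref_end[tgt]
    out[[length(out) + 1L]] <- data.frame(
      contig = s$contig[tgt], coordinate = coord,
      orientation = if (src[i]) "source_to_target" else "target_to_source",
      read_id = group$read_id, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), coordinate = integer(0),
                      orientation = character(0), read_id = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Cluster breakpoints by single linkage
#'
#' Per contig, sorted breakpoint coordinates are chained while consecutive
#' coordinates differ by at most `cluster_max_gap`; the result is independent
#' of input order.
#'
#' @param breakpoints data.frame from [extract_breakpoints()] (one
#'   sample+reaction).
#' @param cluster_max_gap maximum within-cluster gap in bp.
#' @return The input with an added `cluster` column (`contig:index`).
#' @export
cluster_breakpoints <- function(breakpoints, cluster_max_gap = 3000L) {
  if (nrow(breakpoints) == 0L) {
    breakpoints$cluster <- character(0)
    return(breakpoints)
  }
  bp <- breakpoints[order(breakpoints$contig, breakpoints$coordinate), , drop = FALSE]
  parts <- lapply(split(bp, bp$contig), function(b) {
    b$cluster <- paste0(b$contig[1], ":",
                        cumsum(c(1L, diff(b$coordinate) > cluster_max_gap)))
    b
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Call the insertion coordinate of a breakpoint cluster
#'
#' The most frequent coordinate wins; ties go to the smallest coordinate.
#'
#' @param coordinates integer vector of member breakpoint coordinates.
#' @return The called coordinate.
#' @export
call_coordinate <- function(coordinates) {
  stopifnot(length(coordinates) > 0L)
  tab <- table(coordinates)
  min(as.integer(names(tab)[tab == max(tab)]))  # tie -> smallest coordinate
}

.calls_from_breakpoints <- function(bp, sample, reaction, params) {
  bp <- cluster_breakpoints(bp, params$cluster_max_gap)
  if (nrow(bp) == 0L) return(NULL)
  do.call(rbind, lapply(split(bp, bp$cluster), function(cl) {
    reads <- unique(cl$read_id)
    data.frame(sample = sample, reaction = reaction, contig = cl$contig[1],
               coordinate = call_coordinate(cl$coordinate),
               read_count = length(reads),
               reads = paste(reads, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Apply the per-call filter cascade
#'
#' Adds filter flags and a pass/fail status: support (`read_count >=
#' min_support`), cut distance (call coordinate at least `min_cut_distance`
#' from the closest cut site of the reaction's enzyme), and contig whitelist
#' (mitochondrial and unplaced contigs are excluded). Boundary values pass.
#'
#' @param calls call data.frame (from the pipeline or
#'   `.calls_from_breakpoints`).
#' @param cut_maps named list `enzyme -> cut_sites()` output; the enzyme of a
#'   call's reaction is the label's prefix before `"."`.
#' @param params a [caller_params()].
#' @return `calls` with logical flag columns `fail_support`,
#'   `fail_cut_distance`, `fail_contig` and a `status` column.
#' @export
filter_calls <- function(calls, cut_maps, params) {
  if (nrow(calls) == 0L) {
    calls$fail_support <- logical(0); calls$fail_cut_distance <- logical(0)
    calls$fail_contig <- logical(0); calls$status <- character(0)
    return(calls)
  }
  enzymes <- sub("\\..*$", "", calls$reaction)
  unknown <- setdiff(unique(enzymes), names(cut_maps))
  if (length(unknown) > 0L)
    stop("no cut map for enzyme(s): ", paste(unknown, collapse = ", "))
  calls$fail_support <- calls$read_count < params$min_support
  calls$fail_cut_distance <- vapply(seq_len(nrow(calls)), function(i) {
    cuts <- cut_maps[[enzymes[i]]][[calls$contig[i]]]
    if (is.null(cuts) || length(cuts) == 0L) return(FALSE)
    min(abs(calls$coordinate[i] - cuts)) < params$min_cut_distance
  }, logical(1))
  calls$fail_contig <- !(calls$contig %in% params$contig_whitelist)
  calls$status <- ifelse(calls$fail_support | calls$fail_cut_distance |
                           calls$fail_contig, "fail", "pass")
  calls
}

# match calls across rows (same contig, coordinates within gap): returns a
# group id per row, independent of row order
.match_calls <- function(calls, gap) {
  grp <- integer(nrow(calls))
  for (ct in unique(calls$contig)) {
    idx <- which(calls$contig == ct)
    o <- idx[order(calls$coordinate[idx])]
    g <- cumsum(c(1L, diff(calls$coordinate[o]) > gap))
    grp[o] <- paste0(ct, ":", g)
  }
  grp
}

#' Resolve barcode crosstalk between samples
#'
#' Calls at the same location (same contig, coordinates within
#' `cluster_max_gap`) observed in more than one sample are attributed to the
#' sample holding at least `crosstalk_majority` of the total supporting reads;
#' all other members -- and every member, when no sample reaches the majority
#' -- are flagged `fail_crosstalk`.
#'
#' @param calls filtered call data.frame across all samples.
#' @param params a [caller_params()].
#' @return `calls` with a `fail_crosstalk` column and updated `status`.
#' @export
resolve_crosstalk <- function(calls, params) {
  calls$fail_crosstalk <- FALSE
  if (nrow(calls) == 0L) return(calls)
  grp <- .match_calls(calls, params$cluster_max_gap)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(unique(calls$sample[idx])) <= 1L) next
    by_sample <- tapply(calls$read_count[idx], calls$sample[idx], sum)
    share <- by_sample / sum(by_sample)
    winner <- names(share)[share >= params$crosstalk_majority]
    calls$fail_crosstalk[idx] <- if (length(winner) == 1L)
      calls$sample[idx] != winner else TRUE
  }
  calls$status <- ifelse(calls$status == "fail" | calls$fail_crosstalk,
                         "fail", "pass")
  calls
}

#' Deduplicate calls across reactions within a sample
#'
#' The same insertion detected by several enzyme/primer reactions is reported
#' once: the member with the highest read count wins (ties go to the
#' lexicographically first reaction label); all member reactions are recorded
#' in `all_reactions`.
#'
#' @param calls call data.frame of one sample (or several; matching is within
#'   sample).
#' @param params a [caller_params()].
#' @return One representative row per insertion per sample, with
#'   `all_reactions` listing the merged reactions.
#' @export
dedup_reactions <- function(calls, params) {
  if (nrow(calls) == 0L) { calls$all_reactions <- character(0); return(calls) }
  out <- lapply(split(calls, calls$sample), function(cs) {
    grp <- .match_calls(cs, params$cluster_max_gap)
    do.call(rbind, lapply(split(cs, grp), function(m) {
      m <- m[order(-m$read_count, m$reaction), , drop = FALSE]
      rep1 <- m[1L, , drop = FALSE]
      rep1$all_reactions <- paste(sort(unique(m$reaction)), collapse = ",")
      rep1
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample, out$contig, out$coordinate), , drop = FALSE]
}

#' Call L1 3'-transduction insertions from aligned LDI-PCR reads
#'
#' The full calling pipeline: hallmark-read detection, per-read breakpoint
#' extraction, per-sample/per-reaction clustering and modal-coordinate
#' calling, the filter cascade, cross-sample crosstalk resolution, and
#' per-reaction deduplication. Deterministic for any input record order.
#'
#' @param groups list of `read_alignment_group`.
#' @param params a [caller_params()].
#' @param cut_maps named list `enzyme -> cut_sites()` output for the enzymes
#'   appearing in reaction labels.
#' @return A data.frame of calls (all statuses retained): `sample`,
#'   `reaction`, `all_reactions`, `contig`, `coordinate`, `read_count`,
#'   filter flags, `status`, and the comma-separated supporting `reads`.
#' @export
call_insertions <- function(groups, params, cut_maps) {
  hall <- find_hallmark_reads(groups, params)
  if (length(hall) == 0L)
    return(data.frame(sample = character(0), reaction = character(0),
                      contig = character(0), coordinate = integer(0),
                      read_count = integer(0), stringsAsFactors = FALSE))
  bp <- do.call(rbind, lapply(hall, function(g) {
    b <- extract_breakpoints(g, params)
    if (nrow(b) > 0L) { b$sample <- g$sample; b$reaction <- g$reaction }
    b
  }))
  empty <- data.frame(sample = character(0), reaction = character(0),
                      contig = character(0), coordinate = integer(0),
                      read_count = integer(0), stringsAsFactors = FALSE)
  if (is.null(bp) || nrow(bp) == 0L) return(empty)
  bp <- bp[!is.na(bp$sample), , drop = FALSE]
  calls <- do.call(rbind, lapply(split(bp, paste(bp$sample, bp$reaction)),
                                 function(b)
                                   .calls_from_breakpoints(b, b$sample[1],
                                                           b$reaction[1], params)))
  if (is.null(calls)) return(empty)
  rownames(calls) <- NULL
  calls <- filter_calls(calls, cut_maps, params)
  calls <- resolve_crosstalk(calls, params)
  calls <- dedup_reactions(calls, params)
  stopifnot(all(calls$status != "pass" |
                  (!calls$fail_support & !calls$fail_cut_distance &
                     !calls$fail_contig & !calls$fail_crosstalk)))
  calls
}

#' Write insertion calls
#'
#' `write_calls_tsv()` writes the full call table (supporting read ids go to a
#' `<path>.reads.tsv` sidecar for the consensus stage); `write_calls_bed()`
#' writes pass calls as 0-based half-open BED.
#'
#' @param calls call data.frame from [call_insertions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  main <- calls[, setdiff(names(calls), "reads"), drop = FALSE]
  utils::write.table(main, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- data.frame(call = paste0(calls$contig, ":", calls$coordinate,
                                      ":", calls$sample),
                        reads = calls$reads)
  utils::write.table(sidecar, paste0(path, ".reads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_calls_bed <- function(calls, path) {
  pass <- calls[calls$status == "pass", , drop = FALSE]
  bed <- data.frame(chrom = pass$contig, start = pass$coordinate - 1L,
                    end = pass$coordinate,
                    name = paste0(pass$sample, "_", pass$read_count, "reads"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
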