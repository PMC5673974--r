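# Summary statistics over insertion catalogues: the packaged two-tumour
# catalogue of 39 somatic L1 3'-transduction insertions, a continuity-corrected
# Wilcoxon rank-sum test, and the per-study report (group read-count medians,
# target-site-modification and twin-priming tallies, insertion-length range).

.catalogue_columns <- c("sample", "contig", "junction5", "junction3", "gene",
                        "tsm_type", "tsm_size", "donor_start", "donor_end",
                        "strand", "twin_priming", "insertion_bp", "lower_bound",
                        "internal_dup", "read_count", "validated",
                        "wgs_detected", "wgs_read_count")

#' Load an insertion catalogue
#'
#' With no arguments, loads the packaged catalogue of 39 somatic L1
#' 3'-transduction insertions detected in two colorectal tumour samples
#' (c985T, c368T) by LDI-PCR/Nanopore sequencing, and validates it (39 rows,
#' 14 WGS-detected, every call supported by at least 5 reads). A custom path
#' is schema-validated only.
#'
#' @param path optional path to a catalogue TSV with the packaged schema.
#' @return A data.frame, one row per insertion.
#' @export
load_insertion_catalogue <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged)
    path <- system.file("extdata", "crc_insertion_catalogue.tsv",
                        package = "ldipcr", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(contig = "character"))
  missing <- setdiff(.catalogue_columns, names(df))
  if (length(missing) > 0L)
    stop("catalogue is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(df$tsm_type %in% c("duplication", "deletion", "blunt", NA)))
    stop("invalid tsm_type value in catalogue")
  if (any(df$read_count < 5L))
    stop("catalogue contains calls supported by fewer than 5 reads")
  if (packaged && nrow(df) != 39L)
    stop("packaged catalogue must contain 39 records, found ", nrow(df))
  if (packaged && sum(df$wgs_detected == "yes") != 14L)
    stop("packaged catalogue must contain 14 WGS-detected insertions")
  df
}

#' Wilcoxon rank-sum test (normal approximation, continuity-corrected)
#'
#' Mann-Whitney U from midranks, normal approximation with tie-corrected
#' variance and a 0.5 continuity correction, two-sided. The normal
#' approximation is always used (read-count data are tied and span orders of
#' magnitude); identical samples give p = 1.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param continuity apply the 0.5 continuity correction (default `TRUE`).
#' @return A list: `U` (for `x` against `y`), `z`, `p`, `n1`, `n2`,
#'   `tie_corrected` (`TRUE` when the variance was tie-corrected).
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(U = U, z = 0, p = 1, n1 = n1, n2 = n2, tie_corrected = TRUE))
  z <- U - n1 * n2 / 2
  if (continuity) z <- z - sign(z) * 0.5
  z <- z / sqrt(sigma2)
  p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  list(U = U, z = z, p = p, n1 = n1, n2 = n2, tie_corrected = any(ties > 1))
}

#' Convert pipeline characterizations to catalogue records
#'
#' Maps the output of [characterize_insertion()] rows onto the catalogue
#' schema so [summarize_insertions()] can digest pipeline output directly.
#'
#' @param chars data.frame of characterizations.
#' @return A catalogue-schema data.frame.
#' @export
as_insertion_records <- function(chars) {
  data.frame(
    sample = chars$sample, contig = chars$contig,
    junction5 = chars$junction5, junction3 = chars$junction3,
    gene = NA_character_, tsm_type = chars$tsm_type,
    tsm_size = chars$tsm_size, donor_start = chars$donor_start,
    donor_end = chars$donor_end, strand = chars$strand,
    twin_priming = ifelse(is.na(chars$twin_priming), NA_character_,
                          ifelse(chars$twin_priming, "present", "absent")),
    insertion_bp = chars$insertion_len, lower_bound = !chars$complete,
    internal_dup = FALSE, read_count = chars$read_count,
    validated = "no", wgs_detected = "no", wgs_read_count = 0L,
    stringsAsFactors = FALSE)
}

#' Summarize an insertion catalogue
#'
#' Computes the study's headline summaries: insertion counts per sample and
#' per WGS-detection status, read-count group medians with Wilcoxon rank-sum
#' comparisons (novel vs WGS-detected; validated vs unvalidated among novel),
#' target-site-modification and twin-priming tallies over the insertions with
#' complete sequence (lower-bound rows excluded), and insertion-length
#' minimum / maximum / mean over complete insertions.
#'
#' @param records catalogue data.frame ([load_insertion_catalogue()] or
#'   [as_insertion_records()]).
#' @return An object of class `ldi_report` (a list of summaries); empty input
#'   yields an empty report.
#' @export
summarize_insertions <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    return(structure(list(n_insertions = 0L), class = "ldi_report"))
  novel <- records$wgs_detected == "no"
  complete <- !records$lower_bound
  rep <- list(
    n_insertions = nrow(records),
    per_sample = table(records$sample),
    n_novel = sum(novel),
    n_wgs_detected = sum(!novel),
    median_read_count_novel = stats::median(records$read_count[novel]),
    median_read_count_wgs = stats::median(records$read_count[!novel]),
    n_validated_novel = sum(novel & records$validated == "yes"),
    median_read_count_validated =
      stats::median(records$read_count[novel & records$validated == "yes"]),
    median_read_count_unvalidated =
      stats::median(records$read_count[novel & records$validated == "no"]),
    n_complete = sum(complete),
    tsm_complete = c(
      duplication = sum(complete & records$tsm_type %in% "duplication"),
      deletion = sum(complete & records$tsm_type %in% "deletion"),
      blunt = sum(complete & records$tsm_type %in% "blunt")),
    tsm_incomplete = c(
      duplication = sum(!complete & records$tsm_type %in% "duplication"),
      deletion = sum(!complete & records$tsm_type %in% "deletion")),
    twin_priming_complete = sum(complete & records$twin_priming %in% "present"),
    twin_priming_incomplete = sum(!complete & records$twin_priming %in% "present"),
    insertion_len_min = suppressWarnings(min(records$insertion_bp[complete])),
    insertion_len_max = suppressWarnings(max(records$insertion_bp[complete])),
    insertion_len_mean = mean(records$insertion_bp[complete]))
  if (any(novel) && any(!novel))
    rep$wilcoxon_novel_vs_wgs <- wilcoxon_rank_sum(
      records$read_count[novel], records$read_count[!novel])
  val <- novel & records$validated == "yes"
  unval <- novel & records$validated == "no"
  if (any(val) && any(unval))
    rep$wilcoxon_validated_vs_unvalidated <- wilcoxon_rank_sum(
      records$read_count[val], records$read_count[unval])
  structure(rep, class = "ldi_report")
}

#' @export
print.ldi_report <- function(x, ...) {
  cat("LDI-PCR insertion summary\n")
  cat("  insertions:", x$n_insertions, "\n")
  if (x$n_insertions == 0L) return(invisible(x))
  cat("  per sample:", paste(names(x$per_sample), x$per_sample,
                             sep = "=", collapse = ", "), "\n")
  cat(sprintf("  novel: %d (median read count %g), WGS-detected: %d (median %g)\n",
              x$n_novel, x$median_read_count_novel, x$n_wgs_detected,
              x$median_read_count_wgs))
  cat(sprintf("  validated novel: %d (median %g vs unvalidated %g)\n",
              x$n_validated_novel, x$median_read_count_validated,
              x$median_read_count_unvalidated))
  cat(sprintf("  complete insertions: %d (TSM: %d duplications, %d deletions, %d blunt)\n",
              x$n_complete, x$tsm_complete["duplication"],
              x$tsm_complete["deletion"], x$tsm_complete["blunt"]))
  cat(sprintf("  twin-priming: %d of %d complete (+%d incomplete)\n",
              x$twin_priming_complete, x$n_complete, x$twin_priming_incomplete))
  cat(sprintf("  insertion length: %g-%g bp (mean %.0f)\n",
              x$insertion_len_min, x$insertion_len_max, x$insertion_len_mean))
  if (!is.null(x$wilcoxon_novel_vs_wgs))
    cat(sprintf("  read counts, novel vs WGS-detected: p = %.3g\n",
                x$wilcoxon_novel_vs_wgs$p))
  if (!is.null(x$wilcoxon_validated_vs_unvalidated))
    cat(sprintf("  read counts, validated vs unvalidated novel: p = %.3g\n",
                x$wilcoxon_validated_vs_unvalidated$p))
  invisible(x)
}

#' Write a report as TSV
#'
#' Flattens scalar report entries into a two-column key/value TSV.
#'
#' @param report an `ldi_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  flat <- list()
  for (nm in names(report)) {
    v <- report[[nm]]
    if (inherits(v, "table") || (is.atomic(v) && length(v) > 1L)) {
      for (k in seq_along(v))
        flat[[paste0(nm, ".", names(v)[k] %||% k)]] <- unname(v[k])
    } else if (is.list(v)) {
      flat[[paste0(nm, ".p")]] <- v$p
      flat[[paste0(nm, ".U")]] <- v$U
    } else flat[[nm]] <- v
  }
  utils::write.table(
    data.frame(key = names(flat), value = unlist(flat)), path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
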