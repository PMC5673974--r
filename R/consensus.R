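# Amplicon consensus polishing: orientation normalization, greedy centroid
# clustering at a sequence-identity threshold, random sub-sampling, and
# partial-order-alignment consensus (the read-correction step applied to each
# insertion call's supporting reads).

#' Consensus-polishing parameters
#'
#' @param min_cluster_identity minimum global-alignment identity
#'   (matches / alignment columns) for a read to join a cluster (default 0.60).
#' @param sample_size reads drawn from the largest cluster for the
#'   partial-order alignment (default 20).
#' @param seed RNG seed for the sub-sampling step.
#' @param match,mismatch,gap alignment scores (linear gap).
#' @return An object of class `consensus_params`.
#' @export
consensus_params <- function(min_cluster_identity = 0.60, sample_size = 20L,
                             seed = 1L, match = 2L, mismatch = -1L, gap = -2L) {
  stopifnot(min_cluster_identity > 0, min_cluster_identity <= 1, sample_size >= 1)
  structure(list(min_cluster_identity = min_cluster_identity,
                 sample_size = as.integer(sample_size), seed = as.integer(seed),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap)),
            class = "consensus_params")
}

.subst_matrix <- function(params)
  Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                           mismatch = params$mismatch,
                                           baseOnly = TRUE)

#' Global-alignment identity of two sequences
#'
#' Identity is defined as matches divided by alignment length (columns) of a
#' global alignment under the package's scoring scheme.
#'
#' @param a,b DNA sequences (character).
#' @param params a [consensus_params()].
#' @return A number in `[0, 1]`.
#' @export
alignment_identity <- function(a, b, params = consensus_params()) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .subst_matrix(params),
    gapOpening = 0, gapExtension = -params$gap)
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

#' Cluster reads by greedy centroid clustering
#'
#' Reads are orientation-normalized (each read, or its reverse complement,
#' whichever aligns better to the candidate centroid) and processed
#' longest-first; a read joins the first existing cluster whose centroid (its
#' founding read) it matches at `min_cluster_identity`, otherwise it founds a
#' new cluster. Clusters are returned largest-first.
#'
#' @param reads character vector of read sequences (names kept as read ids).
#' @param params a [consensus_params()].
#' @return A list of clusters; each is a named character vector of
#'   orientation-normalized reads, centroid first.
#' @export
cluster_reads <- function(reads, params = consensus_params()) {
  stopifnot(length(reads) >= 1L)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%d", seq_along(reads))
  reads <- reads[order(-nchar(reads))]
  # orientation screen: shared 13-mers with the centroid, probed every 29 bp;
  # the cheap vote picks which orientation to align (the other is only tried
  # when the first misses the identity threshold)
  kmer_votes <- function(a, b) {
    n <- nchar(a)
    if (n < 13L) return(0L)
    starts <- seq(1L, n - 12L, by = 29L)
    sum(vapply(starts, function(s)
      grepl(substr(a, s, s + 12L), b, fixed = TRUE), logical(1)))
  }
  clusters <- list()
  for (i in seq_along(reads)) {
    r <- reads[i]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      centroid <- clusters[[k]][1]
      if (r == centroid) { # identity 1 by definition
        clusters[[k]] <- c(clusters[[k]], r); placed <- TRUE; break
      }
      rc <- stats::setNames(.revcomp(r), names(r))
      first_fwd <- kmer_votes(r, centroid) >= kmer_votes(rc, centroid)
      ord <- if (first_fwd) list(r, rc) else list(rc, r)
      id1 <- alignment_identity(ord[[1]], centroid, params)
      if (id1 >= params$min_cluster_identity) {
        clusters[[k]] <- c(clusters[[k]], ord[[1]]); placed <- TRUE; break
      }
      id2 <- alignment_identity(ord[[2]], centroid, params)
      if (id2 >= params$min_cluster_identity) {
        clusters[[k]] <- c(clusters[[k]], ord[[2]]); placed <- TRUE; break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- r
  }
  clusters[order(-vapply(clusters, length, integer(1)))]
}

#' Sample reads from a cluster
#'
#' Uniform sampling without replacement, capped at `sample_size`; the whole
#' cluster is returned when it is smaller. Deterministic given `params$seed`.
#'
#' @param cluster a named character vector of reads.
#' @param params a [consensus_params()].
#' @return A named character vector of at most `sample_size` reads.
#' @export
sample_cluster <- function(cluster, params = consensus_params()) {
  if (length(cluster) <= params$sample_size) return(cluster)
  set.seed(params$seed)
  cluster[sort(sample(seq_along(cluster), params$sample_size))]
}

#' Build a partial-order alignment graph
#'
#' The first read seeds a linear chain; each following read is aligned
#' globally to the graph (dynamic programming over a topological order, match
#' / mismatch / linear gap scores from `params`), matched bases fuse into
#' existing nodes and mismatches/indels add nodes and edges, with edge weights
#' counting read traversals. Reads are inserted longest-first (a fixed,
#' documented order) unless `reorder = FALSE`.
#'
#' @param reads character vector of (orientation-normalized) reads.
#' @param params a [consensus_params()].
#' @param reorder insert reads longest-first (default `TRUE`).
#' @return An object of class `poa_graph`: node `bases`, `support`,
#'   `start_count`/`end_count`, an `edges` data.frame (`from`, `to`,
#'   `weight`), per-read alignment `scores` (`NA` for the seed read), and the
#'   precomputed heaviest-path consensus.
#' @export
poa_build <- function(reads, params = consensus_params(), reorder = TRUE) {
  stopifnot(length(reads) >= 1L)
  if (reorder) reads <- reads[order(-nchar(reads))]
  res <- .poa_build_cpp(toupper(reads), params$match, params$mismatch, params$gap)
  structure(list(
    bases = res$bases, support = res$support,
    start_count = res$start_count, end_count = res$end_count,
    edges = data.frame(from = res$edge_from, to = res$edge_to,
                       weight = res$edge_weight),
    scores = res$scores, n_reads = length(reads),
    consensus = res$consensus, consensus_support = res$consensus_support,
    consensus_path = res$consensus_path), class = "poa_graph")
}

#' @export
print.poa_graph <- function(x, ...) {
  cat(sprintf("poa_graph: %d nodes, %d edges, %d reads, consensus %d bp\n",
              length(x$bases), nrow(x$edges), x$n_reads, nchar(x$consensus)))
  invisible(x)
}

#' Extract the consensus sequence from a partial-order alignment graph
#'
#' The consensus is the heaviest start-to-end path (edge traversal counts plus
#' virtual start/end weights; ties broken by higher node support, then
#' lexicographic base), with per-base support depth.
#'
#' @param graph a `poa_graph`.
#' @param call_id identifier attached to the consensus.
#' @return An object of class `consensus_seq`: `call_id`, `sequence`, `depth`
#'   (integer vector, one entry per consensus base) and `n_reads`.
#' @export
poa_consensus <- function(graph, call_id = NA_character_) {
  stopifnot(inherits(graph, "poa_graph"))
  structure(list(call_id = call_id, sequence = graph$consensus,
                 depth = graph$consensus_support, n_reads = graph$n_reads),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("consensus_seq %s: %d bp from %d reads (median depth %g)\n",
              x$call_id, nchar(x$sequence), x$n_reads, stats::median(x$depth)))
  invisible(x)
}

#' Polish an insertion call's supporting reads into a consensus amplicon
#'
#' The full read-correction procedure: orientation-normalized greedy
#' clustering at 60% identity, uniform sampling of up to 20 reads from the
#' largest cluster, partial-order alignment, and heaviest-path consensus.
#' Smaller clusters are reported as secondary (count only), not polished.
#'
#' @param reads named character vector of supporting read sequences.
#' @param params a [consensus_params()].
#' @param call_id identifier attached to the consensus.
#' @return A `consensus_seq` with attribute `"secondary_clusters"`.
#' @export
polish_call <- function(reads, params = consensus_params(),
                        call_id = NA_character_) {
  clusters <- cluster_reads(reads, params)
  use <- sample_cluster(clusters[[1]], params)
  cons <- poa_consensus(poa_build(use, params), call_id)
  attr(cons, "secondary_clusters") <- length(clusters) - 1L
  cons
}

#' Write consensus sequences
#'
#' One FASTA record per consensus (id = call id) plus a depth TSV
#' (`<path>.depth.tsv` with columns `call`, `position`, `depth`).
#'
#' @param consensuses a `consensus_seq` or list of them.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensuses, path) {
  if (inherits(consensuses, "consensus_seq")) consensuses <- list(consensuses)
  seqs <- Biostrings::DNAStringSet(vapply(consensuses, `[[`, "", "sequence"))
  names(seqs) <- vapply(consensuses, function(x) as.character(x$call_id), "")
  Biostrings::writeXStringSet(seqs, path)
  depth <- do.call(rbind, lapply(consensuses, function(x)
    data.frame(call = x$call_id, position = seq_along(x$depth), depth = x$depth)))
  utils::write.table(depth, paste0(path, ".depth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
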