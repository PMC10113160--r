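# Overlap and distance algebra. Overlap means >= 1 shared bp under the
# package's single coordinate convention; a shared boundary point of the
# half-open source formats is therefore never an overlap. Strand is carried
# but ignored everywhere here.

#' Count reciprocal overlap hits between two interval sets
#'
#' @param query,subject `GRanges`.
#' @return A list with `n_query_hit` (queries overlapping at least one
#'   subject) and `n_target_hit` (subjects overlapped by at least one
#'   query); each interval counted at most once regardless of multiplicity.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20, 30))
#' countOverlapPairs(a, b)  # 1 and 1: they share base 20
#' @export
countOverlapPairs <- function(query, subject) {
  shared <- intersect(unique(as.character(seqnames(query))),
                      unique(as.character(seqnames(subject))))
  if (length(shared) == 0)
    return(list(n_query_hit = 0L, n_target_hit = 0L))
  list(n_query_hit = sum(countOverlaps(query, subject, ignore.strand = TRUE) > 0L),
       n_target_hit = sum(countOverlaps(subject, query, ignore.strand = TRUE) > 0L))
}

#' Distance to the nearest target interval
#'
#' Unsigned edge-to-edge gap to the closest target on the same chromosome:
#' 0 for overlapping or book-ended intervals, `Inf` when the chromosome has
#' no target. Upstream and downstream are not distinguished.
#'
#' @param anchor `GRanges` of query intervals.
#' @param targets `GRanges` of targets.
#' @return Numeric vector, parallel to `anchor`.
#' @export
nearestDistance <- function(anchor, targets) {
  out <- rep(Inf, length(anchor))
  if (length(anchor) == 0 || length(targets) == 0) return(out)
  shared <- intersect(unique(as.character(seqnames(anchor))),
                      unique(as.character(seqnames(targets))))
  if (length(shared) == 0) return(out)
  hit <- suppressWarnings(
    distanceToNearest(anchor, targets, ignore.strand = TRUE))
  out[queryHits(hit)] <- mcols(hit)$distance
  out
}
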