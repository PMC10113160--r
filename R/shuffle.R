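# Length-preserving interval shuffling inside a mappable space. This is the
# null model of the family-enrichment permutation test: each peak is
# re-placed uniformly at random among every position on its own chromosome
# where it fits entirely inside a single mappable segment, so shuffled
# peaks never touch the exclusion mask and never straddle a masked gap.

#' Build the mappable placement space
#'
#' The per-chromosome complement of a (merged) exclusion mask; with no mask
#' every chromosome is fully mappable.
#'
#' @param chromSizes Named integer vector of chromosome lengths, or a path
#'   to a chrom.sizes TSV (see [readChromSizes()]).
#' @param mask Optional `GRanges` of excluded (unmappable) regions; must
#'   lie within chromosome bounds.
#' @return A [MappableSpace-class].
#' @examples
#' sz <- c(chr1 = 2000L)
#' m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' mappableRegions(mappableSpace(sz, m))  # chr1:1001-2000
#' @export
mappableSpace <- function(chromSizes, mask = NULL) {
  if (is.character(chromSizes)) chromSizes <- readChromSizes(chromSizes)
  sizes <- setNames(as.integer(chromSizes), names(chromSizes))
  whole <- GRanges(names(sizes), IRanges(1L, unname(sizes)))
  if (is.null(mask) || length(mask) == 0) {
    regions <- whole
  } else {
    chr <- as.character(seqnames(mask))
    if (!all(chr %in% names(sizes)))
      stop("mask interval on unknown chromosome: ",
           paste(unique(chr[!chr %in% names(sizes)]), collapse = ", "))
    if (any(start(mask) < 1) || any(end(mask) > sizes[chr]))
      stop("mask interval beyond chromosome end")
    regions <- setdiff(whole, reduce(granges(mask)), ignore.strand = TRUE)
  }
  new("MappableSpace", chromSizes = sizes, regions = granges(regions))
}

# Precompute per-chromosome segment tables and, per interval, the number of
# valid start positions, so repeated draws (permutations) only cost the
# random sampling itself. Errors name the first interval that fits nowhere.
.shufflePlan <- function(intervals, space) {
  stopifnot(is(intervals, "GRanges"), is(space, "MappableSpace"))
  reg <- mappableRegions(space)
  chrAll <- as.character(seqnames(intervals))
  ids <- names(intervals)
  if (is.null(ids)) ids <- as.character(seq_along(intervals))
  plan <- list(n = length(intervals), groups = list())
  for (chr in unique(chrAll)) {
    i <- which(chrAll == chr)
    segs <- reg[as.character(seqnames(reg)) == chr]
    if (length(segs) == 0)
      stop("no mappable segment on chromosome ", chr,
           " for interval ", ids[i[1]])
    segStart <- start(segs)
    segWidth <- width(segs)
    L <- width(intervals)[i]
    # valid starts per segment x interval
    M <- pmax(outer(segWidth, L, function(w, l) w - l + 1L), 0L)
    cs <- M
    if (nrow(cs) > 1)
      for (r in 2:nrow(cs)) cs[r, ] <- cs[r - 1L, ] + M[r, ]
    tot <- cs[nrow(cs), ]
    if (any(tot == 0))
      stop("interval ", ids[i[which(tot == 0)[1]]], " (", L[which(tot == 0)[1]],
           " bp) is longer than every mappable segment on ", chr)
    plan$groups[[chr]] <- list(idx = i, len = L, segStart = segStart,
                               cum = cs, tot = tot)
  }
  plan
}

# One draw from a shuffle plan (consumes the current RNG stream).
.shuffleDraw <- function(plan) {
  starts <- integer(plan$n)
  chroms <- character(plan$n)
  for (chr in names(plan$groups)) {
    g <- plan$groups[[chr]]
    n <- length(g$idx)
    u <- floor(runif(n) * g$tot)  # 0-based rank among valid starts
    u <- pmin(u, g$tot - 1)       # guard runif() == 1 edge
    nseg <- nrow(g$cum)
    seg <- rep(1L, n)
    if (nseg > 1) {
      below <- g$cum <= matrix(u, nrow = nseg, ncol = n, byrow = TRUE)
      seg <- 1L + colSums(below)
    }
    before <- rep(0, n)
    gt1 <- which(seg > 1L)
    if (length(gt1))
      before[gt1] <- g$cum[cbind(seg[gt1] - 1L, gt1)]
    starts[g$idx] <- g$segStart[seg] + as.integer(u - before)
    chroms[g$idx] <- chr
  }
  GRanges(chroms, IRanges(starts, width = .planWidths(plan)))
}

.planWidths <- function(plan) {
  w <- integer(plan$n)
  for (g in plan$groups) w[g$idx] <- g$len
  w
}

#' Shuffle intervals within the mappable space
#'
#' Produces one interval per input, with identical length, on the same
#' chromosome, placed uniformly at random among all positions where it fits
#' entirely inside a single mappable segment. Deterministic for a fixed
#' seed.
#'
#' @param intervals `GRanges` to shuffle.
#' @param space A [MappableSpace-class].
#' @param seed Integer seed.
#' @return A `GRanges` parallel to `intervals` (names preserved).
#' @export
shuffleIntervals <- function(intervals, space, seed) {
  plan <- .shufflePlan(intervals, space)
  out <- .withSeed(seed, .shuffleDraw(plan))
  names(out) <- names(intervals)
  out
}
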