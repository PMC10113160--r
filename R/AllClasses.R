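#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths Seqinfo
#'   seqlevelsInUse keepSeqlevels
NULL

# ---------------------------------------------------------------------------
# TEAnnotation: transposable-element copies grouped into families
# ---------------------------------------------------------------------------

#' TEAnnotation: transposable-element copies grouped into families
#'
#' A `TEAnnotation` is a [GenomicRanges::GRanges] whose elements are
#' individual TE copies, each assigned to a repeat family through the
#' mandatory `family` metadata column (an optional `class_label` column
#' carries the repeat class, e.g. `LTR/ERV1`). Element identifiers are kept
#' in `names()`. The family is the unit of all enrichment testing.
#'
#' @slot elementMetadata carries at least the `family` column.
#' @export
setClass("TEAnnotation", contains = "GRanges")

setValidity("TEAnnotation", function(object) {
  fam <- mcols(object)$family
  if (is.null(fam))
    return("metadata column 'family' is required")
  if (!is.character(fam))
    return("'family' must be character")
  if (length(object) > 0 && any(is.na(fam) | fam == ""))
    return("every element needs a non-empty family name")
  if (length(object) > 0 && is.null(names(object)))
    return("elements must carry identifiers in names()")
  if (anyDuplicated(names(object)))
    return("element identifiers must be unique")
  TRUE
})

#' Construct a TEAnnotation
#'
#' @param ranges A `GRanges` of TE copies.
#' @param family Character vector of family names, parallel to `ranges`.
#'   If missing, taken from `mcols(ranges)$family`.
#' @param classLabel Optional character vector of repeat class labels.
#' @param elementIds Optional unique element identifiers; autogenerated
#'   (`te_00001`, ...) when absent.
#' @return A [TEAnnotation-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 501), width = 100))
#' TEAnnotation(gr, family = c("LTR10A", "MER41B"))
#' @export
TEAnnotation <- function(ranges, family = NULL, classLabel = NULL,
                         elementIds = NULL) {
  stopifnot(is(ranges, "GRanges"))
  gr <- granges(ranges)
  if (is.null(family)) family <- mcols(ranges)$family
  if (is.null(family)) stop("'family' is required")
  family <- as.character(family)
  if (length(family) != length(gr))
    stop("'family' must be parallel to 'ranges'")
  mcols(gr)$family <- family
  if (!is.null(classLabel)) mcols(gr)$class_label <- as.character(classLabel)
  if (is.null(elementIds)) elementIds <- names(ranges)
  if (is.null(elementIds) && length(gr) > 0)
    elementIds <- sprintf("te_%05d", seq_along(gr))
  names(gr) <- elementIds
  new("TEAnnotation", gr)
}

#' @describeIn TEAnnotation Family name of each element.
#' @param x A `TEAnnotation`.
#' @export
teFamily <- function(x) {
  stopifnot(is(x, "TEAnnotation"))
  mcols(x)$family
}

#' @describeIn TEAnnotation Sorted unique family names.
#' @export
familyNames <- function(x) sort(unique(teFamily(x)))

#' @describeIn TEAnnotation Named vector of per-family copy numbers.
#' @export
familyCounts <- function(x) {
  fam <- teFamily(x)
  cnt <- table(fam)
  setNames(as.integer(cnt), names(cnt))[familyNames(x)]
}

#' @describeIn TEAnnotation Subset to the copies of one or more families.
#' @param families Character vector of family names.
#' @export
familyElements <- function(x, families) {
  stopifnot(is(x, "TEAnnotation"))
  x[teFamily(x) %in% families]
}

setMethod("show", "TEAnnotation", function(object) {
  cat(sprintf("TEAnnotation with %d elements in %d families\n",
              length(object), length(unique(teFamily(object)))))
  callNextMethod()
})

# ---------------------------------------------------------------------------
# MappableSpace: where shuffled intervals may be placed
# ---------------------------------------------------------------------------

#' MappableSpace: placement space for interval shuffling
#'
#' Chromosome lengths plus the per-chromosome regions where shuffled
#' intervals may be placed (the complement of an exclusion mask of
#' unmappable sequence). Regions are stored merged, sorted and
#' non-overlapping; construct with [mappableSpace()].
#'
#' @slot chromSizes Named integer vector of chromosome lengths (bp).
#' @slot regions `GRanges` of allowed placement regions.
#' @export
setClass("MappableSpace",
         representation(chromSizes = "integer", regions = "GRanges"))

setValidity("MappableSpace", function(object) {
  sz <- object@chromSizes
  if (is.null(names(sz)) || any(names(sz) == ""))
    return("chromSizes must be named")
  if (any(sz <= 0)) return("chromosome lengths must be positive")
  reg <- object@regions
  if (length(reg) > 0) {
    chr <- as.character(seqnames(reg))
    if (!all(chr %in% names(sz)))
      return("mappable region on unknown chromosome")
    if (any(start(reg) < 1) || any(end(reg) > sz[chr]))
      return("mappable region outside chromosome bounds")
    if (!identical(granges(reg), reduce(granges(reg))))
      return("regions must be merged and sorted")
  }
  if (sum(as.numeric(width(reg))) <= 0)
    return("total mappable length must be positive")
  TRUE
})

#' @describeIn MappableSpace Named chromosome lengths.
#' @param x A `MappableSpace`.
#' @export
chromSizes <- function(x) {
  stopifnot(is(x, "MappableSpace"))
  x@chromSizes
}

#' @describeIn MappableSpace Allowed placement regions as `GRanges`.
#' @export
mappableRegions <- function(x) {
  stopifnot(is(x, "MappableSpace"))
  x@regions
}

#' @describeIn MappableSpace Total mappable length in bp.
#' @export
mappableLength <- function(x) sum(as.numeric(width(mappableRegions(x))))

setMethod("show", "MappableSpace", function(object) {
  tot <- sum(as.numeric(object@chromSizes))
  map <- mappableLength(object)
  cat(sprintf("MappableSpace: %d chromosomes, %.0f bp total, %.0f bp (%.1f%%) mappable\n",
              length(object@chromSizes), tot, map, 100 * map / tot))
})

# ---------------------------------------------------------------------------
# GeneModels: gene spans, TSS and transcript structure
# ---------------------------------------------------------------------------

#' GeneModels: gene spans with strand-aware TSS and transcripts
#'
#' Holds gene-level spans (with a 1-based, strand-aware transcription start
#' position: `start` for `+` genes, `end` for `-` genes) and their
#' transcripts with exon counts. Multi-exonic transcripts
#' (`exon_count >= 2`) are the unit of TE-promoter detection.
#'
#' @slot genes `GRanges` with metadata columns `gene_id` and `tss`.
#' @slot transcripts `GRanges` with metadata columns `transcript_id`,
#'   `gene_id`, `tss` and `exon_count`.
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", transcripts = "GRanges"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  tx <- object@transcripts
  need <- function(gr, cols, what) {
    miss <- setdiff(cols, colnames(mcols(gr)))
    if (length(miss))
      sprintf("%s lack metadata column(s): %s", what, paste(miss, collapse = ", "))
    else TRUE
  }
  ok <- need(g, c("gene_id", "tss"), "genes")
  if (!isTRUE(ok)) return(ok)
  ok <- need(tx, c("transcript_id", "gene_id", "tss", "exon_count"), "transcripts")
  if (!isTRUE(ok)) return(ok)
  if (anyDuplicated(mcols(g)$gene_id)) return("duplicate gene_id")
  if (anyDuplicated(mcols(tx)$transcript_id)) return("duplicate transcript_id")
  if (length(g) > 0) {
    tss <- mcols(g)$tss
    if (any(tss < start(g) | tss > end(g)))
      return("gene TSS must lie within the gene span")
  }
  if (length(tx) > 0 && any(mcols(tx)$exon_count < 0))
    return("exon_count must be >= 0")
  TRUE
})

#' Construct a GeneModels object
#'
#' @param genes `GRanges` with `gene_id` metadata (and optionally `tss`;
#'   computed strand-aware when absent).
#' @param transcripts `GRanges` with `transcript_id`, `gene_id`,
#'   `exon_count` metadata (and optionally `tss`).
#' @return A [GeneModels-class] object.
#' @export
GeneModels <- function(genes, transcripts) {
  addTss <- function(gr) {
    if (is.null(mcols(gr)$tss)) {
      neg <- as.logical(strand(gr) == "-")
      mcols(gr)$tss <- ifelse(neg, end(gr), start(gr))
    }
    gr
  }
  new("GeneModels", genes = addTss(genes), transcripts = addTss(transcripts))
}

#' @describeIn GeneModels Gene spans as `GRanges`.
#' @param x A `GeneModels`.
#' @export
geneRanges <- function(x) {
  stopifnot(is(x, "GeneModels"))
  x@genes
}

#' @describeIn GeneModels Transcripts as `GRanges`.
#' @export
transcriptRanges <- function(x) {
  stopifnot(is(x, "GeneModels"))
  x@transcripts
}

#' @describeIn GeneModels TSS positions as width-1 `GRanges`, one per gene.
#' @export
geneTss <- function(x) {
  g <- geneRanges(x)
  GRanges(seqnames(g), IRanges(mcols(g)$tss, width = 1L), strand = strand(g),
          gene_id = mcols(g)$gene_id)
}

setMethod("show", "GeneModels", function(object) {
  multi <- sum(mcols(object@transcripts)$exon_count >= 2)
  cat(sprintf("GeneModels: %d genes, %d transcripts (%d multi-exonic)\n",
              length(object@genes), length(object@transcripts), multi))
})

# ---------------------------------------------------------------------------
# CoordinateMap: aligned block pairs between two genomes
# ---------------------------------------------------------------------------

#' CoordinateMap: aligned block pairs between two genome assemblies
#'
#' A directed collection of gap-free aligned blocks: interval `i` of the
#' source genome corresponds base-for-base to interval `i` of the target
#' genome (possibly on the `-` strand, in which case positions map in
#' reverse). Blocks must not overlap on either side. This abstracts the
#' alignment-chain input of coordinate lift-over tools into a plain block
#' list; see [readCoordinateMap()] for the TSV dialect.
#'
#' @slot src Source-genome `GRanges` (strand ignored).
#' @slot dst Target-genome `GRanges`; strand `-` means reverse orientation.
#' @export
setClass("CoordinateMap", representation(src = "GRanges", dst = "GRanges"))

setValidity("CoordinateMap", function(object) {
  if (length(object@src) != length(object@dst))
    return("src and dst must have the same number of blocks")
  if (!all(width(object@src) == width(object@dst)))
    return("paired blocks must have identical lengths")
  selfOverlap <- function(gr)
    length(gr) > 1 && any(countOverlaps(gr, gr, ignore.strand = TRUE) > 1)
  if (selfOverlap(object@src)) return("source blocks overlap")
  if (selfOverlap(object@dst)) return("target blocks overlap")
  TRUE
})

#' Construct a CoordinateMap
#'
#' @param src,dst Parallel `GRanges` of equal-width aligned blocks.
#' @return A [CoordinateMap-class] object.
#' @export
CoordinateMap <- function(src, dst) new("CoordinateMap", src = src, dst = dst)

#' @describeIn CoordinateMap Source-side blocks.
#' @param x A `CoordinateMap`.
#' @export
mapSource <- function(x) {
  stopifnot(is(x, "CoordinateMap"))
  x@src
}

#' @describeIn CoordinateMap Target-side blocks.
#' @export
mapTarget <- function(x) {
  stopifnot(is(x, "CoordinateMap"))
  x@dst
}

setMethod("show", "CoordinateMap", function(object) {
  cat(sprintf("CoordinateMap: %d blocks, %.0f aligned bp\n",
              length(object@src), sum(as.numeric(width(object@src)))))
})
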