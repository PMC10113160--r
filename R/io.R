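# Readers and writers for the standard plain-text formats. All coordinates
# are converted at this boundary to the 1-based closed GRanges convention
# used throughout the package: BED records [start, end) become
# start+1 .. end; RepeatMasker and GTF records (1-based inclusive) are taken
# verbatim.

#' Read a chromosome-sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome name in ", path)
  if (any(tab$length <= 0)) stop("non-positive chromosome length in ", path)
  setNames(tab$length, tab$chrom)
}

#' Write a chromosome-sizes table
#'
#' @param sizes Named integer vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeChromSizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), unname(sizes)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file into a GRanges
#'
#' Parses BED records (0-based half-open) into 1-based closed `GRanges`.
#' `track`/`browser` and `#` comment lines are skipped. Column 4, when
#' present, becomes `names()`; column 6 the strand. Malformed records
#' (fewer than three fields, non-integer coordinates, `start >= end`)
#' raise an error naming the offending line.
#'
#' @param path File path.
#' @return A `GRanges`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tpk1", f)
#' readBed(f)  # chr1:11-20, named pk1
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", idx[which(nf < 3)[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  e0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(s0) | is.na(e0)
  if (any(bad))
    stop("BED line ", idx[which(bad)[1]], ": non-integer coordinates")
  bad <- s0 < 0 | s0 >= e0
  if (any(bad))
    stop("BED line ", idx[which(bad)[1]], ": requires 0 <= start < end")
  nm <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  str <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], "*"), "*")
  str[!str %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0), strand = str)
  if (any(nf >= 4)) names(gr) <- nm
  gr
}

#' Write a GRanges as BED
#'
#' Inverse of [readBed()]: emits 0-based half-open coordinates, `names()`
#' as column 4 (with score 0 and strand when names are present), so a
#' write-then-read round trip reproduces coordinates exactly.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(names(gr))) {
    df$name <- names(gr)
    df$score <- 0L
    df$strand <- as.character(strand(gr))
    df$strand[df$strand == "*"] <- "."
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a family-annotated BED file as a TEAnnotation
#'
#' Fallback TE-annotation dialect: BED with the repeat family name in
#' column 4 and, optionally, the repeat class in column 5.
#'
#' @param path File path.
#' @return A [TEAnnotation-class].
#' @export
readTeBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0)
    return(TEAnnotation(GRanges(), family = character(0)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("TE BED line ", idx[which(nf < 4)[1]], ": needs >= 4 fields (family in column 4)")
  gr <- readBed(path)
  fam <- unname(names(gr))
  names(gr) <- NULL
  cls <- if (all(nf >= 5)) vapply(fields, `[`, "", 5L) else NULL
  if (!is.null(cls) && all(grepl("^[0-9.]*$", cls))) cls <- NULL  # score column
  TEAnnotation(gr, family = fam, classLabel = cls)
}

#' Write a TEAnnotation in the BED-dialect (family in column 4)
#'
#' @param x A [TEAnnotation-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeTeBed <- function(x, path) {
  stopifnot(is(x, "TEAnnotation"))
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L, end = end(x),
                   family = teFamily(x))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker .out annotation
#'
#' Parses the standard RepeatMasker output layout: three header lines
#' followed by whitespace-separated rows with 1-based inclusive query
#' coordinates in columns 6-7, strand (`+` or `C` for the reverse
#' complement) in column 9, repeat (family) name in column 10 and repeat
#' class/family in column 11.
#'
#' @param path File path.
#' @return A [TEAnnotation-class]; element ids are `te_<row>` in file order.
#' @export
readRepeatMaskerOut <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) > 0 && grepl("^\\s*SW|^\\s*score", lines[1]))
    lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(TEAnnotation(GRanges(), family = character(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("RepeatMasker row ", which(nf < 11)[1], ": fewer than 11 columns")
  chrom <- vapply(fields, `[`, "", 5L)
  beg <- suppressWarnings(as.integer(vapply(fields, `[`, "", 6L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 7L)))
  bad <- is.na(beg) | is.na(end) | beg < 1 | end < beg
  if (any(bad))
    stop("RepeatMasker row ", which(bad)[1], ": unparsable coordinates")
  str <- vapply(fields, `[`, "", 9L)
  str <- ifelse(str == "C", "-", ifelse(str == "+", "+", "*"))
  fam <- vapply(fields, `[`, "", 10L)
  cls <- vapply(fields, `[`, "", 11L)
  gr <- GRanges(chrom, IRanges(beg, end), strand = str)
  TEAnnotation(gr, family = fam, classLabel = cls,
               elementIds = sprintf("te_%05d", seq_along(gr)))
}

#' Read gene models from a GTF file
#'
#' Imports `gene`, `transcript` and `exon` features (1-based inclusive,
#' parsed by [rtracklayer::import()]) into a [GeneModels-class]. The TSS
#' is strand-aware (`start` for `+`, `end` for `-`); `exon_count` is the
#' number of exon records per transcript. Transcripts without exon records
#' get `exon_count = 0` with a warning, which excludes them from
#' multi-exonic queries. Files without explicit `gene` rows derive gene
#' spans as the range of each gene's transcripts.
#'
#' @param path File path.
#' @return A [GeneModels-class].
#' @export
readGtfGenes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gtf <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gtf$type)

  tx <- gtf[type == "transcript"]
  ex <- gtf[type == "exon"]
  exCount <- table(as.character(ex$transcript_id))
  txIds <- as.character(tx$transcript_id)
  nExon <- as.integer(exCount[txIds])
  nExon[is.na(nExon)] <- 0L
  if (any(nExon == 0L) && length(tx) > 0)
    warning(sum(nExon == 0L), " transcript(s) without exon records (exon_count = 0)")
  txGr <- granges(tx)
  mcols(txGr) <- DataFrame(transcript_id = txIds,
                           gene_id = as.character(tx$gene_id),
                           exon_count = nExon)

  gene <- gtf[type == "gene"]
  if (length(gene) > 0) {
    gGr <- granges(gene)
    mcols(gGr) <- DataFrame(gene_id = as.character(gene$gene_id))
  } else {
    sp <- split(txGr, mcols(txGr)$gene_id)
    gGr <- unlist(range(sp, ignore.strand = FALSE), use.names = FALSE)
    mcols(gGr) <- DataFrame(gene_id = names(sp))
  }
  GeneModels(genes = gGr, transcripts = txGr)
}

#' Read a block-pair coordinate map
#'
#' TSV with columns `src_chrom, src_start, src_end, dst_chrom, dst_start,
#' dst_end, dst_strand` (0-based half-open, the BED convention); a header
#' row is detected and skipped. Paired blocks must be the same length.
#'
#' @param path File path.
#' @return A [CoordinateMap-class].
#' @export
readCoordinateMap <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && grepl("src_chrom", first)) 1L else 0L
  tab <- read.table(path, sep = "\t", header = FALSE, skip = skip,
                    col.names = c("src_chrom", "src_start", "src_end",
                                  "dst_chrom", "dst_start", "dst_end",
                                  "dst_strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "integer",
                                   "character"))
  src <- GRanges(tab$src_chrom, IRanges(tab$src_start + 1L, tab$src_end))
  dst <- GRanges(tab$dst_chrom, IRanges(tab$dst_start + 1L, tab$dst_end),
                 strand = tab$dst_strand)
  CoordinateMap(src, dst)
}

#' Write a coordinate map in the block-pair TSV dialect
#'
#' @param map A [CoordinateMap-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeCoordinateMap <- function(map, path) {
  src <- mapSource(map); dst <- mapTarget(map)
  df <- data.frame(src_chrom = as.character(seqnames(src)),
                   src_start = start(src) - 1L, src_end = end(src),
                   dst_chrom = as.character(seqnames(dst)),
                   dst_start = start(dst) - 1L, dst_end = end(dst),
                   dst_strand = ifelse(as.character(strand(dst)) == "-", "-", "+"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
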