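# Independent brute-force oracles and fixture builders. The oracles work on
# plain data frames of 0-based half-open intervals and never touch the
# package's interval machinery, so implementation and check stay on
# separate routes.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# random 0-based half-open interval table
randIntervals <- function(n, chroms = c("chrA", "chrB"), chromLen = 1e6,
                          maxLen = 5000) {
  len <- sample(maxLen, n, replace = TRUE)
  start <- as.integer(floor(runif(n) * (chromLen - len)))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

asGr <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

# O(n*m) all-pairs overlap oracle on half-open intervals (one explicit
# loop over queries; each query is compared against every target)
bruteOverlapPairs <- function(q, s) {
  qHit <- rep(FALSE, nrow(q)); sHit <- rep(FALSE, nrow(s))
  for (i in seq_len(nrow(q))) {
    ov <- q$chrom[i] == s$chrom & q$start[i] < s$end & s$start < q$end[i]
    qHit[i] <- any(ov)
    sHit <- sHit | ov
  }
  list(n_query_hit = sum(qHit), n_target_hit = sum(sHit))
}

# exhaustive nearest-gap oracle; half-open gap between [a1,a2) and [b1,b2)
bruteNearest <- function(aRow, s) {
  best <- Inf
  for (j in seq_len(nrow(s))) {
    if (s$chrom[j] != aRow$chrom) next
    if (aRow$start < s$end[j] && s$start[j] < aRow$end) gap <- 0
    else if (s$start[j] >= aRow$end) gap <- s$start[j] - aRow$end
    else gap <- aRow$start - s$end[j]
    best <- min(best, gap)
  }
  best
}

# per-base lift oracle: maps every base of a 0-based half-open interval
# through a block table (0-based half-open src/dst, dst_strand +/-), then
# applies the merged-region / min_frac acceptance rule by hand
bruteLift <- function(chrom, start0, end0, blocks, minFrac) {
  pos <- seq.int(start0, end0 - 1L)
  mchr <- rep(NA_character_, length(pos))
  mpos <- rep(NA_integer_, length(pos))
  for (b in seq_len(nrow(blocks))) {
    if (blocks$src_chrom[b] != chrom) next
    inb <- pos >= blocks$src_start[b] & pos < blocks$src_end[b]
    off <- pos[inb] - blocks$src_start[b]
    if (blocks$dst_strand[b] == "-") {
      mpos[inb] <- blocks$dst_end[b] - 1L - off
    } else {
      mpos[inb] <- blocks$dst_start[b] + off
    }
    mchr[inb] <- blocks$dst_chrom[b]
  }
  ok <- !is.na(mpos)
  if (!any(ok)) return(NULL)
  # merge mapped bases into maximal runs of consecutive target positions
  df <- data.frame(chr = mchr[ok], pos = mpos[ok])
  df <- df[order(df$chr, df$pos), ]
  runId <- cumsum(c(1, diff(df$pos) != 1 |
                      df$chr[-1] != df$chr[-nrow(df)]))
  sizes <- tapply(df$pos, runId, length)
  # regions that touch or overlap merge further (reduce() semantics):
  # consecutive runs are already maximal, so runs are the merged regions
  best <- which.max(sizes)
  nb <- max(sizes)
  if (nb < minFrac * (end0 - start0)) return(NULL)
  keep <- runId == as.integer(names(sizes)[best])
  list(chrom = df$chr[keep][1],
       start0 = min(df$pos[keep]), end0 = max(df$pos[keep]) + 1L,
       bases = nb)
}

# independent Benjamini-Hochberg step-up
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# small in-code GTF writer
writeGtfFixture <- function(path, rows) {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', r$gene, r$tx)
    if (r$type == "gene") attrs <- sprintf('gene_id "%s";', r$gene)
    paste(r$chrom, "src", r$type, r$start, r$end, ".", r$strand, ".",
          attrs, sep = "\t")
  }, "")
  writeLines(lines, path)
}

# tiny deterministic simulation config used across tests
smallConfig <- function(seed = 7, planted = c(F01 = 0.4), nPeaks = 300L,
                        nFam = 10L, copies = 30L, chromLen = 5e6,
                        maskFraction = 0.1) {
  simulationConfig(
    seed = seed,
    chromosomes = data.frame(name = c("chr1", "chr2"),
                             length = c(chromLen, chromLen)),
    families = data.frame(name = sprintf("F%02d", seq_len(nFam)),
                          copy_number = copies,
                          length_mean = 800, length_sd = 150),
    maskFraction = maskFraction,
    peaks = list(count = nPeaks, length_mean = 300, length_sd = 50,
                 planted = planted))
}
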