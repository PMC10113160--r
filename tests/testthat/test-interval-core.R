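# Interval model, format readers and overlap/distance algebra.

test_that("BED records parse with half-open coordinates and skip headers", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=peaks", "# comment",
               "chr1\t10\t20\tpk1", "chr2\t0\t5\tpk2\t0\t-"), f)
  gr <- readBed(f)
  expect_length(gr, 2)
  expect_equal(start(gr), c(11L, 1L))
  expect_equal(end(gr), c(20L, 5L))
  expect_equal(names(gr), c("pk1", "pk2"))
  expect_equal(as.character(strand(gr)), c("*", "-"))
})

test_that("empty and malformed BED files behave per contract", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f)
  expect_length(readBed(f), 0)
  writeLines("chr1\t20\t10", f)
  expect_error(readBed(f), "line 1")
  writeLines(c("chr1\t10\t20", "chr1\tx\t30"), f)
  expect_error(readBed(f), "line 2")
  writeLines("chr1\t15", f)
  expect_error(readBed(f), "fewer than 3")
})

test_that("BED round trip is coordinate-exact", {
  withr::local_seed(11)
  df <- randIntervals(80)
  gr <- asGr(df)
  names(gr) <- sprintf("iv%02d", seq_along(gr))
  f <- withr::local_tempfile(fileext = ".bed")
  writeBed(gr, f)
  back <- readBed(f)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(names(back), names(gr))
})

test_that("RepeatMasker .out parses coordinates, strand and families", {
  f <- withr::local_tempfile(fileext = ".out")
  hdr <- c("   SW  perc perc perc  query     position in query", "", "")
  row <- function(chr, b, e, str, fam, cls)
    sprintf("  463  1.3  0.6  1.7  %s  %d  %d  (100)  %s  %s  %s  1  100  (0)  1",
            chr, b, e, str, fam, cls)
  fams <- c(rep("LTR10A", 5), rep("MER41B", 4), rep("LTR8B", 3))
  rows <- vapply(seq_along(fams), function(i)
    row("chr1", 100 * i + 1, 100 * i + 100,
        if (i %% 2 == 0) "C" else "+", fams[i], "LTR/ERV"), "")
  writeLines(c(hdr, rows), f)
  ann <- readRepeatMaskerOut(f)
  expect_s4_class(ann, "TEAnnotation")
  expect_equal(familyNames(ann), c("LTR10A", "LTR8B", "MER41B"))
  expect_equal(unname(familyCounts(ann)), c(5L, 3L, 4L))
  # 1-based inclusive taken verbatim: begin=101 end=200
  expect_equal(start(ann)[1], 101L)
  expect_equal(end(ann)[1], 200L)
  expect_equal(as.character(strand(ann))[2], "-")  # C maps to minus

  writeLines(hdr, f)  # header only
  expect_length(readRepeatMaskerOut(f), 0)
})

test_that("GTF gene models carry strand-aware TSS and exon counts", {
  f <- withr::local_tempfile(fileext = ".gtf")
  rows <- rbind(
    data.frame(chrom = "chr1", type = "gene", start = 1001, end = 2000,
               strand = "+", gene = "g1", tx = ""),
    data.frame(chrom = "chr1", type = "transcript", start = 1001, end = 2000,
               strand = "+", gene = "g1", tx = "t1"),
    data.frame(chrom = "chr1", type = "exon", start = 1001, end = 1100,
               strand = "+", gene = "g1", tx = "t1"),
    data.frame(chrom = "chr1", type = "exon", start = 1301, end = 1400,
               strand = "+", gene = "g1", tx = "t1"),
    data.frame(chrom = "chr1", type = "exon", start = 1801, end = 2000,
               strand = "+", gene = "g1", tx = "t1"),
    data.frame(chrom = "chr2", type = "gene", start = 1001, end = 2000,
               strand = "-", gene = "g2", tx = ""),
    data.frame(chrom = "chr2", type = "transcript", start = 1001, end = 2000,
               strand = "-", gene = "g2", tx = "t2"),
    data.frame(chrom = "chr2", type = "exon", start = 1001, end = 2000,
               strand = "-", gene = "g2", tx = "t2"))
  writeGtfFixture(f, rows)
  gm <- readGtfGenes(f)
  g <- geneRanges(gm)
  expect_equal(start(g), c(1001L, 1001L))
  # strand-aware TSS: start for +, end for -
  expect_equal(mcols(g)$tss[mcols(g)$gene_id == "g1"], 1001)
  expect_equal(mcols(g)$tss[mcols(g)$gene_id == "g2"], 2000)
  expect_equal(sort(mcols(transcriptRanges(gm))$exon_count), c(1L, 3L))
})

test_that("transcripts without exons warn and are excluded from multi-exonic sets", {
  f <- withr::local_tempfile(fileext = ".gtf")
  rows <- rbind(
    data.frame(chrom = "chr1", type = "transcript", start = 101, end = 200,
               strand = "+", gene = "g1", tx = "t1"))
  writeGtfFixture(f, rows)
  expect_warning(gm <- readGtfGenes(f), "without exon")
  expect_equal(mcols(transcriptRanges(gm))$exon_count, 0L)
  hits <- tePromoterTranscripts(gm, GRanges("chr1", IRanges(101, 200)))
  expect_equal(nrow(hits), 0)
})

test_that("overlap counting respects half-open boundary semantics", {
  pk <- asGr(data.frame(chrom = "chrA", start = 10, end = 20))
  expect_equal(countOverlapPairs(pk, asGr(data.frame(chrom = "chrA", start = 19, end = 30))),
               list(n_query_hit = 1L, n_target_hit = 1L))
  expect_equal(countOverlapPairs(pk, asGr(data.frame(chrom = "chrA", start = 20, end = 30))),
               list(n_query_hit = 0L, n_target_hit = 0L))
  expect_equal(countOverlapPairs(GRanges(), pk),
               list(n_query_hit = 0L, n_target_hit = 0L))
  # shifting the target one base past the boundary toggles overlap once
  hits <- vapply(18:21, function(s) {
    countOverlapPairs(pk, asGr(data.frame(chrom = "chrA", start = s, end = s + 10)))$n_query_hit
  }, 0L)
  expect_equal(hits, c(1L, 1L, 0L, 0L))
})

test_that("overlap counts match the all-pairs oracle on random instances", {
  withr::local_seed(42)
  for (i in 1:50) {
    q <- randIntervals(sample(60, 1))
    s <- randIntervals(sample(80, 1))
    expect_equal(countOverlapPairs(asGr(q), asGr(s)), bruteOverlapPairs(q, s))
  }
  # one larger instance
  q <- randIntervals(500)
  s <- randIntervals(800)
  expect_equal(countOverlapPairs(asGr(q), asGr(s)), bruteOverlapPairs(q, s))
})

test_that("nearest distance is the unsigned edge gap", {
  a <- asGr(data.frame(chrom = "chrA", start = 100, end = 200))
  t1 <- asGr(data.frame(chrom = "chrA", start = 250, end = 300))
  expect_equal(nearestDistance(a, t1), 50)
  expect_equal(nearestDistance(t1, a), 50)  # symmetric
  expect_equal(nearestDistance(a, asGr(data.frame(chrom = "chrA", start = 150, end = 260))), 0)
  expect_equal(nearestDistance(a, asGr(data.frame(chrom = "chrZ", start = 1, end = 10))), Inf)
})

test_that("nearest distance matches the exhaustive oracle", {
  withr::local_seed(99)
  targets <- randIntervals(500)
  anchors <- randIntervals(40)
  got <- nearestDistance(asGr(anchors), asGr(targets))
  want <- vapply(seq_len(nrow(anchors)), function(i)
    bruteNearest(anchors[i, ], targets), numeric(1))
  expect_equal(got, want)
})

test_that("TEAnnotation enforces family labels and unique ids", {
  gr <- GRanges("chr1", IRanges(c(1, 100), width = 50))
  expect_error(TEAnnotation(gr), "family")
  ann <- TEAnnotation(gr, family = c("A", "B"))
  expect_equal(teFamily(ann), c("A", "B"))
  expect_error(TEAnnotation(gr, family = c("A", "")), "non-empty")
  expect_error(TEAnnotation(gr, family = c("A", "B"),
                            elementIds = c("x", "x")), "unique")
})
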