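# Coordinate lifting, reciprocal orthology and cross-species
# expression stratification.

# identity map over two chromosomes
identityMap <- function(sizes = c(chr1 = 1e6, chr2 = 1e6)) {
  gr <- GRanges(names(sizes), IRanges(1, unname(sizes)))
  CoordinateMap(gr, gr)
}

blockDf <- function(map) {
  src <- mapSource(map); dst <- mapTarget(map)
  data.frame(src_chrom = as.character(seqnames(src)),
             src_start = start(src) - 1L, src_end = end(src),
             dst_chrom = as.character(seqnames(dst)),
             dst_start = start(dst) - 1L, dst_end = end(dst),
             dst_strand = ifelse(as.character(strand(dst)) == "-", "-", "+"),
             stringsAsFactors = FALSE)
}

test_that("identity maps return the interval itself at any threshold", {
  iv <- GRanges("chr1", IRanges(1234, 5678))
  for (mf in c(0.1, 0.5, 1)) {
    out <- liftInterval(iv, identityMap(), minFrac = mf)
    expect_true(mcols(out)$mapped)
    expect_equal(start(out), 1234L)
    expect_equal(end(out), 5678L)
  }
  expect_null(liftIntervalOne(GRanges("chrZ", IRanges(1, 100)), identityMap()))
})

test_that("partial block coverage applies the min-fraction rule", {
  # 100 bp interval [1000,1100) with 60 bp inside one block
  map <- CoordinateMap(GRanges("chr1", IRanges(1001, 1060)),
                       GRanges("chrB", IRanges(5001, 5060)))
  iv <- GRanges("chr1", IRanges(1001, 1100))
  out5 <- liftInterval(iv, map, minFrac = 0.5)
  expect_true(mcols(out5)$mapped)
  expect_equal(mcols(out5)$mapped_bases, 60L)
  expect_equal(start(out5), 5001L)
  out7 <- liftInterval(iv, map, minFrac = 0.7)
  expect_false(mcols(out7)$mapped)
})

test_that("minus-strand blocks map positions in reverse", {
  map <- CoordinateMap(GRanges("chr1", IRanges(101, 200)),
                       GRanges("chrB", IRanges(501, 600), strand = "-"))
  out <- liftInterval(GRanges("chr1", IRanges(101, 110)), map, minFrac = 1)
  # first 10 bases of the block map to the last 10 of the target block
  expect_equal(start(out), 591L)
  expect_equal(end(out), 600L)
})

test_that("lifting matches the per-base oracle on random block fixtures", {
  withr::local_seed(55)
  for (rep in 1:40) {
    # random non-overlapping source blocks in [0, 10kb)
    nb <- sample(1:6, 1)
    bStart <- sort(sample(seq(0, 9000, by = 100), nb))
    bLen <- pmin(sample(50:400, nb, replace = TRUE),
                 diff(c(bStart, 10000)))
    dStart <- cumsum(c(0, bLen[-nb] + sample(0:50, nb - 1, replace = TRUE)))
    strandB <- sample(c("+", "-"), nb, replace = TRUE)
    blocks <- data.frame(src_chrom = "s", src_start = bStart,
                         src_end = bStart + bLen,
                         dst_chrom = "d", dst_start = dStart,
                         dst_end = dStart + bLen, dst_strand = strandB)
    map <- CoordinateMap(
      GRanges("s", IRanges(blocks$src_start + 1L, blocks$src_end)),
      GRanges("d", IRanges(blocks$dst_start + 1L, blocks$dst_end),
              strand = blocks$dst_strand))
    for (k in 1:10) {
      s0 <- sample(0:9500, 1); e0 <- s0 + sample(1:500, 1)
      mf <- sample(c(0.3, 0.5, 0.9), 1)
      want <- bruteLift("s", s0, e0, blocks, mf)
      got <- liftInterval(GRanges("s", IRanges(s0 + 1L, e0)), map, minFrac = mf)
      if (is.null(want)) {
        expect_false(mcols(got)$mapped)
      } else {
        expect_true(mcols(got)$mapped)
        expect_equal(start(got), want$start0 + 1L)
        expect_equal(end(got), want$end0)
        expect_equal(mcols(got)$mapped_bases, as.integer(want$bases))
      }
    }
  }
})

test_that("reciprocal orthology requires a round trip back onto the element", {
  te <- TEAnnotation(GRanges("chr1", IRanges(c(1001, 3001), width = 500)),
                     family = c("A", "A"), elementIds = c("e1", "e2"))
  # identity both ways: everything reciprocal
  rec <- reciprocalOrthologMap(te, identityMap(), identityMap())
  expect_true(all(rec$reciprocal_ok))
  expect_true(all(rec$has_ortholog))

  # forward block exists for e1 only; reverse sends it elsewhere
  fwd <- CoordinateMap(GRanges("chr1", IRanges(1001, 1500)),
                       GRanges("chrB", IRanges(101, 600)))
  backWrong <- CoordinateMap(GRanges("chrB", IRanges(101, 600)),
                             GRanges("chr9", IRanges(101, 600)))
  rec2 <- reciprocalOrthologMap(te, fwd, backWrong)
  expect_false(any(rec2$reciprocal_ok))
  expect_true(is.na(rec2$lifted_chrom[2]))  # e2 has no forward mapping

  # with a good round trip, target-annotation check gates has_ortholog
  backGood <- CoordinateMap(GRanges("chrB", IRanges(101, 600)),
                            GRanges("chr1", IRanges(1001, 1500)))
  annB <- TEAnnotation(GRanges("chrB", IRanges(301, 400)), family = "A")
  rec3 <- reciprocalOrthologMap(te, fwd, backGood, annotationB = annB)
  expect_equal(rec3$reciprocal_ok, c(TRUE, FALSE))
  expect_equal(rec3$has_ortholog, c(TRUE, FALSE))
  annBwrongFam <- TEAnnotation(GRanges("chrB", IRanges(301, 400)),
                               family = "ZZZ")
  rec4 <- reciprocalOrthologMap(te, fwd, backGood, annotationB = annBwrongFam)
  expect_equal(rec4$has_ortholog, c(FALSE, FALSE))
})

test_that("ortholog fractions aggregate per family", {
  rec <- data.frame(element_id = sprintf("e%02d", 1:16),
                    family = c(rep("A", 12), rep("B", 4)),
                    has_ortholog = c(rep(TRUE, 3), rep(FALSE, 9),
                                     rep(TRUE, 4)))
  fr <- familyOrthologFraction(rec)
  expect_equal(fr$fraction[fr$family == "A"], 0.25)
  expect_equal(fr$fraction[fr$family == "B"], 1.0)
  expect_error(familyOrthologFraction(rec[0, ]), "no TE copies")
})

test_that("cross-species grouping recovers a planted species-specific effect", {
  cfg <- simulationConfig(
    seed = 19,
    chromosomes = data.frame(name = c("chr1", "chr2"),
                             length = c(20e6, 20e6)),
    families = data.frame(name = c("MARKED", "OTHER"),
                          copy_number = c(40L, 30L),
                          length_mean = 1000, length_sd = 100),
    maskFraction = 0,
    expression = list(n_genes = 3000L, gene_length = 10e3,
                      n_samples_per_condition = 4L, baseline_mean = 6,
                      baseline_sd = 1, noise_sd = 0.5, frac_multiexonic = 0.8,
                      effect = list(window_bp = 50e3, log2fc = 1)),
    speciesB = list(shared_fraction = 0.5, marked_families = "MARKED",
                    effect_log2fc = 0.8, window_bp = 100e3, n_samples = 4L))
  g <- simulateGenome(cfg)
  ts <- simulateTwoSpecies(cfg, g)
  cs <- crossSpeciesStratifiedFc(ts$exprA, ts$exprB, ts$orthologs, g$genes,
                                 ts$markedA, window = 100e3)
  diff <- cs$summary$mean[cs$summary$group == "species_specific"] -
    cs$summary$mean[cs$summary$group == "shared"]
  expect_lt(abs(diff - 0.8), 0.2)
  expect_lt(cs$test$p, 1e-4)
  # per-gene groups equal the generator truth
  truth <- ts$truth$genes
  got <- merge(cs$genes, truth, by.x = "gene_a", by.y = "gene_id")
  inWin <- got$group.y != "none"
  expect_equal(got$group.x[inWin], got$group.y[inWin])
  expect_true(all(is.na(got$group.x[!inWin])))
})

test_that("swapping the two species negates ratios but keeps |difference|", {
  cfg <- simulationConfig(
    seed = 23,
    chromosomes = data.frame(name = "chr1", length = 15e6),
    families = data.frame(name = "M", copy_number = 30L,
                          length_mean = 800, length_sd = 100),
    maskFraction = 0,
    expression = list(n_genes = 800L, gene_length = 8e3,
                      n_samples_per_condition = 3L, baseline_mean = 6,
                      baseline_sd = 1, noise_sd = 0.4, frac_multiexonic = 0.8,
                      effect = list(window_bp = 50e3, log2fc = 1)),
    speciesB = list(shared_fraction = 0.5, marked_families = "M",
                    effect_log2fc = 0.8, window_bp = 80e3, n_samples = 3L))
  g <- simulateGenome(cfg)
  ts <- simulateTwoSpecies(cfg, g)
  fwd <- crossSpeciesStratifiedFc(ts$exprA, ts$exprB, ts$orthologs, g$genes,
                                  ts$markedA, window = 80e3, pseudocount = 0)
  # swap the matrices, keep the (species-A-anchored) grouping: per-gene
  # ratios negate exactly, so the |group difference| is preserved
  orthSwap <- data.frame(gene_a = ts$orthologs$gene_b,
                         gene_b = ts$orthologs$gene_a)
  gA <- geneRanges(g$genes)
  grSwap <- gA[match(ts$orthologs$gene_a, mcols(gA)$gene_id)]
  mcols(grSwap)$gene_id <- ts$orthologs$gene_b
  rev <- crossSpeciesStratifiedFc(ts$exprB, ts$exprA, orthSwap, grSwap,
                                  ts$markedA, window = 80e3, pseudocount = 0)
  expect_equal(rev$genes$ratio, -fwd$genes$ratio)
  dF <- diff(fwd$summary$mean)
  dR <- diff(rev$summary$mean)
  expect_equal(abs(dF), abs(dR))
})
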