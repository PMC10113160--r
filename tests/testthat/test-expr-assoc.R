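# Expression fold changes, distance stratification, TE-promoter detection
# and nearest-peak target assignment.

test_that("log2 fold changes follow the stated formula and filter", {
  m <- rbind(g1 = c(8, 8, 2, 2),       # log2(9/3)
             g2 = c(0.1, 0.1, 0.2, 0.2),  # below threshold in both -> dropped
             g3 = c(5, 5, 5, 5),       # symmetric -> 0
             g4 = c(0.2, 0.2, 7, 7))   # passes in one condition -> kept
  cond <- c("A", "A", "B", "B")
  fc <- computeLog2FC(m, "A", "B", conditions = cond)
  expect_setequal(fc$gene_id, c("g1", "g3", "g4"))
  expect_equal(fc$log2fc[fc$gene_id == "g1"], log2(9 / 3))
  expect_equal(fc$log2fc[fc$gene_id == "g3"], 0)
  expect_error(computeLog2FC(m, "A", "C", conditions = cond), "condition C")
})

test_that("swapping conditions negates every fold change exactly", {
  withr::local_seed(8)
  m <- matrix(2^rnorm(300, 5), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  cond <- rep(c("A", "B"), each = 3)
  ab <- computeLog2FC(m, "A", "B", conditions = cond)
  ba <- computeLog2FC(m, "B", "A", conditions = cond)
  expect_equal(ab$log2fc, -ba$log2fc)
})

test_that("distance bins partition retained genes and label the open bin", {
  gr <- GRanges("chr1", IRanges(c(1, 20e3, 80e3, 300e3), width = 1000))
  mcols(gr)$gene_id <- paste0("g", 1:4)
  targets <- GRanges("chr1", IRanges(500, 600))
  fc <- setNames(rep(0, 4), paste0("g", 1:4))
  expect_warning(st <- stratifyByDistance(fc, gr, targets), "< 2 genes")
  expect_equal(levels(st$genes$bin),
               c("overlap", "<=10kb", "10kb-50kb", "50kb-100kb", ">100kb"))
  expect_equal(st$reference, ">100kb")
  expect_equal(as.character(st$genes$bin),
               c("overlap", "10kb-50kb", "50kb-100kb", ">100kb"))
  expect_false(anyNA(st$genes$bin))
  # genes on a chromosome without targets fall in the open reference bin
  gr2 <- suppressWarnings(c(gr, GRanges("chrZ", IRanges(1, 1000), gene_id = "g5")))
  fc2 <- c(fc, g5 = 0)
  expect_warning(st2 <- stratifyByDistance(fc2, gr2, targets))
  expect_equal(as.character(st2$genes$bin[5]), ">100kb")
})

test_that("a planted near-TE effect is recovered and the null is flat", {
  cfg <- simulationConfig(
    seed = 31,
    chromosomes = data.frame(name = "chr1", length = 40e6),
    families = data.frame(name = "F01", copy_number = 150L,
                          length_mean = 800, length_sd = 100),
    maskFraction = 0,
    expression = list(n_genes = 1200L, gene_length = 10e3,
                      n_samples_per_condition = 4L, baseline_mean = 6,
                      baseline_sd = 1, noise_sd = 0.5,
                      frac_multiexonic = 0.8,
                      effect = list(window_bp = 50e3, log2fc = 1.0)))
  g <- simulateGenome(cfg)
  marked <- granges(g$annotation)
  sim <- simulateExpression(cfg, g, marked)
  fc <- computeLog2FC(sim$expr, "A", "B")
  st <- stratifyByDistance(fc, g$genes, marked)
  near <- st$summary$mean[st$summary$bin %in% c("overlap", "<=10kb", "10kb-50kb")]
  expect_true(all(abs(near - 1) < 0.2))
  expect_lt(abs(st$summary$mean[st$summary$bin == ">100kb"]), 0.1)
  expect_lt(st$anova_p, 1e-6)
  expect_true(all(st$tests$p_adj[st$tests$bin %in% c("<=10kb", "10kb-50kb")] < 0.01))
  # permuting the gene labels destroys the association
  fcPerm <- fc
  fcPerm$log2fc <- withr::with_seed(1, sample(fcPerm$log2fc))
  stPerm <- stratifyByDistance(fcPerm, g$genes, marked)
  expect_gt(stPerm$anova_p, 0.01)
  # wilcox mode agrees on the planted contrast
  stW <- stratifyByDistance(fc, g$genes, marked, test = "wilcox")
  expect_true(all(stW$tests$p_adj[stW$tests$bin %in% c("<=10kb", "10kb-50kb")] < 0.01))
})

test_that("TE promoters require a multi-exonic TSS inside an element", {
  te <- TEAnnotation(GRanges("chr1", IRanges(c(1000, 5000), width = 500)),
                     family = c("LTR8B", "MER39"),
                     elementIds = c("el1", "el2"))
  mkTx <- function(id, start, end, strand, nex) {
    gr <- GRanges("chr1", IRanges(start, end), strand = strand)
    mcols(gr) <- DataFrame(transcript_id = id, gene_id = paste0(id, "g"),
                           exon_count = nex)
    gr
  }
  tx <- c(mkTx("t1", 1100, 3000, "+", 3),  # TSS 1100 inside el1 -> in
          mkTx("t2", 1100, 3000, "+", 1),  # single exon -> out
          mkTx("t3", 100, 900, "+", 2),    # TSS outside -> out
          mkTx("t4", 3000, 5200, "-", 2),  # minus strand TSS 5200 inside el2 -> in
          mkTx("t5", 5100, 9000, "-", 4))  # minus strand TSS 9000 outside -> out
  genes <- GRanges("chr1", IRanges(1, 10000), gene_id = "gX", tss = 1)
  gm <- GeneModels(genes = genes[rep(1, 0)], transcripts = tx)
  hits <- tePromoterTranscripts(gm, te)
  expect_equal(sort(hits$transcript_id), c("t1", "t4"))
  expect_equal(hits$family[hits$transcript_id == "t4"], "MER39")
})

test_that("nearest-peak targets honour the distance boundary exactly", {
  genes <- GRanges("chr1", IRanges(c(100050, 200101, 200102), width = 100),
                   gene_id = c("a", "b", "c"))
  peaks <- GRanges("chr1", IRanges(100101, 100200))
  # gene b: gap = 200101 - 100200 - 1 = 99900; gene c: 99901
  out <- nearestPeakTargets(genes, peaks, maxDist = 99900)
  expect_setequal(out$gene_id, c("a", "b"))
  expect_equal(out$distance[out$gene_id == "a"], 0)
  # random fixture against the exhaustive filter
  withr::local_seed(13)
  gdf <- randIntervals(60)
  pdf <- randIntervals(40)
  gr <- asGr(gdf); mcols(gr)$gene_id <- sprintf("g%02d", 1:60)
  want <- vapply(seq_len(60), function(i) bruteNearest(gdf[i, ], pdf),
                 numeric(1))
  got <- nearestPeakTargets(gr, asGr(pdf), maxDist = 20e3)
  expect_setequal(got$gene_id, sprintf("g%02d", which(want <= 20e3)))
})

test_that("per-family target fold changes flag only the shifted family", {
  withr::local_seed(77)
  # two families far apart; genes near each
  te <- TEAnnotation(
    GRanges("chr1", IRanges(c(seq(1e6, 5e6, by = 1e5),
                              seq(20e6, 24e6, by = 1e5)), width = 500)),
    family = rep(c("UP", "NULLFAM"), each = 41))
  genes <- GRanges("chr1", IRanges(c(seq(1e6, 5e6, by = 5e4),
                                     seq(20e6, 24e6, by = 5e4)), width = 2000))
  mcols(genes)$gene_id <- sprintf("g%03d", seq_along(genes))
  nearUp <- nearestDistance(genes, granges(te)[teFamily(te) == "UP"]) <= 100e3
  fc <- setNames(rnorm(length(genes), 0, 0.2) + ifelse(nearUp, 1, 0),
                 mcols(genes)$gene_id)
  res <- familyTargetFc(te, fc, genes, maxDist = 100e3)
  expect_gte(res$tests$n_targets[res$tests$family == "UP"], 50)
  expect_lt(res$tests$p_adj[res$tests$family == "UP"], 0.01)
  expect_gt(res$tests$p_adj[res$tests$family == "NULLFAM"], 0.05)
  expect_lt(abs(res$tests$median_fc[res$tests$family == "NULLFAM"]), 0.15)
  # all-zero fold changes: median 0, not significant
  fc0 <- setNames(rep(0, length(genes)), mcols(genes)$gene_id)
  res0 <- familyTargetFc(te, fc0, genes, maxDist = 100e3)
  expect_true(all(res0$tests$median_fc == 0))
  expect_true(all(res0$tests$p == 1))
})
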