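# Distance-stratified association between marked elements and gene
# expression. Expression arrives as a SummarizedExperiment (first assay =
# abundances on a linear normalized scale, colData$condition labelling the
# samples) or as a plain matrix plus a condition vector.

.exprMatrix <- function(x, conditions = NULL, assay = 1L) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, assay)
    if (is.null(conditions))
      conditions <- SummarizedExperiment::colData(x)$condition
  } else {
    m <- as.matrix(x)
  }
  if (is.null(conditions))
    stop("sample conditions are required (colData$condition or 'conditions')")
  if (length(conditions) != ncol(m))
    stop("'conditions' must label every sample column")
  if (is.null(rownames(m))) stop("expression matrix needs gene ids as rownames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in expression matrix")
  list(m = m, cond = as.character(conditions))
}

#' Per-gene log2 fold change between two conditions
#'
#' Computes `log2((mean_a + pseudocount) / (mean_b + pseudocount))` from
#' arithmetic per-condition means of the abundance values. Genes whose
#' mean abundance is below `minExpr` in *both* conditions are dropped (the
#' minimal-expression filter); a gene passing in either condition is kept.
#'
#' @param expr `SummarizedExperiment` (assay = abundances,
#'   `colData$condition`) or numeric matrix (genes x samples).
#' @param condA,condB Condition labels; the fold change is A over B.
#' @param conditions Sample condition labels when `expr` is a matrix.
#' @param minExpr Minimal-expression threshold on the per-condition mean
#'   (default 1; dataset-dependent, record it with your results).
#' @param pseudocount Added to both means before the ratio (default 1).
#' @return Data frame `gene_id, mean_a, mean_b, log2fc` for retained genes.
#' @examples
#' m <- rbind(g1 = c(8, 8, 2, 2), g2 = c(.1, .1, .2, .2))
#' computeLog2FC(m, "A", "B", conditions = c("A", "A", "B", "B"))
#' # g1: log2(9/3) = 1.585; g2 dropped by the expression filter
#' @export
computeLog2FC <- function(expr, condA, condB, conditions = NULL,
                          minExpr = 1, pseudocount = 1) {
  em <- .exprMatrix(expr, conditions)
  ia <- em$cond == condA
  ib <- em$cond == condB
  if (!any(ia)) stop("no samples with condition ", condA)
  if (!any(ib)) stop("no samples with condition ", condB)
  meanA <- rowMeans(em$m[, ia, drop = FALSE])
  meanB <- rowMeans(em$m[, ib, drop = FALSE])
  keep <- meanA >= minExpr | meanB >= minExpr
  data.frame(gene_id = rownames(em$m)[keep],
             mean_a = unname(meanA[keep]), mean_b = unname(meanB[keep]),
             log2fc = unname(log2((meanA[keep] + pseudocount) /
                                  (meanB[keep] + pseudocount))),
             stringsAsFactors = FALSE)
}

# fc: data.frame from computeLog2FC or named numeric vector
.fcVector <- function(fc) {
  if (is.data.frame(fc)) setNames(fc$log2fc, fc$gene_id)
  else if (is.numeric(fc) && !is.null(names(fc))) fc
  else stop("'fc' must be a computeLog2FC data frame or a named numeric vector")
}

.binEdgeLabel <- function(x) {
  ifelse(x %% 1000 == 0, paste0(x / 1000, "kb"), paste0(x, "bp"))
}

# bin labels for edges e1 < e2 < ...: overlap, (0,e1], (e1,e2], ..., (>eK)
.binLabels <- function(edges) {
  lab <- c("overlap", paste0("<=", .binEdgeLabel(edges[1])))
  if (length(edges) > 1)
    lab <- c(lab, paste0(.binEdgeLabel(edges[-length(edges)]), "-",
                         .binEdgeLabel(edges[-1])))
  c(lab, paste0(">", .binEdgeLabel(edges[length(edges)])))
}

.assignBins <- function(distance, edges) {
  labels <- .binLabels(edges)
  idx <- findInterval(distance, c(0, edges), left.open = TRUE) + 1L
  idx[distance == 0] <- 1L
  idx[is.infinite(distance)] <- length(labels)
  factor(labels[idx], levels = labels)
}

#' Stratify expression changes by distance to the nearest marked element
#'
#' Assigns each gene the distance from its span (or TSS, with
#' `anchor = "tss"`) to the nearest target element, bins genes by distance
#' and tests whether the per-bin log2 fold-change distributions differ
#' from the distal reference bin. Bins are: overlap (distance 0), then
#' intervals between the supplied edges, then an open reference bin beyond
#' the last edge (genes on chromosomes without targets also fall there).
#' The default test is a one-way ANOVA followed by Tukey honest
#' significant differences, reporting each bin's contrast against the open
#' reference bin; `test = "wilcox"` instead runs two-sided rank-sum tests
#' of each bin against the reference with Benjamini-Hochberg correction.
#' Bins with fewer than 2 genes are excluded from testing with a warning.
#'
#' @param fc Data frame from [computeLog2FC()] or named numeric vector of
#'   per-gene log2 fold changes.
#' @param genes A [GeneModels-class] or `GRanges` with `gene_id` metadata.
#' @param targets `GRanges` of marked elements.
#' @param edges Increasing positive bin edges in bp
#'   (default `c(10e3, 50e3, 100e3)`).
#' @param anchor Measure distance from the gene `"body"` (default) or its
#'   `"tss"`.
#' @param test `"anova"` (ANOVA + Tukey) or `"wilcox"` (rank-sum + BH).
#' @return A list of class `DistanceStratification`: `genes` (per-gene
#'   table with distance and bin), `summary` (per-bin n/mean/median),
#'   `tests` (per-bin contrast vs the reference), `anova_p` (overall F
#'   test p, `NA` for wilcox mode), `reference` (reference bin label).
#' @export
stratifyByDistance <- function(fc, genes, targets,
                               edges = c(10e3, 50e3, 100e3),
                               anchor = c("body", "tss"),
                               test = c("anova", "wilcox")) {
  anchor <- match.arg(anchor)
  test <- match.arg(test)
  if (any(diff(edges) <= 0) || any(edges <= 0))
    stop("'edges' must be strictly increasing and positive")
  v <- .fcVector(fc)
  gr <- if (is(genes, "GeneModels")) geneRanges(genes) else genes
  if (is.null(mcols(gr)$gene_id)) stop("'genes' must carry gene_id metadata")
  gr <- gr[mcols(gr)$gene_id %in% names(v)]
  anchorGr <- gr
  if (anchor == "tss") {
    tss <- mcols(gr)$tss
    if (is.null(tss)) {
      neg <- as.logical(strand(gr) == "-")
      tss <- ifelse(neg, end(gr), start(gr))
    }
    anchorGr <- GRanges(seqnames(gr), IRanges(tss, width = 1L),
                        strand = strand(gr))
  }
  d <- nearestDistance(anchorGr, targets)
  bin <- .assignBins(d, edges)
  ref <- levels(bin)[nlevels(bin)]
  tab <- data.frame(gene_id = mcols(gr)$gene_id,
                    log2fc = unname(v[mcols(gr)$gene_id]),
                    distance = d, bin = bin, stringsAsFactors = FALSE)

  counts <- table(tab$bin)
  usable <- names(counts)[counts >= 2]
  if (length(setdiff(levels(bin), usable)))
    warning("bins with < 2 genes excluded from testing: ",
            paste(setdiff(levels(bin), usable), collapse = ", "))
  testTab <- tab[tab$bin %in% usable, , drop = FALSE]
  testTab$bin <- droplevels(testTab$bin)

  summ <- do.call(rbind, lapply(levels(bin), function(b) {
    x <- tab$log2fc[tab$bin == b]
    data.frame(bin = b, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               median = if (length(x)) median(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  anovaP <- NA_real_
  tests <- data.frame(bin = character(0), estimate = numeric(0),
                      p = numeric(0), p_adj = numeric(0))
  if (nlevels(testTab$bin) >= 2 && ref %in% levels(testTab$bin)) {
    others <- setdiff(levels(testTab$bin), ref)
    if (test == "anova") {
      fit <- aov(log2fc ~ bin, data = testTab)
      anovaP <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk <- TukeyHSD(fit)$bin
      rows <- rownames(tk)
      est <- p <- setNames(rep(NA_real_, length(others)), others)
      for (b in others) {
        r <- which(rows == paste0(b, "-", ref) | rows == paste0(ref, "-", b))
        if (length(r)) {
          flip <- rows[r[1]] == paste0(ref, "-", b)
          est[b] <- if (flip) -tk[r[1], "diff"] else tk[r[1], "diff"]
          p[b] <- tk[r[1], "p adj"]
        }
      }
      tests <- data.frame(bin = others, estimate = unname(est),
                          p = unname(p), p_adj = unname(p),
                          stringsAsFactors = FALSE)
    } else {
      refVals <- testTab$log2fc[testTab$bin == ref]
      res <- lapply(others, function(b) {
        x <- testTab$log2fc[testTab$bin == b]
        w <- wilcox.test(x, refVals)
        data.frame(bin = b, estimate = median(x) - median(refVals),
                   p = w$p.value, stringsAsFactors = FALSE)
      })
      tests <- do.call(rbind, res)
      tests$p_adj <- p.adjust(tests$p, method = "BH")
    }
  }
  structure(list(genes = tab, summary = summ, tests = tests,
                 anova_p = anovaP, reference = ref, edges = edges,
                 anchor = anchor, test = test),
            class = "DistanceStratification")
}

#' @export
print.DistanceStratification <- function(x, ...) {
  cat("Distance-stratified expression association (", x$test, " mode)\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  if (!is.na(x$anova_p)) cat(sprintf("ANOVA p = %.3g\n", x$anova_p))
  if (nrow(x$tests)) {
    cat("Contrasts vs reference bin '", x$reference, "':\n", sep = "")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Transcripts with a TE-derived promoter
#'
#' Multi-exonic transcripts (`exon_count >= 2`) whose TSS position lies
#' inside an active TE element.
#'
#' @param genes A [GeneModels-class].
#' @param activeTes `GRanges` or [TEAnnotation-class] of active elements.
#' @return Data frame `transcript_id, gene_id, tss, element_id, family`
#'   (element columns `NA` when `activeTes` carries no ids/families).
#' @export
tePromoterTranscripts <- function(genes, activeTes) {
  tx <- transcriptRanges(genes)
  tx <- tx[mcols(tx)$exon_count >= 2L]
  if (length(tx) == 0)
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      tss = integer(0), element_id = character(0),
                      family = character(0)))
  tssGr <- GRanges(seqnames(tx), IRanges(mcols(tx)$tss, width = 1L))
  h <- findOverlaps(tssGr, activeTes, ignore.strand = TRUE)
  first <- !duplicated(queryHits(h))
  qi <- queryHits(h)[first]
  si <- subjectHits(h)[first]
  data.frame(transcript_id = mcols(tx)$transcript_id[qi],
             gene_id = mcols(tx)$gene_id[qi],
             tss = mcols(tx)$tss[qi],
             element_id = if (!is.null(names(activeTes)))
               names(activeTes)[si] else NA_character_,
             family = if (!is.null(mcols(activeTes)$family))
               mcols(activeTes)$family[si] else NA_character_,
             stringsAsFactors = FALSE)
}

#' Genes within a distance of the nearest peak
#'
#' @param genes A [GeneModels-class] or `GRanges` with `gene_id`.
#' @param peaks `GRanges`.
#' @param maxDist Maximum nearest-peak distance in bp (inclusive).
#' @param anchor Distance from gene `"body"` or `"tss"`.
#' @return Data frame `gene_id, distance` for qualifying genes.
#' @export
nearestPeakTargets <- function(genes, peaks, maxDist,
                               anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(maxDist >= 0)
  gr <- if (is(genes, "GeneModels")) geneRanges(genes) else genes
  if (is.null(mcols(gr)$gene_id)) stop("'genes' must carry gene_id metadata")
  a <- if (anchor == "tss" && is(genes, "GeneModels")) geneTss(genes) else gr
  d <- nearestDistance(a, peaks)
  keep <- d <= maxDist
  data.frame(gene_id = mcols(gr)$gene_id[keep], distance = d[keep],
             stringsAsFactors = FALSE)
}

#' Per-family fold-change distributions of nearby target genes
#'
#' For each family, collects the log2 fold changes of genes lying within
#' `maxDist` of any of the family's elements and tests the distribution
#' against zero with a two-sided Wilcoxon signed-rank test,
#' Benjamini-Hochberg corrected across families. Pass an annotation
#' already restricted to marked copies (e.g. H3K27ac-overlapping ones), or
#' supply `marks` to restrict here.
#'
#' @param annotation A [TEAnnotation-class] of (marked) elements.
#' @param fc Per-gene log2 fold changes (data frame or named vector).
#' @param genes A [GeneModels-class] or `GRanges` with `gene_id`.
#' @param maxDist Window in bp (default 100 kb).
#' @param marks Optional `GRanges`; only elements overlapping it are used.
#' @return List: `targets` (long data frame `family, gene_id, distance,
#'   log2fc`) and `tests` (`family, n_targets, median_fc, p, p_adj`;
#'   families with no targets keep `n_targets = 0` and `NA` statistics).
#' @export
familyTargetFc <- function(annotation, fc, genes, maxDist = 100e3,
                           marks = NULL) {
  stopifnot(is(annotation, "TEAnnotation"))
  if (!is.null(marks))
    annotation <- annotation[countOverlaps(annotation, marks,
                                           ignore.strand = TRUE) > 0L]
  v <- .fcVector(fc)
  gr <- if (is(genes, "GeneModels")) geneRanges(genes) else genes
  gr <- gr[mcols(gr)$gene_id %in% names(v)]
  fams <- familyNames(annotation)
  if (length(fams) == 0)
    return(list(targets = data.frame(family = character(0),
                                     gene_id = character(0),
                                     distance = numeric(0),
                                     log2fc = numeric(0)),
                tests = data.frame(family = character(0),
                                   n_targets = integer(0),
                                   median_fc = numeric(0), p = numeric(0),
                                   p_adj = numeric(0))))
  rows <- list(); tests <- list()
  for (f in fams) {
    el <- granges(familyElements(annotation, f))
    d <- nearestDistance(gr, el)
    keep <- d <= maxDist
    n <- sum(keep)
    if (n > 0) {
      gid <- mcols(gr)$gene_id[keep]
      rows[[f]] <- data.frame(family = f, gene_id = gid,
                              distance = d[keep],
                              log2fc = unname(v[gid]),
                              stringsAsFactors = FALSE)
    }
    vals <- if (n > 0) unname(v[mcols(gr)$gene_id[keep]]) else numeric(0)
    p <- if (n > 0 && any(vals != 0)) wilcox.test(vals, mu = 0)$p.value
         else if (n > 0) 1 else NA_real_
    tests[[f]] <- data.frame(family = f, n_targets = n,
                             median_fc = if (n > 0) median(vals) else NA_real_,
                             p = p, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, c(tests, list(make.row.names = FALSE)))
  tests$p_adj <- p.adjust(tests$p, method = "BH")
  list(targets = if (length(rows))
         do.call(rbind, c(rows, list(make.row.names = FALSE)))
       else data.frame(family = character(0), gene_id = character(0),
                       distance = numeric(0), log2fc = numeric(0)),
       tests = tests)
}
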