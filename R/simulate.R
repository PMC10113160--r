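# Seeded generators for synthetic genomes, TE annotations, masks, peaks,
# expression and two-species fixtures with planted, parameterised
# structure. Every generator is a pure function of (config, seed): the
# genome stream uses config$seed, peaks seed+1, expression seed+2, the
# two-species derivation seed+3, so stages can be regenerated
# independently without disturbing each other.

#' Simulation configuration
#'
#' Validates and assembles the parameter set for the synthetic-data
#' generators. Defaults describe a small two-chromosome genome with
#' twenty TE families and unplanted peaks; every study-specific fixture
#' overrides the relevant block.
#'
#' @param seed Integer master seed.
#' @param chromosomes Data frame `name, length` (bp).
#' @param families Data frame `name, copy_number, length_mean, length_sd`.
#' @param maskFraction Fraction of each chromosome covered by the
#'   unmappable mask (blocks of `maskBlock` bp placed at random).
#' @param maskBlock Mask block size in bp.
#' @param peaks List: `count`, `length_mean`, `length_sd`, `planted`
#'   (named numeric: family -> fraction of peaks planted inside that
#'   family's copies; fractions sum to at most 1).
#' @param expression List: `n_genes`, `gene_length`,
#'   `n_samples_per_condition`, `baseline_mean` and `baseline_sd` (log2
#'   scale), `noise_sd` (log2 scale, per sample), `frac_multiexonic`, and
#'   `effect = list(window_bp, log2fc)` -- the planted condition-A effect
#'   for genes within `window_bp` of a marked TE.
#' @param speciesB List: `shared_fraction` (scalar or named per family),
#'   `marked_families` (families whose copies count as marked; default
#'   first family), `effect_log2fc` (species-A extra expression near
#'   marked TEs; in species B only near shared copies), `window_bp`,
#'   `n_samples`.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             chromosomes = data.frame(
                               name = c("chr1", "chr2"),
                               length = c(25e6, 25e6)),
                             families = data.frame(
                               name = sprintf("TE_F%02d", 1:20),
                               copy_number = 50L,
                               length_mean = 800,
                               length_sd = 200),
                             maskFraction = 0.1,
                             maskBlock = 20e3,
                             peaks = list(count = 500L, length_mean = 300,
                                          length_sd = 50,
                                          planted = numeric(0)),
                             expression = list(n_genes = 2000L,
                                               gene_length = 20e3,
                                               n_samples_per_condition = 4L,
                                               baseline_mean = 6,
                                               baseline_sd = 1,
                                               noise_sd = 0.5,
                                               frac_multiexonic = 0.8,
                                               effect = list(window_bp = 50e3,
                                                             log2fc = 1.0)),
                             speciesB = list(shared_fraction = 0.5,
                                             marked_families = NULL,
                                             effect_log2fc = 0.8,
                                             window_bp = 100e3,
                                             n_samples = 4L)) {
  seed <- .assertCount(seed, "seed")
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)),
            all(chromosomes$length > 0),
            is.data.frame(families),
            all(c("name", "copy_number", "length_mean", "length_sd") %in%
                names(families)),
            all(families$copy_number >= 0),
            all(families$length_mean > 0))
  if (anyDuplicated(families$name)) stop("duplicate family names")
  maskFraction <- .assertFraction(maskFraction, "maskFraction")
  pl <- peaks$planted
  if (length(pl)) {
    if (is.null(names(pl)) || any(!names(pl) %in% families$name))
      stop("peaks$planted must be named by known families")
    vapply(seq_along(pl), function(i)
      .assertFraction(pl[i], "peaks$planted"), numeric(1))
    if (sum(pl) > 1) stop("planted fractions must sum to at most 1")
  }
  .assertCount(peaks$count, "peaks$count")
  .assertCount(expression$n_genes, "expression$n_genes")
  .assertCount(expression$n_samples_per_condition,
               "expression$n_samples_per_condition", min = 1L)
  sf <- speciesB$shared_fraction
  if (is.null(names(sf))) {
    .assertFraction(sf, "speciesB$shared_fraction")
  } else {
    vapply(seq_along(sf), function(i)
      .assertFraction(sf[i], "speciesB$shared_fraction"), numeric(1))
  }
  if (is.null(speciesB$marked_families))
    speciesB$marked_families <- families$name[1]
  structure(list(seed = seed, chromosomes = chromosomes,
                 families = families, maskFraction = maskFraction,
                 maskBlock = maskBlock, peaks = peaks,
                 expression = expression, speciesB = speciesB),
            class = "SimulationConfig")
}

# place `n` intervals of widths `w` uniformly inside `space`, rejecting
# overlaps with each other (and implicitly with the mask, which is outside
# the space); draws from the current RNG stream
.placeNonOverlapping <- function(w, space, what = "interval",
                                 maxTries = 60L) {
  n <- length(w)
  if (n == 0) return(GRanges())
  chroms <- names(chromSizes(space))
  # weight chromosomes by mappable length
  reg <- mappableRegions(space)
  regChr <- as.character(seqnames(reg))
  wts <- vapply(chroms, function(c)
    sum(as.numeric(width(reg)[regChr == c])), numeric(1))
  accepted <- GRanges()
  todo <- w
  for (try in seq_len(maxTries)) {
    chr <- sample(chroms, length(todo), replace = TRUE, prob = wts)
    cand <- .withRanges(chr, todo, space)
    ok <- countOverlaps(cand, accepted, ignore.strand = TRUE) == 0L
    # also reject collisions within the batch
    ok <- ok & countOverlaps(cand, cand, ignore.strand = TRUE) == 1L
    accepted <- c(accepted, cand[ok])
    todo <- todo[!ok]
    if (length(todo) == 0) break
  }
  if (length(todo) > 0)
    stop("could not place ", length(todo), " ", what,
         "(s) without overlap: requested content exceeds genome capacity")
  sort(accepted)
}

# sample one interval per (chrom, width) uniformly within the space
.withRanges <- function(chr, w, space) {
  gr <- GRanges(chr, IRanges(1L, width = pmax(w, 1L)))
  plan <- .shufflePlan(gr, space)
  .shuffleDraw(plan)
}

#' Simulate a genome: chromosome sizes, mask, TE annotation, gene models
#'
#' TE copies are placed uniformly at random without overlapping each other
#' or the unmappable mask; genes are placed uniformly (they may overlap
#' TEs), with random strand, a strand-aware TSS, and one transcript each
#' (multi-exonic with probability `frac_multiexonic`). Deterministic for a
#' fixed `config$seed`.
#'
#' @param config A [simulationConfig()] object.
#' @return List: `chromSizes` (named integer), `mask` (`GRanges`),
#'   `space` ([MappableSpace-class]), `annotation`
#'   ([TEAnnotation-class]), `genes` ([GeneModels-class]).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(config$seed, {
    sizes <- setNames(as.integer(config$chromosomes$length),
                      config$chromosomes$name)
    # mask: non-overlapping blocks per chromosome
    mask <- GRanges()
    if (config$maskFraction > 0) {
      free <- mappableSpace(sizes)
      nBlock <- pmax(0L, as.integer(round(
        sizes * config$maskFraction / config$maskBlock)))
      w <- rep(as.integer(config$maskBlock), sum(nBlock))
      if (length(w))
        mask <- .placeNonOverlapping(w, free, what = "mask block")
    }
    space <- mappableSpace(sizes, mask)

    fam <- config$families
    famNames <- rep(fam$name, fam$copy_number)
    teW <- pmax(50L, as.integer(round(rnorm(length(famNames),
                                            rep(fam$length_mean, fam$copy_number),
                                            rep(fam$length_sd, fam$copy_number)))))
    # shuffle placement order so no family is systematically crowded out
    ord <- sample(length(famNames))
    placed <- .placeNonOverlappingKeyed(teW[ord], famNames[ord], space)
    annotation <- TEAnnotation(placed$gr, family = placed$key,
                               elementIds = sprintf("te_%05d",
                                                    seq_along(placed$gr)))

    ex <- config$expression
    nG <- ex$n_genes
    gChr <- sample(names(sizes), nG, replace = TRUE,
                   prob = sizes / sum(as.numeric(sizes)))
    gLen <- as.integer(ex$gene_length)
    gStart <- floor(runif(nG) * (sizes[gChr] - gLen)) + 1L
    gStrand <- sample(c("+", "-"), nG, replace = TRUE)
    gid <- sprintf("gene_%05d", seq_len(nG))
    genesGr <- GRanges(gChr, IRanges(gStart, width = gLen), strand = gStrand)
    mcols(genesGr)$gene_id <- gid
    nExon <- ifelse(runif(nG) < ex$frac_multiexonic, 2L, 1L)
    txGr <- genesGr
    mcols(txGr) <- DataFrame(transcript_id = paste0(gid, ".t1"),
                             gene_id = gid, exon_count = nExon)
    genes <- GeneModels(genes = genesGr, transcripts = txGr)
    list(chromSizes = sizes, mask = mask, space = space,
         annotation = annotation, genes = genes)
  })
}

# like .placeNonOverlapping but keeps a key (e.g. family) attached to each
# placed interval
.placeNonOverlappingKeyed <- function(w, key, space, maxTries = 60L) {
  n <- length(w)
  if (n == 0) return(list(gr = GRanges(), key = character(0)))
  chroms <- names(chromSizes(space))
  reg <- mappableRegions(space)
  regChr <- as.character(seqnames(reg))
  wts <- vapply(chroms, function(c)
    sum(as.numeric(width(reg)[regChr == c])), numeric(1))
  accepted <- GRanges(); accKey <- character(0)
  todo <- seq_len(n)
  for (try in seq_len(maxTries)) {
    chr <- sample(chroms, length(todo), replace = TRUE, prob = wts)
    cand <- .withRanges(chr, w[todo], space)
    ok <- countOverlaps(cand, accepted, ignore.strand = TRUE) == 0L
    ok <- ok & countOverlaps(cand, cand, ignore.strand = TRUE) == 1L
    accepted <- c(accepted, cand[ok])
    accKey <- c(accKey, key[todo[ok]])
    todo <- todo[!ok]
    if (length(todo) == 0) break
  }
  if (length(todo) > 0)
    stop("could not place ", length(todo),
         " interval(s) without overlap: requested content exceeds genome capacity")
  o <- order(accepted)
  list(gr = accepted[o], key = accKey[o])
}

#' Simulate peaks with a planted fraction inside chosen families
#'
#' Planted peaks each overlap (by at least 1 bp) a uniformly chosen copy
#' of their target family; background peaks are placed uniformly over the
#' mappable space. Counts are exact: `round(fraction * count)` peaks per
#' planted family. Deterministic for a fixed `config$seed` (stream
#' `seed + 1`).
#'
#' @param config A [simulationConfig()] object.
#' @param genome Output of [simulateGenome()].
#' @return List: `peaks` (`GRanges`, named `peak_<i>`) and `truth` (data
#'   frame `peak_id, provenance` with `background` or
#'   `planted:<family>`).
#' @export
simulatePeaks <- function(config, genome) {
  stopifnot(inherits(config, "SimulationConfig"))
  pk <- config$peaks
  .withSeed(config$seed + 1L, {
    nTotal <- pk$count
    planted <- pk$planted
    nPlanted <- if (length(planted))
      setNames(as.integer(round(planted * nTotal)), names(planted))
    else integer(0)
    if (length(nPlanted))
      stopifnot(all(names(nPlanted) %in% familyNames(genome$annotation)))
    nBack <- nTotal - sum(nPlanted)
    lens <- pmax(50L, as.integer(round(rnorm(nTotal, pk$length_mean,
                                             pk$length_sd))))
    sizes <- genome$chromSizes
    out <- GRanges(); prov <- character(0)
    li <- 1L
    for (f in names(nPlanted)) {
      k <- nPlanted[[f]]
      if (k == 0) next
      copies <- familyElements(genome$annotation, f)
      pick <- sample(length(copies), k, replace = TRUE)
      el <- copies[pick]
      L <- lens[li:(li + k - 1L)]; li <- li + k
      lo <- pmax(1L, start(el) - L + 1L)
      hi <- pmax(lo, pmin(end(el), sizes[as.character(seqnames(el))] - L + 1L))
      st <- lo + floor(runif(k) * (hi - lo + 1L))
      out <- c(out, GRanges(seqnames(el), IRanges(as.integer(st), width = L)))
      prov <- c(prov, rep(paste0("planted:", f), k))
    }
    if (nBack > 0) {
      chrs <- names(sizes)
      reg <- mappableRegions(genome$space)
      regChr <- as.character(seqnames(reg))
      wts <- vapply(chrs, function(c)
        sum(as.numeric(width(reg)[regChr == c])), numeric(1))
      chr <- sample(chrs, nBack, replace = TRUE, prob = wts)
      back <- .withRanges(chr, lens[li:(li + nBack - 1L)], genome$space)
      out <- c(out, back)
      prov <- c(prov, rep("background", nBack))
    }
    names(out) <- sprintf("peak_%05d", seq_along(out))
    list(peaks = out,
         truth = data.frame(peak_id = names(out), provenance = prov,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate two-condition expression with a distance-dependent effect
#'
#' Per-gene log2 baselines are drawn normal(`baseline_mean`,
#' `baseline_sd`); condition-A samples add `effect$log2fc` iff the gene
#' span lies within `effect$window_bp` of a marked TE; per-sample
#' log2-scale noise is normal(0, `noise_sd`); the emitted abundances are
#' `2^(...)`, i.e. linear-scale. Deterministic for a fixed `config$seed`
#' (stream `seed + 2`).
#'
#' @param config A [simulationConfig()] object.
#' @param genome Output of [simulateGenome()].
#' @param markedTes `GRanges` of marked TE copies.
#' @return List: `expr` (`SummarizedExperiment`, assay `abund`,
#'   `colData$condition` in `A`/`B`) and `truth` (data frame `gene_id,
#'   distance, effect`).
#' @export
simulateExpression <- function(config, genome, markedTes) {
  stopifnot(inherits(config, "SimulationConfig"))
  ex <- config$expression
  .withSeed(config$seed + 2L, {
    g <- geneRanges(genome$genes)
    nG <- length(g)
    d <- nearestDistance(g, markedTes)
    eff <- ifelse(d <= ex$effect$window_bp, ex$effect$log2fc, 0)
    base <- rnorm(nG, ex$baseline_mean, ex$baseline_sd)
    nS <- ex$n_samples_per_condition
    cond <- rep(c("A", "B"), each = nS)
    m <- matrix(0, nrow = nG, ncol = 2L * nS,
                dimnames = list(mcols(g)$gene_id,
                                paste0(cond, rep(seq_len(nS), 2L))))
    for (j in seq_len(2L * nS)) {
      mu <- base + if (cond[j] == "A") eff else 0
      m[, j] <- 2^(mu + rnorm(nG, 0, ex$noise_sd))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(abund = m),
      colData = S4Vectors::DataFrame(condition = cond,
                                     row.names = colnames(m)))
    list(expr = se,
         truth = data.frame(gene_id = mcols(g)$gene_id, distance = d,
                            effect = eff, stringsAsFactors = FALSE))
  })
}

#' Simulate a second species by deleting TE copies
#'
#' Species B is species A with an exact per-family subset of TE copies
#' deleted (`round(shared_fraction * n)` copies kept per family);
#' coordinate maps in both directions carry the deletions as unmapped
#' gaps, genes map one-to-one, and expression for both species plants
#' `effect_log2fc` near marked TEs -- in species B only when every marked
#' TE within the window is shared, so genes near a species-A-specific
#' marked copy carry the effect in A only. Deterministic for a fixed
#' `config$seed` (stream `seed + 3`).
#'
#' @param config A [simulationConfig()] object.
#' @param genome Output of [simulateGenome()] (species A).
#' @return List: `annotationB` ([TEAnnotation-class], B coordinates),
#'   `chromSizesB`, `mapAB`, `mapBA` ([CoordinateMap-class]),
#'   `orthologs` (data frame `gene_a, gene_b`), `genesB`
#'   ([GeneModels-class]), `exprA`, `exprB` (`SummarizedExperiment`),
#'   `markedA` (`GRanges` with truth `has_ortholog` flags), and `truth`
#'   (list `elements` -- per-copy shared flag -- and `genes` -- per-gene
#'   group `shared`/`species_specific`/`none` plus planted effects).
#' @export
simulateTwoSpecies <- function(config, genome) {
  stopifnot(inherits(config, "SimulationConfig"))
  sp <- config$speciesB
  .withSeed(config$seed + 3L, {
    ann <- genome$annotation
    fams <- familyNames(ann)
    sf <- sp$shared_fraction
    sharedFrac <- if (is.null(names(sf)))
      setNames(rep(sf, length(fams)), fams) else sf
    shared <- logical(length(ann))
    for (f in fams) {
      i <- which(teFamily(ann) == f)
      frac <- if (f %in% names(sharedFrac)) sharedFrac[[f]] else 1
      k <- as.integer(round(frac * length(i)))
      shared[sample(i, k)] <- TRUE
    }
    deleted <- reduce(granges(ann[!shared]), ignore.strand = TRUE)

    sizes <- genome$chromSizes
    sizesB <- sizes
    bc <- character(0); bs <- integer(0); be <- integer(0); sh <- integer(0)
    for (chr in names(sizes)) {
      del <- sort(deleted[as.character(seqnames(deleted)) == chr])
      bStart <- c(1L, end(del) + 1L)
      bEnd <- c(start(del) - 1L, sizes[[chr]])
      keep <- bStart <= bEnd
      shiftBy <- cumsum(c(0L, width(del)))[keep]
      bStart <- bStart[keep]; bEnd <- bEnd[keep]
      bc <- c(bc, rep(chr, length(bStart)))
      bs <- c(bs, bStart); be <- c(be, bEnd); sh <- c(sh, shiftBy)
      sizesB[[chr]] <- sizes[[chr]] - sum(width(del))
    }
    srcBlocks <- GRanges(bc, IRanges(bs, be))
    dstBlocks <- GRanges(bc, IRanges(bs - sh, be - sh))
    mapAB <- CoordinateMap(srcBlocks, dstBlocks)
    mapBA <- CoordinateMap(dstBlocks, srcBlocks)

    sharedIdx <- which(shared)
    liftedShared <- liftInterval(granges(ann[sharedIdx]), mapAB, minFrac = 1)
    stopifnot(all(mcols(liftedShared)$mapped))
    annB <- TEAnnotation(.pruneSeqlevels(granges(liftedShared)),
                         family = teFamily(ann)[sharedIdx],
                         elementIds = paste0(names(ann)[sharedIdx], "_B"))

    gA <- geneRanges(genome$genes)
    liftedGenes <- liftInterval(gA, mapAB, minFrac = 0.5)
    keepG <- mcols(liftedGenes)$mapped
    gidA <- mcols(gA)$gene_id[keepG]
    gidB <- paste0(gidA, "_B")
    genesBGr <- .pruneSeqlevels(granges(liftedGenes[keepG]))
    strand(genesBGr) <- strand(gA[keepG])
    mcols(genesBGr)$gene_id <- gidB
    txB <- genesBGr
    txA <- transcriptRanges(genome$genes)
    exCount <- setNames(mcols(txA)$exon_count, mcols(txA)$gene_id)
    mcols(txB) <- DataFrame(transcript_id = paste0(gidB, ".t1"),
                            gene_id = gidB,
                            exon_count = unname(exCount[gidA]))
    genesB <- GeneModels(genes = genesBGr, transcripts = txB)
    orthologs <- data.frame(gene_a = gidA, gene_b = gidB,
                            stringsAsFactors = FALSE)

    markedA <- granges(familyElements(ann, sp$marked_families))
    markedShared <- shared[teFamily(ann) %in% sp$marked_families]
    mcols(markedA)$has_ortholog <- markedShared
    names(markedA) <- names(ann)[teFamily(ann) %in% sp$marked_families]

    # per-gene truth grouping in species-A coordinates
    gAkeep <- gA[keepG]
    dAny <- nearestDistance(gAkeep, markedA)
    dSpec <- nearestDistance(gAkeep, markedA[!markedShared])
    group <- ifelse(dAny > sp$window_bp, "none",
                    ifelse(dSpec <= sp$window_bp, "species_specific",
                           "shared"))
    effA <- ifelse(group == "none", 0, sp$effect_log2fc)
    effB <- ifelse(group == "shared", sp$effect_log2fc, 0)

    ex <- config$expression
    nS <- sp$n_samples
    base <- rnorm(length(gidA), ex$baseline_mean, ex$baseline_sd)
    mkExpr <- function(eff, ids) {
      m <- matrix(2^(rep(base + eff, nS) +
                     rnorm(length(ids) * nS, 0, ex$noise_sd)),
                  nrow = length(ids), ncol = nS,
                  dimnames = list(ids, paste0("s", seq_len(nS))))
      SummarizedExperiment::SummarizedExperiment(
        assays = list(abund = m),
        colData = S4Vectors::DataFrame(condition = rep("TSC", nS),
                                       row.names = colnames(m)))
    }
    exprA <- mkExpr(effA, gidA)
    exprB <- mkExpr(effB, gidB)

    list(annotationB = annB, chromSizesB = sizesB, mapAB = mapAB,
         mapBA = mapBA, orthologs = orthologs, genesB = genesB,
         exprA = exprA, exprB = exprB, markedA = markedA,
         truth = list(
           elements = data.frame(element_id = names(ann),
                                 family = teFamily(ann),
                                 shared = shared,
                                 stringsAsFactors = FALSE),
           genes = data.frame(gene_id = gidA, group = group,
                              effect_a = effA, effect_b = effB,
                              stringsAsFactors = FALSE)))
  })
}
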