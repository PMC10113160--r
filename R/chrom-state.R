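# Chromatin-state combination profiling: classify each TE copy by the set
# of histone-mark peak sets it overlaps, then summarise per-family label
# proportions. Labels are plain combination strings over the provided
# marks (no fixed ontology and no precedence between active and repressive
# marks), so the figure-style categories -- active enhancer
# (K27ac+K4me1), poised enhancer (K4me1_only), promoter-like (anything
# with K4me3) -- are recovered by grouping.

.knownMarks <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K9me3", "H3K27me3")
.shortMark <- c(H3K27ac = "K27ac", H3K4me1 = "K4me1", H3K4me3 = "K4me3",
                H3K9me3 = "K9me3", H3K27me3 = "K27me3")

.stateLabel <- function(present) {
  # present: character vector of mark names, canonical order
  if (length(present) == 0) return("none")
  short <- unname(.shortMark[present])
  if (length(short) == 1) paste0(short, "_only") else paste(short, collapse = "+")
}

#' Classify TE copies by overlapping histone-mark combinations
#'
#' An element carries a mark iff it shares at least 1 bp with that mark's
#' peak set. The `label` is a pure function of the combination of marks
#' present, e.g. `"K27ac+K4me1"`, `"K4me1_only"`, `"none"`.
#'
#' @param annotation A [TEAnnotation-class].
#' @param markPeaks Named list of `GRanges`, one per mark; names must be
#'   among H3K27ac, H3K4me1, H3K4me3, H3K9me3, H3K27me3.
#' @return Data frame with `element_id`, `family`, one logical column per
#'   provided mark, and `label`.
#' @export
classifyElements <- function(annotation, markPeaks) {
  stopifnot(is(annotation, "TEAnnotation"))
  if (!is.list(markPeaks) || length(markPeaks) == 0 ||
      is.null(names(markPeaks)))
    stop("'markPeaks' must be a non-empty named list of GRanges")
  unknown <- setdiff(names(markPeaks), .knownMarks)
  if (length(unknown))
    stop("unknown mark name(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(.knownMarks, collapse = ", "), ")")
  marks <- .knownMarks[.knownMarks %in% names(markPeaks)]  # canonical order
  hit <- vapply(marks, function(m)
    countOverlaps(annotation, markPeaks[[m]], ignore.strand = TRUE) > 0L,
    logical(length(annotation)))
  hit <- matrix(hit, nrow = length(annotation),
                dimnames = list(NULL, marks))
  label <- apply(hit, 1L, function(row) .stateLabel(marks[row]))
  if (length(annotation) == 0) label <- character(0)
  out <- data.frame(element_id = names(annotation),
                    family = teFamily(annotation),
                    stringsAsFactors = FALSE)
  for (m in marks) out[[m]] <- hit[, m]
  out$label <- label
  out
}

#' Per-family proportions of chromatin-state labels
#'
#' With `denominator = "all"` proportions are over every family copy; with
#' a mark name (e.g. `"H3K27ac"`) they are over the copies carrying that
#' mark only, matching summaries like "proportion of H3K27ac-marked
#' elements also marked by H3K4me1". Proportions within a family sum to 1.
#' Families empty under the chosen denominator are omitted with a warning.
#'
#' @param calls Data frame from [classifyElements()].
#' @param denominator `"all"` or one of the marks present in `calls`.
#' @return Data frame `family, label, n, denominator_n, proportion`.
#' @export
familyStateProportions <- function(calls, denominator = "all") {
  if (nrow(calls) == 0)
    return(data.frame(family = character(0), label = character(0),
                      n = integer(0), denominator_n = integer(0),
                      proportion = numeric(0)))
  if (!identical(denominator, "all")) {
    if (!denominator %in% names(calls))
      stop("denominator mark ", denominator, " not present in calls")
    keepFam <- unique(calls$family)
    calls <- calls[calls[[denominator]], , drop = FALSE]
    empty <- setdiff(keepFam, unique(calls$family))
    if (length(empty))
      warning("families with no ", denominator, "-marked copies omitted: ",
              paste(empty, collapse = ", "))
  }
  if (nrow(calls) == 0)
    return(data.frame(family = character(0), label = character(0),
                      n = integer(0), denominator_n = integer(0),
                      proportion = numeric(0)))
  tab <- as.data.frame(table(family = calls$family, label = calls$label),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  denomN <- table(calls$family)
  tab$denominator_n <- as.integer(denomN[tab$family])
  out <- data.frame(family = tab$family, label = tab$label,
                    n = as.integer(tab$Freq),
                    denominator_n = tab$denominator_n,
                    proportion = tab$Freq / tab$denominator_n,
                    stringsAsFactors = FALSE)
  out[order(out$family, out$label), , drop = FALSE]
}

#' Per-family proportion of copies carrying a mark
#'
#' Convenience co-marking summary: the fraction of each family's copies
#' carrying `mark`, optionally among the copies carrying `given` (e.g.
#' fraction of H3K27ac-marked copies that are also H3K4me1-marked).
#'
#' @param calls Data frame from [classifyElements()].
#' @param mark Mark whose proportion is wanted.
#' @param given Optional conditioning mark (the denominator).
#' @return Named numeric vector of proportions, one per family; families
#'   with an empty denominator are dropped.
#' @export
familyMarkProportion <- function(calls, mark, given = NULL) {
  if (!mark %in% names(calls)) stop("mark ", mark, " not present in calls")
  if (!is.null(given)) {
    if (!given %in% names(calls)) stop("mark ", given, " not present in calls")
    calls <- calls[calls[[given]], , drop = FALSE]
  }
  if (nrow(calls) == 0) return(setNames(numeric(0), character(0)))
  prop <- tapply(calls[[mark]], calls$family, mean)
  setNames(as.numeric(prop), names(prop))
}

#' Cross-family summary of a state proportion
#'
#' Median and range, across families, of the per-family proportion of one
#' label (the style of summaries such as "median 72%, range 44-85%").
#'
#' @param proportions Data frame from [familyStateProportions()].
#' @param label The state label to summarise. Families lacking the label
#'   contribute a proportion of 0.
#' @return List with `median`, `min`, `max` and `n_families`.
#' @export
crossFamilySummary <- function(proportions, label) {
  fams <- unique(proportions$family)
  if (length(fams) == 0) stop("no families in the proportion table")
  p <- setNames(rep(0, length(fams)), fams)
  sub <- proportions[proportions$label == label, , drop = FALSE]
  p[sub$family] <- sub$proportion
  list(median = median(p), min = min(p), max = max(p),
       n_families = length(fams))
}
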