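# Multi-assay candidate-family selection: families must be significantly
# peak-enriched in both of two cell contexts, then show placenta-specific
# open chromatin against a panel of non-placental tissues.

#' Families significant in both of two enrichment runs
#'
#' @param recordsA,recordsB Data frames from [familyEnrichment()] /
#'   [callSignificant()], each with `family` and `significant` columns.
#' @return Character vector of families significant in both, sorted.
#' @export
concordantFamilies <- function(recordsA, recordsB) {
  pick <- function(r) {
    if (!all(c("family", "significant") %in% names(r)))
      stop("enrichment records need 'family' and 'significant' columns")
    r$family[r$significant %in% TRUE]
  }
  sort(intersect(pick(recordsA), pick(recordsB)))
}

#' Tissue-specificity filter on a panel of open-chromatin enrichments
#'
#' Applies the placenta-specificity rule to a per-family panel of fold
#' enrichments, one per dataset, labelled by tissue. A family passes when
#' (i) the fraction of placental datasets with fold strictly above
#' `foldMin` is strictly above `fracPlacenta`, and (ii) the median
#' placental fold exceeds the pooled median over the comparison tissues
#' (kidney, liver, lung) by strictly more than `medianDiffMin`. Medians of
#' even-sized groups are midpoint averages.
#'
#' @param panel Data frame with columns `family`, `dataset_id`, `tissue`
#'   (one of `placenta`, `kidney`, `liver`, `lung`) and `fold` (from
#'   [familyEnrichment()] on that dataset's peaks).
#' @param fracPlacenta Required fraction of passing placental datasets
#'   (default 0.8, strict).
#' @param foldMin Per-dataset fold threshold (default 2, strict).
#' @param medianDiffMin Required placental-vs-other median difference
#'   (default 2, strict).
#' @return Data frame, one row per family: `family,
#'   placenta_pass_fraction, placenta_median, other_median, median_diff`,
#'   per-tissue medians (`median_kidney` etc., diagnostics) and `pass`.
#' @export
dnaseSpecificityFilter <- function(panel, fracPlacenta = 0.8, foldMin = 2,
                                   medianDiffMin = 2) {
  need <- c("family", "dataset_id", "tissue", "fold")
  if (!all(need %in% names(panel)))
    stop("panel must contain columns: ", paste(need, collapse = ", "))
  tissues <- c("placenta", "kidney", "liver", "lung")
  bad <- setdiff(unique(panel$tissue), tissues)
  if (length(bad))
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  out <- lapply(sort(unique(panel$family)), function(f) {
    p <- panel[panel$family == f, ]
    have <- tissues %in% p$tissue
    if (!all(have))
      stop("family ", f, " is missing tissue group(s): ",
           paste(tissues[!have], collapse = ", "))
    plac <- p$fold[p$tissue == "placenta"]
    other <- p$fold[p$tissue != "placenta"]
    passFrac <- mean(plac > foldMin)
    mDiff <- median(plac) - median(other)
    data.frame(family = f,
               n_placenta = length(plac),
               placenta_pass_fraction = passFrac,
               placenta_median = median(plac),
               other_median = median(other),
               median_diff = mDiff,
               median_kidney = median(p$fold[p$tissue == "kidney"]),
               median_liver = median(p$fold[p$tissue == "liver"]),
               median_lung = median(p$fold[p$tissue == "lung"]),
               pass = passFrac > fracPlacenta & mDiff > medianDiffMin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select candidate regulatory families
#'
#' Composition of the two selection rules: families significantly enriched
#' in both cell contexts ([concordantFamilies()]) that also pass the
#' tissue-specificity filter ([dnaseSpecificityFilter()]). With no panel
#' the concordant list is returned unchanged, flagged with a warning.
#'
#' @param recordsA,recordsB Enrichment records for the two cell contexts.
#' @param panel Optional open-chromatin panel (see
#'   [dnaseSpecificityFilter()]); families absent from the panel are
#'   dropped with a warning.
#' @param ... Thresholds passed on to [dnaseSpecificityFilter()].
#' @return Data frame with `family` and, when a panel was supplied, the
#'   filter diagnostics; rows sorted by family.
#' @export
selectCandidateFamilies <- function(recordsA, recordsB, panel = NULL, ...) {
  conc <- concordantFamilies(recordsA, recordsB)
  if (length(conc) == 0)
    return(data.frame(family = character(0), stringsAsFactors = FALSE))
  if (is.null(panel) || nrow(panel) == 0) {
    warning("no open-chromatin panel supplied; returning concordant families unfiltered")
    return(data.frame(family = conc, stringsAsFactors = FALSE))
  }
  missing <- setdiff(conc, unique(panel$family))
  if (length(missing))
    warning("concordant families absent from the panel were dropped: ",
            paste(missing, collapse = ", "))
  sub <- panel[panel$family %in% conc, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(family = character(0), stringsAsFactors = FALSE))
  diag <- dnaseSpecificityFilter(sub, ...)
  diag[diag$pass, , drop = FALSE]
}
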