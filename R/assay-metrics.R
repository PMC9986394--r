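# Small, exactly specified bench-assay formulas: delta-delta-Ct fold
# change with multiple reference genes, xenograft tumour volume, the IHC
# staining rubric, and SRB relative growth.

#' Construct a qPCR Ct record
#'
#' One sample's cycle thresholds: the target gene's Ct plus one Ct per
#' reference gene (e.g. Snord48 and U6 for miR assays, L19 and GAPDH for
#' mRNA assays).
#'
#' @param targetCt target-gene cycle threshold (positive, finite).
#' @param referenceCts numeric vector of reference-gene Cts (>= 1).
#' @param sampleId,condition optional labels.
#' @return list of class \code{"CtRecord"}.
#' @export
ctRecord <- function(targetCt, referenceCts, sampleId = NA_character_,
                     condition = NA_character_) {
  stopifnot(is.finite(targetCt), targetCt > 0,
            length(referenceCts) >= 1,
            all(is.finite(referenceCts)), all(referenceCts > 0))
  structure(list(sampleId = sampleId, condition = condition,
                 targetCt = targetCt, referenceCts = referenceCts),
            class = "CtRecord")
}

#' Delta-delta-Ct fold change with multiple reference genes
#'
#' Per record, \code{dCt = targetCt - mean(referenceCts)} (the arithmetic
#' mean of reference Cts is the geometric-mean normaliser on the linear
#' scale); then \code{ddCt = dCt_treated - dCt_control} and the fold change
#' is \code{2^(-ddCt)}. Reciprocity holds exactly:
#' \code{ddctFoldChange(a, b) * ddctFoldChange(b, a) == 1}.
#'
#' @param treated,control \code{\link{ctRecord}} objects with the same
#'   number (and order) of reference genes.
#' @return fold change (numeric scalar) with the intermediate
#'   \code{ddCt} attached as attribute \code{"ddct"}.
#' @examples
#' tr <- ctRecord(25, c(20, 22)); ct <- ctRecord(24, c(20, 22))
#' ddctFoldChange(tr, ct)  # ddCt = 1 -> 0.5
#' @export
ddctFoldChange <- function(treated, control) {
  stopifnot(inherits(treated, "CtRecord"), inherits(control, "CtRecord"))
  if (length(treated$referenceCts) != length(control$referenceCts))
    stop("treated and control must use the same reference genes")
  dctT <- treated$targetCt - mean(treated$referenceCts)
  dctC <- control$targetCt - mean(control$referenceCts)
  ddct <- dctT - dctC
  structure(2^(-ddct), ddct = ddct)
}

#' Xenograft tumour volume (modified ellipsoid)
#'
#' \code{volume = width^2 * length / 2}, with width the shorter calliper
#' dimension; if width exceeds length the two are swapped with a warning
#' so the convention is enforced rather than silently violated.
#'
#' @param width,length calliper measurements in mm (positive).
#' @return volume in mm^3 (vectorised).
#' @examples
#' tumourVolume(5, 8)  # 100
#' @export
tumourVolume <- function(width, length) {
  stopifnot(length(width) == length(length))
  if (any(width <= 0) || any(length <= 0))
    stop("tumour dimensions must be positive")
  swap <- width > length
  if (any(swap)) {
    warning(sprintf("width > length in %d measurement(s): swapped",
                    sum(swap)))
    tmp <- width[swap]
    width[swap] <- length[swap]
    length[swap] <- tmp
  }
  width^2 * length / 2
}

#' Immunohistochemistry staining score
#'
#' Three-point rubric on staining intensity and percentage of positive
#' cells: score 1 for weak intensity in under 10\% of cells; score 2 for
#' weak staining in up to 20\% of cells or moderate staining in up to
#' 10\%; score 3 for moderate or strong staining in over 10\% of cells.
#' Two combinations the rubric leaves uncovered are completed by
#' nearest-neighbour extension preserving monotonicity -- weak staining
#' above 20\% and strong staining at up to 10\% both score 2 -- and are
#' flagged in the \code{"extrapolated"} attribute.
#'
#' @param intensity character vector: \code{"weak"}, \code{"moderate"} or
#'   \code{"strong"}.
#' @param pctPositive percentage of positive cells in [0, 100].
#' @return integer scores in \{1, 2, 3\} with logical attribute
#'   \code{"extrapolated"} marking rubric-completed cells.
#' @examples
#' ihcScore("weak", 5)      # 1
#' ihcScore("moderate", 8)  # 2
#' ihcScore("strong", 50)   # 3
#' @export
ihcScore <- function(intensity, pctPositive) {
  n <- length(intensity)
  stopifnot(length(pctPositive) == n,
            all(pctPositive >= 0 & pctPositive <= 100))
  bad <- setdiff(unique(intensity), c("weak", "moderate", "strong"))
  if (length(bad))
    stop("unknown intensity label(s): ", paste(bad, collapse = ", "))
  score <- integer(n)
  extrapolated <- logical(n)
  for (i in seq_len(n)) {
    p <- pctPositive[i]
    score[i] <- switch(intensity[i],
      weak = if (p < 10) 1L else 2L,
      moderate = if (p <= 10) 2L else 3L,
      strong = if (p <= 10) 2L else 3L)
    extrapolated[i] <- (intensity[i] == "weak" && p > 20) ||
      (intensity[i] == "strong" && p <= 10)
  }
  structure(score, extrapolated = extrapolated)
}

#' SRB relative growth
#'
#' Mean absorbance at day t relative to the day-0 absorbance of the same
#' condition: the cell-mass growth ratio of the sulphorhodamine B assay.
#'
#' @param absorbanceDayT,absorbanceDay0 readings; day 0 must be positive.
#' @return ratio (vectorised).
#' @examples
#' relativeGrowth(0.9, 0.45)  # 2
#' @export
relativeGrowth <- function(absorbanceDayT, absorbanceDay0) {
  if (any(absorbanceDay0 <= 0))
    stop("day-0 absorbance must be positive")
  absorbanceDayT / absorbanceDay0
}
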