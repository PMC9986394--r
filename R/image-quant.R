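# Image quantification: nuclear segmentation of the Hoechst channel,
# caspase measurement inside nuclei only, per-field and per-well scoring.

#' Segment nuclei from the Hoechst channel
#'
#' Standard transparent stack: Gaussian smoothing, global Otsu threshold
#' (or a fixed threshold), hole filling, connected-component labelling,
#' removal of objects outside \code{[minArea, maxArea]}, and an optional
#' distance-transform watershed to split touching nuclei. The caspase
#' channel is then measured \emph{inside each nucleus mask only}, giving
#' the per-nucleus mean reporter intensity.
#'
#' @param image a \linkS4class{FieldImage}.
#' @param thresholdMethod \code{"otsu"} (default) or \code{"fixed"}.
#' @param fixedThreshold intensity threshold on the smoothed Hoechst channel
#'   (16-bit scale), required when \code{thresholdMethod = "fixed"}.
#' @param smoothSigma Gaussian smoothing SD in pixels.
#' @param minArea,maxArea object area bounds in pixels.
#' @param splitTouching if \code{TRUE}, apply a distance-transform watershed
#'   to split touching nuclei.
#' @return A data.frame with one row per nucleus: \code{label},
#'   \code{centroidRow}, \code{centroidCol}, \code{area},
#'   \code{meanCaspase}, and \code{isApoptotic} (\code{NA} until
#'   \code{\link{callApoptotic}} is applied). A field with no foreground
#'   (e.g. a constant channel) yields zero rows, not an error.
#' @examples
#' f <- genFieldImage(nNuclei = 20, seed = 3, imageShape = c(256L, 256L))
#' nuc <- segmentNuclei(f$image)
#' nrow(nuc)
#' @export
segmentNuclei <- function(image, thresholdMethod = c("otsu", "fixed"),
                          fixedThreshold = NULL, smoothSigma = 2,
                          minArea = 10, maxArea = 5000,
                          splitTouching = FALSE) {
  stopifnot(is(image, "FieldImage"))
  validObject(image)
  thresholdMethod <- match.arg(thresholdMethod)
  hx <- image@hoechst / 65535
  empty <- data.frame(label = integer(0), centroidRow = numeric(0),
                      centroidCol = numeric(0), area = integer(0),
                      meanCaspase = numeric(0), isApoptotic = logical(0))
  if (diff(range(hx)) == 0) return(empty)

  img <- EBImage::Image(hx)
  sm <- if (smoothSigma > 0) EBImage::gblur(img, sigma = smoothSigma) else img
  thr <- if (thresholdMethod == "otsu") {
    EBImage::otsu(sm, range = c(0, 1))
  } else {
    if (is.null(fixedThreshold))
      stop("fixedThreshold is required with thresholdMethod = 'fixed'")
    fixedThreshold / 65535
  }
  mask <- sm > thr
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(mask)
  lab <- if (splitTouching) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- EBImage::imageData(lab)

  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= minArea & areas <= maxArea)
  if (!length(keep)) return(empty)

  idx <- which(lab > 0 & lab %in% keep)
  labv <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  casp <- image@caspase[idx]

  ord <- sort(unique(labv))
  f <- factor(labv, levels = ord)
  data.frame(
    label = seq_along(ord),
    centroidRow = as.numeric(tapply(rows, f, mean)),
    centroidCol = as.numeric(tapply(cols, f, mean)),
    area = as.integer(tapply(rows, f, length)),
    meanCaspase = as.numeric(tapply(casp, f, mean)),
    isApoptotic = NA,
    row.names = NULL
  )
}

# 1-D Otsu threshold on a numeric vector (between-class variance maximiser).
otsuVector <- function(x, nBins = 256L) {
  rg <- range(x)
  if (diff(rg) == 0) return(rg[1])
  br <- seq(rg[1], rg[2], length.out = nBins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nBins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[nBins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  # threshold at the upper edge of the optimal class-1 bin, so the whole
  # bin stays below the cut
  br[-1][which.max(sigmaB)]
}

#' Mark nuclei as apoptotic by their nuclear caspase signal
#'
#' Under the default fixed rule a nucleus is apoptotic when its mean
#' nuclear caspase intensity is at or above \code{threshold}; fixed
#' thresholds keep wells comparable across a plate and can be calibrated on
#' control wells. The \code{"otsu"} rule instead derives the cut from the
#' field's own distribution of per-nucleus means; with fewer than two
#' nuclei it falls back to the fixed threshold with a warning.
#'
#' Raising the threshold can never increase the number of positives.
#'
#' @param nuclei data.frame from \code{\link{segmentNuclei}}.
#' @param method \code{"fixed"} (default) or \code{"otsu"}.
#' @param threshold fixed intensity threshold (16-bit scale).
#' @return The input with \code{isApoptotic} set.
#' @export
callApoptotic <- function(nuclei, method = c("fixed", "otsu"),
                          threshold = 10000) {
  method <- match.arg(method)
  stopifnot(is.data.frame(nuclei), "meanCaspase" %in% colnames(nuclei))
  if (method == "otsu") {
    if (nrow(nuclei) < 2L) {
      warning("fewer than 2 nuclei: falling back to the fixed threshold")
    } else {
      threshold <- otsuVector(nuclei$meanCaspase)
    }
  }
  nuclei$isApoptotic <- nuclei$meanCaspase >= threshold
  nuclei
}

#' Score one field: the apoptotic fraction
#'
#' The screen's primary readout: the fraction (0-1) of nuclei in the field
#' whose nuclear caspase signal was called positive. A field with no cells
#' has an undefined score, returned as \code{NA} with \code{nCells = 0}.
#'
#' @param nuclei data.frame with \code{isApoptotic} set
#'   (\code{\link{callApoptotic}}).
#' @return One-row data.frame: \code{nCells}, \code{nApoptotic},
#'   \code{apoptoticScore}.
#' @export
scoreField <- function(nuclei) {
  stopifnot(is.data.frame(nuclei))
  n <- nrow(nuclei)
  if (n > 0 && anyNA(nuclei$isApoptotic))
    stop("isApoptotic must be set on all nuclei; run callApoptotic() first")
  nApo <- if (n > 0) sum(nuclei$isApoptotic) else 0L
  data.frame(nCells = n, nApoptotic = as.integer(nApo),
             apoptoticScore = if (n > 0) nApo / n else NA_real_)
}

#' Aggregate field scores into a per-well score
#'
#' Wells aggregate by the unweighted mean of the defined field scores
#' (fields, not pooled cells, are the replication unit of the readout);
#' fields with no cells are dropped from the mean. If every field is
#' empty the well is flagged missing (\code{NA} score) with a warning so
#' it can be excluded downstream.
#'
#' @param fieldScores data.frame of rows from \code{\link{scoreField}}.
#' @param plateRow named list or one-row data.frame carrying the plate-map
#'   entry: \code{well}, \code{cell_line}, \code{inhibitor_id}, \code{role},
#'   \code{replicate}.
#' @param poolCells if \code{TRUE}, score the well as total apoptotic
#'   nuclei over total nuclei instead of the mean of field fractions.
#' @return One-row data.frame: plate-map columns plus
#'   \code{apoptotic_score}, \code{total_cells}, \code{n_fields}.
#' @export
aggregateWell <- function(fieldScores, plateRow, poolCells = FALSE) {
  stopifnot(is.data.frame(fieldScores), nrow(fieldScores) >= 1)
  ok <- !is.na(fieldScores$apoptoticScore)
  score <- if (!any(ok)) {
    warning(sprintf("well %s: all %d fields empty; flagged missing",
                    plateRow[["well"]], nrow(fieldScores)))
    NA_real_
  } else if (poolCells) {
    sum(fieldScores$nApoptotic[ok]) / sum(fieldScores$nCells[ok])
  } else {
    mean(fieldScores$apoptoticScore[ok])
  }
  data.frame(
    well = plateRow[["well"]],
    cell_line = plateRow[["cell_line"]],
    inhibitor_id = plateRow[["inhibitor_id"]],
    role = plateRow[["role"]],
    replicate = plateRow[["replicate"]],
    apoptotic_score = score,
    total_cells = sum(fieldScores$nCells),
    n_fields = nrow(fieldScores),
    stringsAsFactors = FALSE
  )
}

#' Quantify a set of fields end-to-end into a well score
#'
#' Convenience pipeline: segment each field, call apoptotic nuclei, score
#' fields, aggregate to the well.
#'
#' @param images list of \linkS4class{FieldImage} from one well.
#' @param plateRow plate-map entry for the well (see
#'   \code{\link{aggregateWell}}).
#' @param caspaseThreshold fixed caspase positivity threshold.
#' @param ... further arguments to \code{\link{segmentNuclei}}.
#' @return One-row well-score data.frame.
#' @export
quantifyWell <- function(images, plateRow, caspaseThreshold = 10000, ...) {
  fs <- do.call(rbind, lapply(images, function(im) {
    scoreField(callApoptotic(segmentNuclei(im, ...),
                             threshold = caspaseThreshold))
  }))
  aggregateWell(fs, plateRow)
}
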