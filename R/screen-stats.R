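# The screen statistic: per-inhibitor log fold change of resistant-line vs
# parental apoptotic scores, robust Z-scores via median/MAD with the 0.6745
# normal-consistency constant, the |RZ| >= 2.5 significance rule, and the
# three-way phenotype classification.

#' Construct a ScreenStatsConfig
#'
#' Defaults reproduce the published analysis: fold change of the mean
#' resistant-line score over the parental MCF7 score in log base 2 with
#' pseudocount 0.001, robust Z via median/MAD scaled by 0.6745,
#' significance at |RZ| >= 2.5, and phenotype criteria 0.10 / 0.20 / 0.50.
#'
#' @param logBase base of the fold-change logarithm; the robust Z-score is
#'   invariant to this choice (it rescales all LFCs by one positive
#'   constant), so only the reported LFC column changes.
#' @param pseudocount added to numerator and denominator of the score
#'   ratio; guards wells with a zero parental score. 0 restores the
#'   literal formula.
#' @param zConstant MAD-to-sigma consistency constant, the 0.75 quantile
#'   of the standard normal (see \code{\link{madNormalConstant}}).
#' @param zThreshold significance cut-off on |robust Z|.
#' @param critResponsive,critResistant,critPan phenotype classification
#'   criteria on the apoptotic-score scale.
#' @param parentalLine,resistantLines cell-line names.
#' @param collapse replicate collapse, \code{"mean"} (default) or
#'   \code{"median"}.
#' @return A validated \linkS4class{ScreenStatsConfig}.
#' @examples
#' screenStatsConfig()
#' @export
screenStatsConfig <- function(logBase = 2, pseudocount = 0.001,
                              zConstant = 0.6745, zThreshold = 2.5,
                              critResponsive = 0.10, critResistant = 0.20,
                              critPan = 0.50, parentalLine = "MCF7",
                              resistantLines = c("TamR", "LTED"),
                              collapse = c("mean", "median")) {
  new("ScreenStatsConfig", logBase = logBase, pseudocount = pseudocount,
      zConstant = zConstant, zThreshold = zThreshold,
      critResponsive = critResponsive, critResistant = critResistant,
      critPan = critPan, parentalLine = parentalLine,
      resistantLines = resistantLines, collapse = match.arg(collapse))
}

#' The MAD normal-consistency constant
#'
#' For normally distributed data the median absolute deviation converges to
#' \eqn{\sigma / \Phi^{-1}(0.75)}; multiplying \code{(x - median) / MAD} by
#' \eqn{\Phi^{-1}(0.75) \approx 0.6745} therefore makes the robust Z-score
#' comparable to a classical standard-normal Z.
#'
#' @param p quantile, 0.75 by default.
#' @return \code{qnorm(p)}.
#' @examples
#' round(madNormalConstant(), 4)  # 0.6745
#' @export
madNormalConstant <- function(p = 0.75) qnorm(p)

#' One-sided normal tail probability of a Z threshold
#'
#' The p-value attached to the screen's significance rule: an absolute
#' robust Z of at least \code{z} corresponds to a one-sided standard-normal
#' tail probability \eqn{1 - \Phi(z)}; at the default threshold 2.5 this is
#' 0.00621.
#'
#' @param z Z threshold (finite).
#' @return \code{1 - pnorm(z)}, strictly decreasing in \code{z}.
#' @examples
#' signif(significancePValue(2.5), 3)  # 0.00621
#' @export
significancePValue <- function(z) {
  stopifnot(is.finite(z))
  pnorm(z, lower.tail = FALSE)
}

#' Log fold change of resistant over parental apoptotic score
#'
#' \code{log_base((resistant + pseudocount) / (parental + pseudocount))},
#' where \code{resistant} is the mean apoptotic score across the resistant
#' lines and \code{parental} the MCF7 score. With pseudocount 0 a zero
#' parental score is a domain error, reported with the offending
#' inhibitor's id.
#'
#' @param resistant,parental numeric vectors of apoptotic scores in [0, 1].
#' @param config a \linkS4class{ScreenStatsConfig}.
#' @param ids optional inhibitor ids used in error messages.
#' @return numeric vector of LFCs.
#' @examples
#' cfg <- screenStatsConfig(pseudocount = 0)
#' computeLfc(0.5, 0.25, cfg)  # 1
#' @export
computeLfc <- function(resistant, parental, config = screenStatsConfig(),
                       ids = NULL) {
  stopifnot(length(resistant) == length(parental))
  denom <- parental + config@pseudocount
  if (any(denom <= 0)) {
    bad <- which(denom <= 0)
    lab <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("zero parental score with pseudocount 0 for inhibitor(s): ", lab)
  }
  log((resistant + config@pseudocount) / denom, base = config@logBase)
}

#' Robust Z-scores via median and MAD
#'
#' Centre on the median, scale by the raw median absolute deviation
#' \code{median(|x - median(x)|)} and multiply by the normal-consistency
#' constant (0.6745 by default), giving scores comparable to classical
#' Z-scores for normal data but resistant to the screen's hit outliers.
#' A degenerate spread (MAD = 0) leaves every score undefined: they are
#' returned as \code{NA} with a warning, never silently dropped.
#'
#' @param x numeric vector of LFCs (length >= 2).
#' @param zConstant consistency constant.
#' @return list with \code{xMedian}, \code{mad} and \code{rz} (same length
#'   as \code{x}).
#' @examples
#' robustZScores(c(-2, -1, 0, 1, 2))$rz  # 0.6745 * x
#' @export
robustZScores <- function(x, zConstant = 0.6745) {
  if (length(x) == 0) stop("empty LFC vector")
  if (length(x) < 2) stop("at least 2 values are required")
  xMedian <- median(x)
  madRaw <- median(abs(x - xMedian))
  rz <- if (madRaw == 0) {
    warning("MAD is 0: robust Z-scores undefined, returned as NA")
    rep(NA_real_, length(x))
  } else {
    zConstant * (x - xMedian) / madRaw
  }
  list(xMedian = xMedian, mad = madRaw, rz = rz)
}

#' Classify an inhibitor's apoptotic phenotype across the three lines
#'
#' Evaluated in priority order pan, resistant-only, responsive-only (a hit
#' meeting a broader criterion is never double-assigned to a narrower one):
#' \itemize{
#'   \item \code{pan}: all three scores at or above \code{critPan};
#'   \item \code{resistant_only}: both resistant scores at or above
#'     \code{critResistant} while the parental score is below it;
#'   \item \code{responsive_only}: parental score at or above
#'     \code{critResponsive} while both resistant scores are below it;
#'   \item \code{none}: otherwise.
#' }
#'
#' @param parental,resistant1,resistant2 numeric vectors of per-line mean
#'   apoptotic scores.
#' @param config a \linkS4class{ScreenStatsConfig}.
#' @return character vector of categories.
#' @examples
#' classifyCategory(0.6, 0.6, 0.6)    # "pan"
#' classifyCategory(0.05, 0.25, 0.25) # "resistant_only"
#' @export
classifyCategory <- function(parental, resistant1, resistant2,
                             config = screenStatsConfig()) {
  n <- length(parental)
  stopifnot(length(resistant1) == n, length(resistant2) == n)
  out <- rep("none", n)
  respOnly <- parental >= config@critResponsive &
    resistant1 < config@critResponsive & resistant2 < config@critResponsive
  resOnly <- resistant1 >= config@critResistant &
    resistant2 >= config@critResistant & parental < config@critResistant
  pan <- parental >= config@critPan & resistant1 >= config@critPan &
    resistant2 >= config@critPan
  out[respOnly] <- "responsive_only"
  out[resOnly] <- "resistant_only"
  out[pan] <- "pan"
  out
}

#' Call hits on a screen score table
#'
#' The full screen statistic: control wells are excluded, replicates are
#' collapsed (arithmetic mean by default) to one profile per inhibitor and
#' line, the resistant-vs-parental LFC is computed per inhibitor, robust
#' Z-scores are taken over the LFC distribution of the whole library, the
#' significance flag applies the |RZ| >= threshold rule, and the phenotype
#' category applies the three-way classification. The two flags are
#' independent: a category can be assigned to a non-significant inhibitor
#' and vice versa.
#'
#' Inhibitors missing any of the three cell lines are excluded with a
#' warning naming them.
#'
#' @param wellScores data.frame with columns \code{inhibitor_id},
#'   \code{cell_line}, \code{replicate}, \code{apoptotic_score} and
#'   optionally \code{role} (rows with role other than \code{"sample"} are
#'   dropped).
#' @param config a \linkS4class{ScreenStatsConfig}.
#' @return A \link[S4Vectors]{DataFrame} sorted by |robust Z| descending,
#'   with columns \code{inhibitor_id}, per-line mean scores,
#'   \code{resistant_mean}, \code{lfc}, \code{rz_score},
#'   \code{significant}, \code{category}; table-level \code{metadata()}
#'   holds \code{xMedian} and \code{mad} of the LFC distribution.
#' @examples
#' tbl <- genScreenTable(screenScenario(noiseSd = 0), seed = 1)
#' hits <- callHits(tbl$scores)
#' table(hits$category)
#' @export
callHits <- function(wellScores, config = screenStatsConfig()) {
  validObject(config)
  if (length(config@resistantLines) != 2L)
    stop("the three-way classification requires exactly two resistant lines")
  need <- c("inhibitor_id", "cell_line", "apoptotic_score")
  stopifnot(all(need %in% colnames(wellScores)))
  if ("role" %in% colnames(wellScores))
    wellScores <- wellScores[wellScores$role == "sample", , drop = FALSE]
  wellScores <- wellScores[!is.na(wellScores$apoptotic_score), , drop = FALSE]

  lines <- c(config@parentalLine, config@resistantLines)
  collapse <- if (config@collapse == "mean") mean else median
  agg <- aggregate(apoptotic_score ~ inhibitor_id + cell_line,
                   data = wellScores, FUN = collapse)
  prof <- reshape(agg, idvar = "inhibitor_id", timevar = "cell_line",
                  direction = "wide")
  colnames(prof) <- sub("^apoptotic_score\\.", "", colnames(prof))
  missingLine <- !lines %in% colnames(prof)
  if (any(missingLine))
    stop("cell line(s) absent from the table: ",
         paste(lines[missingLine], collapse = ", "))
  complete <- stats::complete.cases(prof[, lines])
  if (any(!complete)) {
    warning(sprintf("excluding %d inhibitor(s) missing a cell line: %s",
                    sum(!complete),
                    paste(head(prof$inhibitor_id[!complete], 5),
                          collapse = ", ")))
    prof <- prof[complete, , drop = FALSE]
  }

  parental <- prof[[config@parentalLine]]
  resMat <- as.matrix(prof[, config@resistantLines, drop = FALSE])
  resistantMean <- rowMeans(resMat)
  lfc <- computeLfc(resistantMean, parental, config,
                    ids = prof$inhibitor_id)
  rzs <- robustZScores(lfc, config@zConstant)
  significant <- !is.na(rzs$rz) & abs(rzs$rz) >= config@zThreshold
  category <- classifyCategory(parental, resMat[, 1], resMat[, 2], config)

  out <- S4Vectors::DataFrame(
    inhibitor_id = prof$inhibitor_id,
    prof[, lines, drop = FALSE],
    resistant_mean = resistantMean,
    lfc = lfc,
    rz_score = rzs$rz,
    significant = significant,
    category = category
  )
  ord <- order(abs(out$rz_score), decreasing = TRUE, na.last = TRUE)
  out <- out[ord, ]
  S4Vectors::metadata(out) <- list(xMedian = rzs$xMedian, mad = rzs$mad,
                                   config = config)
  out
}
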