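# S4 classes for the screen's central data objects.
#
# Pixel convention: matrices are indexed [row, col], 1-based, as everywhere
# in R. Intensities are 16-bit (integers in 0..65535 stored as numeric).

#' FieldImage: one two-channel microscope field
#'
#' The raw unit of the screen readout: a Hoechst (nuclear stain) channel and
#' a caspase-3/7 reporter channel of identical shape, plus the plate-well
#' label and field index they came from.
#'
#' @slot hoechst numeric matrix of 16-bit nuclear-stain intensities.
#' @slot caspase numeric matrix of 16-bit caspase-reporter intensities,
#'   same shape as \code{hoechst}.
#' @slot well character(1), plate-well label.
#' @slot fieldIndex integer(1), 1-based index of the field within the well.
#'
#' @seealso \code{\link{genFieldImage}}, \code{\link{segmentNuclei}}
#' @export
setClass("FieldImage",
  representation(
    hoechst = "matrix",
    caspase = "matrix",
    well = "character",
    fieldIndex = "integer"
  )
)

setValidity("FieldImage", function(object) {
  msg <- character()
  if (!identical(dim(object@hoechst), dim(object@caspase)))
    msg <- c(msg, "hoechst and caspase channels must share the same shape")
  if (any(object@hoechst < 0) || any(object@caspase < 0))
    msg <- c(msg, "channel intensities must be non-negative")
  if (length(object@well) != 1L || is.na(object@well))
    msg <- c(msg, "well must be a single non-missing label")
  if (length(object@fieldIndex) != 1L || object@fieldIndex < 1L)
    msg <- c(msg, "fieldIndex must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' FieldTruth: ground truth for a generated field
#'
#' Records the generator's intent for one synthetic field: how many nuclei
#' were placed and where, their radii, and which of them were rendered
#' apoptotic (elevated nuclear caspase signal).
#'
#' @slot nNuclei integer(1), number of nuclei placed.
#' @slot centers numeric matrix with \code{nNuclei} rows and columns
#'   \code{row}, \code{col} (1-based pixel coordinates of nucleus centres).
#' @slot radii numeric vector of per-nucleus radii in pixels.
#' @slot apoptoticIds integer vector of nucleus indices (1-based) rendered
#'   apoptotic.
#' @slot apoptoticFraction numeric(1), \code{length(apoptoticIds)/nNuclei}
#'   (0 when no nuclei were placed).
#'
#' @export
setClass("FieldTruth",
  representation(
    nNuclei = "integer",
    centers = "matrix",
    radii = "numeric",
    apoptoticIds = "integer",
    apoptoticFraction = "numeric"
  )
)

setValidity("FieldTruth", function(object) {
  n <- object@nNuclei
  msg <- character()
  if (nrow(object@centers) != n)
    msg <- c(msg, "centers must have one row per nucleus")
  if (length(object@radii) != n)
    msg <- c(msg, "radii must have one entry per nucleus")
  if (any(object@apoptoticIds < 1L) || any(object@apoptoticIds > n))
    msg <- c(msg, "apoptoticIds must index nuclei")
  if (anyDuplicated(object@apoptoticIds))
    msg <- c(msg, "apoptoticIds must be unique")
  expected <- if (n > 0L) length(object@apoptoticIds) / n else 0
  if (abs(object@apoptoticFraction - expected) > 1e-8)
    msg <- c(msg, "apoptoticFraction inconsistent with apoptoticIds")
  if (length(msg)) msg else TRUE
})

#' ScreenScenario: parameters of a simulated inhibitor screen
#'
#' Describes a full screen to simulate: library size, per-line baseline
#' apoptotic scores of non-hits, replicate noise, and a table of planted
#' hits with their per-line effect scores and phenotype category.
#'
#' The defaults emulate the screened library: 954 inhibitors in three cell
#' lines (MCF7 and its endocrine-resistant derivatives TamR and LTED) in
#' biological triplicate, with 4 responsive-only, 9 resistant-only and 13
#' pan-apoptotic hits planted.
#'
#' @slot nInhibitors integer(1), library size.
#' @slot baseline named numeric, mean apoptotic score of non-hit wells per
#'   cell line (names are the cell lines).
#' @slot noiseSd numeric(1), replicate-level Gaussian noise SD.
#' @slot nReplicates integer(1), biological replicates per (inhibitor, line).
#' @slot planted data.frame with columns \code{inhibitor_id},
#'   \code{category} (one of \code{responsive_only}, \code{resistant_only},
#'   \code{pan}) and one score column per cell line.
#'
#' @seealso \code{\link{screenScenario}}, \code{\link{genScreenTable}}
#' @export
setClass("ScreenScenario",
  representation(
    nInhibitors = "integer",
    baseline = "numeric",
    noiseSd = "numeric",
    nReplicates = "integer",
    planted = "data.frame"
  )
)

.validCategories <- c("responsive_only", "resistant_only", "pan", "none")

setValidity("ScreenScenario", function(object) {
  msg <- character()
  lines <- names(object@baseline)
  if (is.null(lines) || any(!nzchar(lines)))
    msg <- c(msg, "baseline must be named by cell line")
  if (any(object@baseline < 0 | object@baseline > 1))
    msg <- c(msg, "baseline scores must lie in [0, 1]")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (object@nInhibitors < 1L || object@nReplicates < 1L)
    msg <- c(msg, "nInhibitors and nReplicates must be positive")
  pl <- object@planted
  if (nrow(pl)) {
    need <- c("inhibitor_id", "category", lines)
    if (!all(need %in% colnames(pl)))
      msg <- c(msg, sprintf("planted must have columns: %s",
                            paste(need, collapse = ", ")))
    else {
      if (!all(pl$category %in% setdiff(.validCategories, "none")))
        msg <- c(msg, "planted categories must be responsive_only, resistant_only or pan")
      sc <- as.matrix(pl[, lines, drop = FALSE])
      if (any(sc < 0 | sc > 1))
        msg <- c(msg, "planted per-line scores must lie in [0, 1]")
      if (anyDuplicated(pl$inhibitor_id))
        msg <- c(msg, "planted inhibitor ids must be unique")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScreenStatsConfig: hit-calling parameters
#'
#' Holds every tunable of the screen statistic: the log base and
#' pseudocount of the fold change, the robust-Z constant and significance
#' threshold, and the three phenotype-classification criteria.
#'
#' Defaults are the published analysis values: log base 2 with pseudocount
#' 0.001, Z constant 0.6745 (the 0.75 quantile of the standard normal, to
#' which the MAD of normal data converges), significance at |RZ| >= 2.5,
#' and classification criteria 0.10 (parental-only), 0.20 (resistant-only)
#' and 0.50 (all three lines).
#'
#' @slot logBase numeric(1), base of the fold-change logarithm.
#' @slot pseudocount numeric(1), added to numerator and denominator of the
#'   score ratio; 0 restores the literal formula.
#' @slot zConstant numeric(1), MAD-to-sigma consistency constant.
#' @slot zThreshold numeric(1), |robust Z| significance cut-off.
#' @slot critResponsive numeric(1), minimum parental score for the
#'   responsive-only category.
#' @slot critResistant numeric(1), minimum resistant-line scores for the
#'   resistant-only category.
#' @slot critPan numeric(1), minimum score in all lines for the pan category.
#' @slot parentalLine character(1), name of the drug-responsive line.
#' @slot resistantLines character, names of the resistant lines.
#' @slot collapse character(1), replicate collapse: "mean" or "median".
#'
#' @seealso \code{\link{screenStatsConfig}}, \code{\link{callHits}}
#' @export
setClass("ScreenStatsConfig",
  representation(
    logBase = "numeric",
    pseudocount = "numeric",
    zConstant = "numeric",
    zThreshold = "numeric",
    critResponsive = "numeric",
    critResistant = "numeric",
    critPan = "numeric",
    parentalLine = "character",
    resistantLines = "character",
    collapse = "character"
  )
)

setValidity("ScreenStatsConfig", function(object) {
  msg <- character()
  crit <- c(object@critResponsive, object@critResistant, object@critPan)
  if (any(crit <= 0 | crit > 1))
    msg <- c(msg, "classification criteria must lie in (0, 1]")
  if (object@zThreshold <= 0)
    msg <- c(msg, "zThreshold must be positive")
  if (object@logBase <= 0 || object@logBase == 1)
    msg <- c(msg, "logBase must be positive and != 1")
  if (object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be non-negative")
  if (!object@collapse %in% c("mean", "median"))
    msg <- c(msg, "collapse must be 'mean' or 'median'")
  if (length(object@resistantLines) < 1L)
    msg <- c(msg, "at least one resistant line is required")
  if (length(msg)) msg else TRUE
})

#' DoseResponseMatrix: a two-drug combination grid
#'
#' Growth-inhibition fractions on a grid of dose pairs. Row \code{i},
#' column \code{j} holds the effect of \code{dosesA[i]} of agent A combined
#' with \code{dosesB[j]} of agent B; both dose vectors start at 0, so the
#' first row and column are the single-agent effect curves and
#' \code{effect[1, 1]} is the untreated anchor, 0 by definition.
#'
#' @slot dosesA ascending numeric vector of agent-A doses, starting at 0.
#' @slot dosesB ascending numeric vector of agent-B doses, starting at 0.
#' @slot effect numeric matrix of inhibition fractions in [0, 1],
#'   \code{length(dosesA)} by \code{length(dosesB)}.
#'
#' @seealso \code{\link{normalizeEffects}}, \code{\link{hsaSurplus}}
#' @export
setClass("DoseResponseMatrix",
  representation(
    dosesA = "numeric",
    dosesB = "numeric",
    effect = "matrix"
  )
)

setValidity("DoseResponseMatrix", function(object) {
  msg <- character()
  if (length(object@dosesA) < 1L || length(object@dosesB) < 1L)
    msg <- c(msg, "dose vectors must be non-empty")
  if (object@dosesA[1] != 0 || object@dosesB[1] != 0)
    msg <- c(msg, "dose vectors must start at 0 (untreated anchor)")
  if (is.unsorted(object@dosesA, strictly = TRUE) ||
      is.unsorted(object@dosesB, strictly = TRUE))
    msg <- c(msg, "dose vectors must be strictly ascending")
  if (!identical(dim(object@effect),
                 c(length(object@dosesA), length(object@dosesB))))
    msg <- c(msg, "effect matrix shape must match the dose vectors")
  else {
    if (any(object@effect < 0 | object@effect > 1))
      msg <- c(msg, "effects must lie in [0, 1]")
    if (abs(object@effect[1, 1]) > 1e-12)
      msg <- c(msg, "effect[1, 1] (untreated) must be 0")
  }
  if (length(msg)) msg else TRUE
})

#' SynergyMatrix: HSA surplus over a dose grid
#'
#' Per-dose-pair surplus of the observed combination effect over the
#' highest-single-agent (HSA) reference: positive values indicate synergy,
#' negative values antagonism. Single-agent rows/columns are their own
#' reference, so the first row and column are identically zero.
#'
#' @slot dosesA,dosesB dose vectors inherited from the input grid.
#' @slot surplus numeric matrix, same shape as the input effect matrix.
#'
#' @seealso \code{\link{hsaSurplus}}
#' @export
setClass("SynergyMatrix",
  representation(
    dosesA = "numeric",
    dosesB = "numeric",
    surplus = "matrix"
  )
)

setValidity("SynergyMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@surplus),
                 c(length(object@dosesA), length(object@dosesB))))
    msg <- c(msg, "surplus matrix shape must match the dose vectors")
  else if (max(abs(object@surplus[1, ]), abs(object@surplus[, 1])) > 1e-12)
    msg <- c(msg, "single-agent row/column surplus must be zero")
  if (length(msg)) msg else TRUE
})
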