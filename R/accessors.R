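# Constructors, accessors and show methods.

#' Construct a FieldImage
#'
#' @param hoechst,caspase numeric matrices of 16-bit intensities (same shape).
#' @param well plate-well label.
#' @param fieldIndex 1-based field index within the well.
#' @return A \linkS4class{FieldImage}.
#' @examples
#' fi <- fieldImage(matrix(0, 8, 8), matrix(0, 8, 8), well = "A01")
#' dim(hoechst(fi))
#' @export
fieldImage <- function(hoechst, caspase, well = "A01", fieldIndex = 1L) {
  new("FieldImage", hoechst = hoechst, caspase = caspase,
      well = as.character(well), fieldIndex = as.integer(fieldIndex))
}

#' @rdname fieldImage
#' @param x a \code{FieldImage}.
#' @export
setGeneric("hoechst", function(x) standardGeneric("hoechst"))

#' @rdname fieldImage
#' @export
setGeneric("caspase", function(x) standardGeneric("caspase"))

#' @rdname fieldImage
#' @export
setGeneric("well", function(x) standardGeneric("well"))

#' @rdname fieldImage
#' @export
setGeneric("fieldIndex", function(x) standardGeneric("fieldIndex"))

#' @rdname fieldImage
setMethod("hoechst", "FieldImage", function(x) x@hoechst)

#' @rdname fieldImage
setMethod("caspase", "FieldImage", function(x) x@caspase)

#' @rdname fieldImage
setMethod("well", "FieldImage", function(x) x@well)

#' @rdname fieldImage
setMethod("fieldIndex", "FieldImage", function(x) x@fieldIndex)

setMethod("show", "FieldImage", function(object) {
  cat(sprintf("FieldImage well %s field %d: %d x %d px, 2 channels (hoechst, caspase)\n",
              object@well, object@fieldIndex,
              nrow(object@hoechst), ncol(object@hoechst)))
})

#' Accessors for FieldTruth
#'
#' @param x a \linkS4class{FieldTruth}.
#' @return \code{nNuclei}: integer count; \code{nucleusCenters}: matrix of
#'   (row, col) centres; \code{apoptoticIds}: integer indices;
#'   \code{apoptoticFraction}: numeric fraction in [0, 1].
#' @name FieldTruth-accessors
NULL

#' @rdname FieldTruth-accessors
#' @export
setGeneric("nNuclei", function(x) standardGeneric("nNuclei"))

#' @rdname FieldTruth-accessors
#' @export
setGeneric("nucleusCenters", function(x) standardGeneric("nucleusCenters"))

#' @rdname FieldTruth-accessors
#' @export
setGeneric("apoptoticIds", function(x) standardGeneric("apoptoticIds"))

#' @rdname FieldTruth-accessors
#' @export
setGeneric("apoptoticFraction", function(x) standardGeneric("apoptoticFraction"))

#' @rdname FieldTruth-accessors
setMethod("nNuclei", "FieldTruth", function(x) x@nNuclei)

#' @rdname FieldTruth-accessors
setMethod("nucleusCenters", "FieldTruth", function(x) x@centers)

#' @rdname FieldTruth-accessors
setMethod("apoptoticIds", "FieldTruth", function(x) x@apoptoticIds)

#' @rdname FieldTruth-accessors
setMethod("apoptoticFraction", "FieldTruth", function(x) x@apoptoticFraction)

setMethod("show", "FieldTruth", function(object) {
  cat(sprintf("FieldTruth: %d nuclei, %d apoptotic (fraction %.3f)\n",
              object@nNuclei, length(object@apoptoticIds),
              object@apoptoticFraction))
})

#' Accessors for dose grids and synergy maps
#'
#' @param x a \linkS4class{DoseResponseMatrix} or \linkS4class{SynergyMatrix}.
#' @return \code{dosesA}/\code{dosesB}: numeric dose vectors;
#'   \code{effect}: inhibition-fraction matrix; \code{surplus}: HSA-surplus
#'   matrix.
#' @name dose-accessors
NULL

#' @rdname dose-accessors
#' @export
setGeneric("dosesA", function(x) standardGeneric("dosesA"))

#' @rdname dose-accessors
#' @export
setGeneric("dosesB", function(x) standardGeneric("dosesB"))

#' @rdname dose-accessors
#' @export
setGeneric("effect", function(x) standardGeneric("effect"))

#' @rdname dose-accessors
#' @export
setGeneric("surplus", function(x) standardGeneric("surplus"))

#' @rdname dose-accessors
setMethod("dosesA", "DoseResponseMatrix", function(x) x@dosesA)

#' @rdname dose-accessors
setMethod("dosesB", "DoseResponseMatrix", function(x) x@dosesB)

#' @rdname dose-accessors
setMethod("effect", "DoseResponseMatrix", function(x) x@effect)

#' @rdname dose-accessors
setMethod("dosesA", "SynergyMatrix", function(x) x@dosesA)

#' @rdname dose-accessors
setMethod("dosesB", "SynergyMatrix", function(x) x@dosesB)

#' @rdname dose-accessors
setMethod("surplus", "SynergyMatrix", function(x) x@surplus)

setMethod("show", "DoseResponseMatrix", function(object) {
  cat(sprintf("DoseResponseMatrix: %d x %d dose grid, effects in [%.3f, %.3f]\n",
              length(object@dosesA), length(object@dosesB),
              min(object@effect), max(object@effect)))
})

setMethod("show", "SynergyMatrix", function(object) {
  cat(sprintf("SynergyMatrix (HSA): %d x %d grid, max surplus %.3f, min %.3f\n",
              length(object@dosesA), length(object@dosesB),
              max(object@surplus), min(object@surplus)))
})

setMethod("show", "ScreenScenario", function(object) {
  cat(sprintf("ScreenScenario: %d inhibitors x %d lines x %d replicates, noise SD %.3g\n",
              object@nInhibitors, length(object@baseline),
              object@nReplicates, object@noiseSd))
  if (nrow(object@planted)) {
    tb <- table(object@planted$category)
    cat("  planted hits:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  } else cat("  no planted hits\n")
})

setMethod("show", "ScreenStatsConfig", function(object) {
  cat(sprintf(paste0(
    "ScreenStatsConfig: log base %g (pseudocount %g), |RZ| >= %g ",
    "(constant %.4f)\n  criteria: responsive >= %.2f, resistant >= %.2f, ",
    "pan >= %.2f; lines: %s vs %s\n"),
    object@logBase, object@pseudocount, object@zThreshold, object@zConstant,
    object@critResponsive, object@critResistant, object@critPan,
    object@parentalLine, paste(object@resistantLines, collapse = "/")))
})
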