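# Highest-single-agent (HSA) synergy scoring of two-drug dose grids.

#' Normalise raw viability readings to growth-inhibition fractions
#'
#' Inhibition is defined relative to the untreated control:
#' \code{effect = 1 - raw / control}, clamped to [0, 1]. Readings above the
#' control (apparent growth stimulation) clamp to 0 with a message. The
#' untreated anchor \code{effect[1, 1]} is 0 by construction when
#' \code{control} is the untreated reading (the default).
#'
#' @param raw numeric matrix of viability readings (e.g. SRB absorbance),
#'   rows indexed by agent-A dose, columns by agent-B dose, dose 0 first.
#' @param dosesA,dosesB ascending dose vectors starting at 0.
#' @param control untreated reading; defaults to \code{raw[1, 1]}.
#' @return A \linkS4class{DoseResponseMatrix}.
#' @examples
#' raw <- matrix(c(1, 0.8, 0.9, 0.5), 2, 2)
#' normalizeEffects(raw, c(0, 1), c(0, 1))
#' @export
normalizeEffects <- function(raw, dosesA, dosesB, control = raw[1, 1]) {
  stopifnot(is.matrix(raw))
  if (control <= 0) stop("untreated control reading must be positive")
  eff <- 1 - raw / control
  if (any(eff < 0))
    message(sprintf("%d reading(s) above control clamped to 0 inhibition",
                    sum(eff < 0)))
  eff <- pmin(pmax(eff, 0), 1)
  eff[1, 1] <- 0
  new("DoseResponseMatrix", dosesA = as.numeric(dosesA),
      dosesB = as.numeric(dosesB), effect = eff)
}

#' HSA synergy surplus of a dose grid
#'
#' Under the highest-single-agent reference the expected combination effect
#' at dose pair (i, j) is the larger of the two single-agent effects,
#' \code{max(effect[i, 1], effect[1, j])}; the surplus is the observed
#' effect minus that reference. Positive surplus indicates synergy,
#' negative antagonism; single-agent rows and columns are their own
#' reference and score exactly zero.
#'
#' @param dr a \linkS4class{DoseResponseMatrix}, or a list of replicate
#'   matrices on the same dose grid, which are averaged before scoring
#'   (for this linear operator, averaging then scoring equals scoring then
#'   averaging).
#' @return A \linkS4class{SynergyMatrix}.
#' @examples
#' g <- genDoseResponse(c(0, 1, 2), c(0, 1, 2))
#' max(abs(surplus(hsaSurplus(g$dr))))  # 0: additive surface
#' @export
hsaSurplus <- function(dr) {
  if (is.list(dr)) dr <- averageReplicates(dr)
  stopifnot(is(dr, "DoseResponseMatrix"))
  validObject(dr)
  eff <- dr@effect
  ref <- outer(eff[, 1], eff[1, ], pmax)
  new("SynergyMatrix", dosesA = dr@dosesA, dosesB = dr@dosesB,
      surplus = eff - ref)
}

#' Average replicate dose-response matrices
#'
#' Replicates must share the dose grid; the mean effect matrix is returned
#' with the per-cell standard error attached as attribute \code{"se"}.
#'
#' @param drs list of \linkS4class{DoseResponseMatrix} replicates.
#' @return A \linkS4class{DoseResponseMatrix}.
#' @export
averageReplicates <- function(drs) {
  stopifnot(length(drs) >= 1,
            all(vapply(drs, is, logical(1), "DoseResponseMatrix")))
  d1 <- drs[[1]]
  same <- vapply(drs, function(d)
    identical(d@dosesA, d1@dosesA) && identical(d@dosesB, d1@dosesB),
    logical(1))
  if (!all(same)) stop("replicates must share the same dose grid")
  arr <- simplify2array(lapply(drs, slot, "effect"))
  m <- apply(arr, c(1, 2), mean)
  se <- if (length(drs) > 1)
    apply(arr, c(1, 2), function(v) sd(v) / sqrt(length(v)))
  else matrix(NA_real_, nrow(m), ncol(m))
  out <- new("DoseResponseMatrix", dosesA = d1@dosesA, dosesB = d1@dosesB,
             effect = m)
  attr(out, "se") <- se
  out
}
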