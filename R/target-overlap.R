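# Direct-target nomination: intersect differentially expressed genes with
# the union of predicted and validated miR target databases.

#' Build the union of target databases with per-gene provenance
#'
#' Gene symbols are case-normalised (upper case) and deduplicated within
#' each source; the union records, for every gene, the set of evidence
#' sources supporting it (predicted databases such as miRDB/TargetScan,
#' validated sources such as AGO-PAR-CLIP or miRTarBase -- the label set is
#' open).
#'
#' @param sourceLists named list, one character vector of gene symbols per
#'   evidence source.
#' @return named list mapping gene symbol to the character vector of
#'   sources containing it; empty input gives an empty union.
#' @examples
#' buildTargetUnion(list(A = c("g1", "g2"), B = "G2"))
#' @export
buildTargetUnion <- function(sourceLists) {
  if (length(sourceLists) == 0) return(setNames(list(), character(0)))
  if (is.null(names(sourceLists)) || any(!nzchar(names(sourceLists))))
    stop("every source list must be named")
  pairs <- do.call(rbind, lapply(names(sourceLists), function(s) {
    g <- unique(toupper(sourceLists[[s]]))
    if (!length(g)) return(NULL)
    data.frame(gene = g, source = s, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) return(setNames(list(), character(0)))
  split(pairs$source, pairs$gene)
}

#' Nominate candidate direct miR targets
#'
#' A gene is a candidate direct target when it is differentially expressed
#' below the p-value threshold (strict inequality, so a gene exactly at
#' the threshold is excluded) \emph{and} present in the target union. The
#' direction of change is carried through but not filtered on: genuine
#' direct targets may move in either direction in vivo. Matching is by
#' exact case-insensitive symbol; no alias resolution is attempted.
#'
#' @param degs data.frame with columns \code{gene}, \code{log2fc},
#'   \code{pvalue} and optionally \code{fdr}.
#' @param targetUnion union from \code{\link{buildTargetUnion}}.
#' @param pThreshold significance threshold in (0, 1), default 0.05.
#' @param useColumn which DEG column to threshold: \code{"pvalue"}
#'   (default) or \code{"fdr"}.
#' @return data.frame of candidates sorted by ascending p-value: the DEG
#'   columns plus a semicolon-joined \code{sources} column; zero rows when
#'   nothing intersects.
#' @examples
#' fx <- genTargetsAndDegs(nGenes = 200, nTargets = 50,
#'                         nPlantedDirect = 3, nSigDegs = 10, seed = 1)
#' un <- buildTargetUnion(fx$sources)
#' candidateDirectTargets(fx$degs, un)$gene
#' @export
candidateDirectTargets <- function(degs, targetUnion, pThreshold = 0.05,
                                   useColumn = c("pvalue", "fdr")) {
  stopifnot(pThreshold > 0, pThreshold < 1,
            all(c("gene", "pvalue") %in% colnames(degs)))
  useColumn <- match.arg(useColumn)
  if (useColumn == "fdr" && !"fdr" %in% colnames(degs))
    stop("degs has no fdr column")
  stat <- degs[[useColumn]]
  keep <- !is.na(stat) & stat < pThreshold &
    toupper(degs$gene) %in% names(targetUnion)
  out <- degs[keep, , drop = FALSE]
  out$sources <- vapply(toupper(out$gene), function(g)
    paste(targetUnion[[g]], collapse = ";"), character(1))
  out <- out[order(out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
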