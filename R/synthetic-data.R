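# Seeded synthetic-data generators with recorded ground truth.
#
# Every generator is a pure function of (parameters, seed): the RNG state
# of the caller is saved and restored, and a per-generator stream is derived
# from the single user seed so partial re-runs stay reproducible.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic sub-stream seed, kept below 2^31 (R integers are 32-bit).
splitSeed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) %% 65521) * 32749 + stream * 7919 + 1) %%
    2147483629L
}

# ---------------------------------------------------------------------------
# microscopy fields

#' Generate a synthetic two-channel microscope field with known truth
#'
#' Emulates one field of the screen's high-content readout: the Hoechst
#' channel shows one bright Gaussian-profiled disc per nucleus over a dark,
#' noisy background; the caspase-3/7 reporter channel carries elevated
#' signal in the nuclear regions of the nuclei designated apoptotic, and
#' background elsewhere. The exact placement and apoptotic assignment are
#' returned as a \linkS4class{FieldTruth}, so segmentation and scoring can
#' be checked against ground truth.
#'
#' Nuclei are placed by rejection sampling with a minimum pairwise
#' centre separation (default \code{2 * radius + 4} px), so they do not
#' overlap; if the requested density cannot be placed within a bounded
#' number of retries the generator fails rather than silently packing
#' nuclei closer.
#'
#' @param nNuclei number of nuclei to place (>= 0).
#' @param apoptoticFraction fraction of nuclei rendered caspase-positive;
#'   the realised count is \code{round(nNuclei * apoptoticFraction)}.
#' @param seed integer seed; identical (parameters, seed) give bit-identical
#'   images.
#' @param imageShape integer(2), image size in pixels (rows, cols).
#' @param radius mean nucleus radius in pixels.
#' @param radiusJitter relative SD of per-nucleus radius variation.
#' @param minSeparation minimum centre-to-centre distance in pixels;
#'   default \code{2 * radius + 4}.
#' @param bgLevel background intensity (16-bit scale) of both channels.
#' @param noiseSd SD of additive Gaussian read noise.
#' @param nucleusAmp peak Hoechst amplitude of a nucleus above background.
#' @param caspaseAmp peak caspase amplitude of an apoptotic nucleus.
#' @param well,fieldIndex labels stored on the returned image.
#' @return A list with elements \code{image} (\linkS4class{FieldImage}) and
#'   \code{truth} (\linkS4class{FieldTruth}).
#' @examples
#' f <- genFieldImage(nNuclei = 30, apoptoticFraction = 0.2, seed = 1)
#' f$truth
#' @export
genFieldImage <- function(nNuclei, apoptoticFraction = 0, seed = 1L,
                          imageShape = c(512L, 512L), radius = 5,
                          radiusJitter = 0.1, minSeparation = 2 * radius + 4,
                          bgLevel = 1000, noiseSd = 150,
                          nucleusAmp = 30000, caspaseAmp = 30000,
                          well = "A01", fieldIndex = 1L) {
  stopifnot(nNuclei >= 0, apoptoticFraction >= 0, apoptoticFraction <= 1,
            length(imageShape) == 2, all(imageShape >= 1))
  nr <- as.integer(imageShape[1]); nc <- as.integer(imageShape[2])
  withSeed(splitSeed(seed, 1L), {
    margin <- ceiling(radius * (1 + 3 * radiusJitter)) + 2
    if (nNuclei > 0 && (nr <= 2 * margin || nc <= 2 * margin))
      stop("image too small to place nuclei at the requested radius")

    centers <- matrix(numeric(0), ncol = 2,
                      dimnames = list(NULL, c("row", "col")))
    if (nNuclei > 0) {
      placed <- matrix(NA_real_, nrow = nNuclei, ncol = 2)
      nPlaced <- 0L
      tries <- 0L
      maxTries <- max(2000L, 400L * nNuclei)
      while (nPlaced < nNuclei && tries < maxTries) {
        tries <- tries + 1L
        cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
        ok <- nPlaced == 0L ||
          min(sqrt((placed[seq_len(nPlaced), 1] - cand[1])^2 +
                   (placed[seq_len(nPlaced), 2] - cand[2])^2)) >= minSeparation
        if (ok) {
          nPlaced <- nPlaced + 1L
          placed[nPlaced, ] <- cand
        }
      }
      if (nPlaced < nNuclei)
        stop(sprintf(
          "cannot place %d nuclei with separation %.1f px in a %d x %d field",
          nNuclei, minSeparation, nr, nc))
      centers <- placed
      colnames(centers) <- c("row", "col")
    }

    radii <- if (nNuclei > 0)
      pmax(2, radius * (1 + radiusJitter * rnorm(nNuclei))) else numeric(0)

    nApo <- round(nNuclei * apoptoticFraction)
    apoIds <- if (nApo > 0) sort(sample.int(nNuclei, nApo)) else integer(0)

    hoechst <- matrix(rnorm(nr * nc, bgLevel, noiseSd), nr, nc)
    casp <- matrix(rnorm(nr * nc, bgLevel, noiseSd), nr, nc)
    for (i in seq_len(nNuclei)) {
      sig <- radii[i] / 2
      ext <- ceiling(3 * sig)
      r0 <- max(1L, floor(centers[i, 1]) - ext)
      r1 <- min(nr, ceiling(centers[i, 1]) + ext)
      c0 <- max(1L, floor(centers[i, 2]) - ext)
      c1 <- min(nc, ceiling(centers[i, 2]) + ext)
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+")
      blob <- exp(-d2 / (2 * sig^2))
      hoechst[rr, cc] <- hoechst[rr, cc] + nucleusAmp * blob
      if (i %in% apoIds)
        casp[rr, cc] <- casp[rr, cc] + caspaseAmp * blob
    }
    clamp16 <- function(m) round(pmin(pmax(m, 0), 65535))
    list(
      image = fieldImage(clamp16(hoechst), clamp16(casp),
                         well = well, fieldIndex = fieldIndex),
      truth = new("FieldTruth", nNuclei = as.integer(nNuclei),
                  centers = centers, radii = radii,
                  apoptoticIds = apoIds,
                  apoptoticFraction = if (nNuclei > 0)
                    length(apoIds) / nNuclei else 0)
    )
  })
}

# ---------------------------------------------------------------------------
# screen tables

#' Default planted-hit table mirroring the screen's category counts
#'
#' Four responsive-only, nine resistant-only and thirteen pan hits (26 in
#' total), assigned to evenly spaced inhibitor ids. Effect scores sit well
#' clear of the classification criteria: responsive-only hits at parental
#' score 0.15 (criterion 0.10), resistant-only at 0.30 in both resistant
#' lines (criterion 0.20), pan at 0.60 in all lines (criterion 0.50).
#'
#' @param nInhibitors library size the ids are drawn from.
#' @param lines cell-line names (parental first).
#' @return data.frame suitable for the \code{planted} slot of
#'   \linkS4class{ScreenScenario}.
#' @export
defaultPlantedHits <- function(nInhibitors = 954L,
                               lines = c("MCF7", "TamR", "LTED")) {
  counts <- c(responsive_only = 4L, resistant_only = 9L, pan = 13L)
  nHits <- sum(counts)
  stopifnot(nInhibitors >= nHits)
  ids <- sprintf("miR-%04d", round(seq(1, nInhibitors, length.out = nHits)))
  cat3 <- rep(names(counts), counts)
  scores <- rbind(
    responsive_only = c(0.15, 0.05, 0.05),
    resistant_only  = c(0.05, 0.30, 0.30),
    pan             = c(0.60, 0.60, 0.60))
  colnames(scores) <- lines
  out <- data.frame(inhibitor_id = ids, category = cat3,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores[cat3, , drop = FALSE], row.names = FALSE))
}

#' Construct a ScreenScenario
#'
#' The defaults reproduce the screened study conditions: a 954-inhibitor
#' library in MCF7, TamR and LTED in biological triplicate, with the
#' \code{\link{defaultPlantedHits}} table planted. Baseline (non-hit)
#' apoptotic scores default to 0.05 in parental MCF7 and 0.07 in the
#' resistant derivatives, giving the mildly positive bulk log fold change
#' the screen statistic centres on.
#'
#' @param nInhibitors library size.
#' @param baseline named numeric of per-line non-hit mean scores.
#' @param noiseSd replicate Gaussian noise SD (apoptotic-score units).
#' @param nReplicates biological replicates.
#' @param planted planted-hit data.frame (possibly 0-row); see
#'   \code{\link{defaultPlantedHits}}.
#' @return A validated \linkS4class{ScreenScenario}.
#' @examples
#' screenScenario(noiseSd = 0)
#' @export
screenScenario <- function(nInhibitors = 954L,
                           baseline = c(MCF7 = 0.05, TamR = 0.07, LTED = 0.07),
                           noiseSd = 0.02, nReplicates = 3L,
                           planted = defaultPlantedHits(nInhibitors,
                                                        names(baseline))) {
  new("ScreenScenario", nInhibitors = as.integer(nInhibitors),
      baseline = baseline, noiseSd = noiseSd,
      nReplicates = as.integer(nReplicates), planted = planted)
}

#' Simulate a full screen score table
#'
#' One row per (inhibitor, cell line, replicate) with apoptotic score equal
#' to the planted effect (for planted hits) or the per-line baseline, plus
#' Gaussian replicate noise, clamped to [0, 1]. Control wells (mock,
#' negative-control inhibitor, and a cell-death positive control at score
#' 0.9) are appended with \code{role} labels so plate-map handling stays
#' honest; they are excluded from hit calling.
#'
#' @param scenario a \linkS4class{ScreenScenario}.
#' @param seed integer seed; the layout is seed-independent, only the noise
#'   draws change.
#' @return A list with \code{scores} (data.frame: well, cell_line,
#'   inhibitor_id, role, replicate, apoptotic_score) and \code{truth}
#'   (data.frame: inhibitor_id, category -- \code{"none"} for non-hits).
#' @export
genScreenTable <- function(scenario = screenScenario(), seed = 1L) {
  validObject(scenario)
  lines <- names(scenario@baseline)
  ids <- sprintf("miR-%04d", seq_len(scenario@nInhibitors))
  planted <- scenario@planted

  # truth map over the whole library
  truth <- data.frame(inhibitor_id = ids, category = "none",
                      stringsAsFactors = FALSE)
  if (nrow(planted)) {
    if (!all(planted$inhibitor_id %in% ids))
      stop("planted inhibitor ids must belong to the library")
    truth$category[match(planted$inhibitor_id, ids)] <- planted$category
  }

  grid <- expand.grid(replicate = seq_len(scenario@nReplicates),
                      cell_line = lines, inhibitor_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- scenario@baseline[grid$cell_line]
  if (nrow(planted)) {
    hit <- match(grid$inhibitor_id, planted$inhibitor_id)
    has <- !is.na(hit)
    mu[has] <- as.matrix(planted[, lines])[cbind(hit[has],
                                                 match(grid$cell_line[has],
                                                       lines))]
  }

  ctrl <- expand.grid(replicate = seq_len(scenario@nReplicates),
                      cell_line = lines,
                      inhibitor_id = c("mock", "neg_ctrl", "death_ctrl"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ctrlMu <- ifelse(ctrl$inhibitor_id == "death_ctrl", 0.9,
                   scenario@baseline[ctrl$cell_line])

  all <- rbind(grid, ctrl)
  allMu <- c(mu, ctrlMu)
  role <- c(rep("sample", nrow(grid)),
            c(mock = "mock", neg_ctrl = "neg_ctrl",
              death_ctrl = "death_ctrl")[ctrl$inhibitor_id])

  score <- withSeed(splitSeed(seed, 2L),
                    allMu + rnorm(nrow(all), 0, scenario@noiseSd))
  scores <- data.frame(
    well = sprintf("%s_r%d_%s", all$cell_line, all$replicate,
                   all$inhibitor_id),
    cell_line = all$cell_line,
    inhibitor_id = all$inhibitor_id,
    role = unname(role),
    replicate = all$replicate,
    apoptotic_score = pmin(pmax(score, 0), 1),
    stringsAsFactors = FALSE)
  list(scores = scores, truth = truth)
}

# ---------------------------------------------------------------------------
# DEG / target fixtures

#' Simulate a DEG table and miR target databases with planted direct targets
#'
#' Builds the inputs of the direct-target intersection: a differential
#' expression table and per-source target gene lists (two predicted-style
#' and two validated-style sources), constructed so that \emph{exactly} the
#' planted genes are both significant (p below \code{sigP}) and present in
#' the target union. All other target genes receive p-values at or above
#' \code{sigP}; additional non-target genes are made significant to reach
#' \code{nSigDegs} significant rows in total.
#'
#' @param nGenes total genes in the DEG table.
#' @param nTargets genes in the target-database union (default 1075).
#' @param nPlantedDirect planted direct targets (default 9).
#' @param nSigDegs total significant DEGs (default 194).
#' @param sigP significance cut-off used in the construction (default 0.05).
#' @param seed integer seed.
#' @return A list: \code{degs} (data.frame gene, log2fc, pvalue, fdr),
#'   \code{sources} (named list of per-source gene vectors), \code{truth}
#'   (character vector of planted direct-target genes).
#' @export
genTargetsAndDegs <- function(nGenes = 5000L, nTargets = 1075L,
                              nPlantedDirect = 9L, nSigDegs = 194L,
                              sigP = 0.05, seed = 1L) {
  stopifnot(nTargets <= nGenes, nPlantedDirect <= nTargets,
            nPlantedDirect <= nSigDegs)
  if (nSigDegs - nPlantedDirect > nGenes - nTargets)
    stop("infeasible counts: not enough non-target genes to reach nSigDegs")
  withSeed(splitSeed(seed, 3L), {
    genes <- sprintf("GENE%05d", seq_len(nGenes))
    targets <- sort(sample(genes, nTargets))
    planted <- sort(sample(targets, nPlantedDirect))

    srcNames <- c("miRDB", "TargetScan", "AGO-PAR-CLIP", "miRTarBase")
    nSrc <- sample(1:3, nTargets, replace = TRUE,
                   prob = c(0.6, 0.3, 0.1))
    sources <- setNames(vector("list", 4), srcNames)
    memb <- lapply(seq_len(nTargets),
                   function(i) sample(srcNames, nSrc[i]))
    # planted genes get >= 1 source already; ensure >= 2 sources represented
    for (s in srcNames)
      sources[[s]] <- targets[vapply(memb, function(m) s %in% m, logical(1))]
    sources <- sources[vapply(sources, length, integer(1)) > 0]

    p <- runif(nGenes, sigP, 1)                      # default: not significant
    names(p) <- genes
    p[planted] <- runif(nPlantedDirect, 1e-6, sigP * 0.8)
    nonTarget <- setdiff(genes, targets)
    extraSig <- sample(nonTarget, nSigDegs - nPlantedDirect)
    p[extraSig] <- runif(length(extraSig), 1e-6, sigP * 0.999)

    lfc <- rnorm(nGenes, 0, 0.5)
    sig <- c(planted, extraSig)
    # planted targets carry both directions of change (de-repression and
    # secondary loss), larger in magnitude than the bulk
    lfc[match(sig, genes)] <- sample(c(-1, 1), length(sig), replace = TRUE) *
      runif(length(sig), 0.8, 2.5)

    degs <- data.frame(gene = genes, log2fc = lfc, pvalue = unname(p),
                       fdr = p.adjust(p, "BH"), stringsAsFactors = FALSE)
    list(degs = degs, sources = sources, truth = planted)
  })
}

# ---------------------------------------------------------------------------
# dose-response surfaces

#' Simulate a two-drug dose-response surface with known synergy surplus
#'
#' Single-agent inhibition curves are supplied (monotone, in [0, 1],
#' starting at 0 for dose 0); the combination effect at each dose pair is
#' the highest-single-agent reference \code{max(effectA[i], effectB[j])}
#' plus any planted surplus, clamped to [0, 1]. Under the pure
#' \code{"additive"} model the surplus is identically zero, so downstream
#' HSA scoring must return an all-zero map.
#'
#' @param dosesA,dosesB ascending dose vectors starting at 0.
#' @param effectA,effectB single-agent inhibition fractions, one per dose,
#'   monotone non-decreasing from 0.
#' @param surplus either \code{NULL}/0 (additive surface) or a matrix of
#'   planted surplus values with shape (length(dosesA), length(dosesB)) and
#'   zero first row/column.
#' @param noiseSd optional Gaussian measurement noise SD (default 0).
#' @param seed integer seed (used only when \code{noiseSd > 0}).
#' @return A list: \code{dr} (\linkS4class{DoseResponseMatrix}) and
#'   \code{truth} (the planted surplus matrix).
#' @export
genDoseResponse <- function(dosesA, dosesB,
                            effectA = seq(0, 0.6, length.out = length(dosesA)),
                            effectB = seq(0, 0.5, length.out = length(dosesB)),
                            surplus = NULL, noiseSd = 0, seed = 1L) {
  if (length(dosesA) == 0 || length(dosesB) == 0)
    stop("dose vectors must be non-empty")
  stopifnot(length(effectA) == length(dosesA),
            length(effectB) == length(dosesB))
  if (effectA[1] != 0 || effectB[1] != 0)
    stop("single-agent curves must start at 0 inhibition for dose 0")
  if (is.unsorted(effectA) || is.unsorted(effectB))
    stop("single-agent curves must be monotone non-decreasing")
  if (any(effectA < 0 | effectA > 1) || any(effectB < 0 | effectB > 1))
    stop("single-agent effects must lie in [0, 1]")

  ref <- outer(effectA, effectB, pmax)
  if (is.null(surplus)) surplus <- matrix(0, nrow(ref), ncol(ref))
  stopifnot(identical(dim(surplus), dim(ref)))
  if (max(abs(surplus[1, ]), abs(surplus[, 1])) > 0)
    stop("planted surplus must be zero in single-agent rows/columns")

  eff <- ref + surplus
  if (noiseSd > 0) {
    noise <- withSeed(splitSeed(seed, 4L),
                      matrix(rnorm(length(eff), 0, noiseSd),
                             nrow(eff), ncol(eff)))
    noise[1, 1] <- 0
    eff <- eff + noise
  }
  eff <- pmin(pmax(eff, 0), 1)
  dr <- new("DoseResponseMatrix", dosesA = as.numeric(dosesA),
            dosesB = as.numeric(dosesB), effect = eff)
  list(dr = dr, truth = surplus)
}
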