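# Segmentation, apoptotic calling, field scoring, well aggregation.

test_that("segmentation recovers generated nuclei and their centroids", {
  f <- genFieldImage(nNuclei = 50, apoptoticFraction = 0.2, seed = 21)
  nuc <- segmentNuclei(f$image)
  expect_equal(nrow(nuc), 50)

  # each detected centroid lies within 2 px of a distinct truth centre
  ctr <- nucleusCenters(f$truth)
  d <- sqrt(outer(nuc$centroidRow, ctr[, "row"], "-")^2 +
            outer(nuc$centroidCol, ctr[, "col"], "-")^2)
  assignment <- apply(d, 1, which.min)
  expect_false(anyDuplicated(assignment) > 0)
  expect_lt(max(d[cbind(seq_len(nrow(nuc)), assignment)]), 2)

  # background-only field: no foreground, no error
  flat <- fieldImage(matrix(500, 64, 64), matrix(500, 64, 64))
  expect_equal(nrow(segmentNuclei(flat)), 0)

  # mismatched channel shapes are rejected at construction
  expect_error(fieldImage(matrix(0, 10, 10), matrix(0, 10, 12)), "shape")
})

test_that("heavily overlapping discs merge into one object when not split", {
  hx <- matrix(0, 96, 96)
  # two discs of radius 6 with centres 4 px apart: > 50% overlap
  hx <- addBlob(hx, c(48, 46), 6, 30000)
  hx <- addBlob(hx, c(48, 50), 6, 30000)
  img <- fieldImage(round(pmin(hx, 65535)), matrix(0, 96, 96))
  nuc <- segmentNuclei(img, splitTouching = FALSE)
  expect_equal(nrow(nuc), 1)
})

test_that("apoptotic calling is thresholded, monotone and truth-faithful", {
  f <- genFieldImage(nNuclei = 100, apoptoticFraction = 0.2, seed = 5)
  nuc <- segmentNuclei(f$image)

  # strong signal separation: exactly the planted 20 are positive
  called <- callApoptotic(nuc)
  expect_equal(sum(called$isApoptotic), 20)

  # all below a huge fixed threshold: no positives
  none <- callApoptotic(nuc, threshold = 70000)
  expect_equal(sum(none$isApoptotic), 0)

  # monotonicity: raising the threshold only removes positives
  t1 <- callApoptotic(nuc, threshold = 5000)
  t2 <- callApoptotic(nuc, threshold = 20000)
  expect_true(all(which(t2$isApoptotic) %in% which(t1$isApoptotic)))

  # otsu on per-nucleus means agrees with truth at this separation
  ots <- callApoptotic(nuc, method = "otsu")
  expect_equal(sum(ots$isApoptotic), 20)

  # < 2 nuclei: otsu falls back to the fixed threshold with a warning
  expect_warning(callApoptotic(nuc[1, ], method = "otsu"), "falling back")
})

test_that("field scores are exact fractions and permutation-invariant", {
  mk <- function(apo) {
    n <- length(apo)
    data.frame(label = seq_len(n), centroidRow = rep(0, n),
               centroidCol = rep(0, n), area = rep(50L, n),
               meanCaspase = rep(0, n), isApoptotic = apo)
  }
  expect_equal(scoreField(mk(rep(FALSE, 10)))$apoptoticScore, 0)
  expect_equal(scoreField(mk(rep(TRUE, 10)))$apoptoticScore, 1)
  fs <- scoreField(mk(rep(c(TRUE, FALSE), c(20, 80))))
  expect_equal(fs$apoptoticScore, 0.20)

  apo <- rep(c(TRUE, FALSE), c(7, 13))
  expect_equal(scoreField(mk(apo)), scoreField(mk(rev(apo))))

  # empty field: undefined score, not an error
  empty <- scoreField(mk(logical(0)))
  expect_equal(empty$nCells, 0)
  expect_true(is.na(empty$apoptoticScore))

  # unset calls are an error
  expect_error(scoreField(mk(NA)), "callApoptotic")
})

test_that("well aggregation averages defined fields and flags empty wells", {
  pr <- list(well = "B02", cell_line = "MCF7", inhibitor_id = "miR-0001",
             role = "sample", replicate = 1L)
  fs <- function(score, n = 100L)
    data.frame(nCells = ifelse(is.na(score), 0L, n),
               nApoptotic = ifelse(is.na(score), 0L, as.integer(score * n)),
               apoptoticScore = score)

  expect_equal(aggregateWell(fs(rep(0.2, 5)), pr)$apoptotic_score, 0.2)
  expect_equal(aggregateWell(fs(c(0, 1)), pr)$apoptotic_score, 0.5)
  expect_equal(aggregateWell(fs(c(0.1, 0.3, NA)), pr)$apoptotic_score, 0.2)
  expect_warning(w <- aggregateWell(fs(c(NA, NA)), pr), "flagged missing")
  expect_true(is.na(w$apoptotic_score))

  # pooled-cell alternative weights fields by their cell counts
  two <- rbind(fs(0.0, 100L), fs(1.0, 300L))
  expect_equal(aggregateWell(two, pr, poolCells = TRUE)$apoptotic_score, 0.75)
})

test_that("fields round-trip through 16-bit TIFF channel files", {
  f <- genFieldImage(nNuclei = 10, apoptoticFraction = 0.5, seed = 2,
                     imageShape = c(96L, 96L), well = "C03", fieldIndex = 2L)
  dir <- withr::local_tempdir()
  writeFieldImage(f$image, dir)
  expect_true(file.exists(file.path(dir, "C03_f2_hoechst.tif")))
  back <- readFieldImage(dir, "C03", 2L)
  expect_equal(hoechst(back), hoechst(f$image))
  expect_equal(caspase(back), caspase(f$image))

  # end-to-end: quantified well score matches the generated truth
  ws <- quantifyWell(list(f$image),
                     list(well = "C03", cell_line = "MCF7",
                          inhibitor_id = "miR-0001", role = "sample",
                          replicate = 1L))
  expect_equal(ws$apoptotic_score, 0.5)
})
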