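# The screen statistic: LFC, robust Z, significance, classification.

test_that("LFC follows the log-ratio formula with pseudocount guard", {
  cfg0 <- screenStatsConfig(pseudocount = 0)
  expect_equal(computeLfc(0.3, 0.3, cfg0), 0)
  expect_equal(computeLfc(0.5, 0.25, cfg0), 1)
  expect_equal(computeLfc(0.25, 0.5, cfg0), -1)

  # zero parental score with pseudocount 0 names the offender
  expect_error(computeLfc(c(0.2, 0.3), c(0.4, 0), cfg0,
                          ids = c("miR-0001", "miR-0002")),
               "miR-0002")
  # the default pseudocount makes the same input finite
  expect_true(is.finite(computeLfc(0.3, 0, screenStatsConfig())))
})

test_that("robust Z-scores implement median/MAD with the 0.6745 constant", {
  # centre maps to zero; symmetric vector scales by the constant
  r <- robustZScores(c(-2, -1, 0, 1, 2))
  expect_equal(r$xMedian, 0)
  expect_equal(r$mad, 1)
  expect_equal(r$rz, 0.6745 * c(-2, -1, 0, 1, 2))
  expect_equal(r$rz[3], 0)

  # degenerate spread: MAD 0, scores undefined but reported
  expect_warning(rc <- robustZScores(rep(1.3, 5)), "MAD is 0")
  expect_true(all(is.na(rc$rz)))
  expect_warning(r01 <- robustZScores(c(0, 0, 0, 0, 1)), "MAD is 0")
  expect_equal(r01$xMedian, 0)
  expect_equal(r01$mad, 0)

  expect_error(robustZScores(numeric(0)), "empty")
  expect_error(robustZScores(1), "at least 2")
})

test_that("robust Z-scores match the brute-force oracle and are affine-invariant", {
  set.seed(101)
  for (i in 1:50) {
    x <- rnorm(sample(3:50, 1), sd = runif(1, 0.1, 5))
    got <- robustZScores(x)
    want <- bruteRobustZ(x)
    expect_equal(got$rz, want$rz, tolerance = 1e-12)
    # positive affine transforms leave the scores unchanged
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(robustZScores(a * x + b)$rz, got$rz, tolerance = 1e-10)
  }
})

test_that("significance p-value is the normal tail and decreases in z", {
  expect_equal(significancePValue(0), 0.5)
  expect_equal(round(significancePValue(1), 4), 0.1587)
  expect_equal(significancePValue(1), simpsonNormalTail(1), tolerance = 1e-8)
  zs <- seq(0, 4, by = 0.25)
  expect_true(all(diff(significancePValue(zs)) < 0))
})

test_that("phenotype classification follows the three criteria in priority order", {
  expect_equal(classifyCategory(0.6, 0.6, 0.6), "pan")
  expect_equal(classifyCategory(0.05, 0.25, 0.25), "resistant_only")
  expect_equal(classifyCategory(0.12, 0.05, 0.05), "responsive_only")
  expect_equal(classifyCategory(0.05, 0.05, 0.05), "none")
  # meets the resistant criterion but with high parental: not "only"
  expect_equal(classifyCategory(0.3, 0.3, 0.3), "none")
  # pan outranks resistant_only when both nominally apply
  expect_equal(classifyCategory(0.5, 0.6, 0.6), "pan")
  # boundary: criteria are inclusive
  expect_equal(classifyCategory(0.10, 0.05, 0.05), "responsive_only")
})

test_that("callHits excludes controls, collapses replicates and sorts by |RZ|", {
  tbl <- genScreenTable(screenScenario(noiseSd = 0.03), seed = 4)
  hits <- callHits(tbl$scores)
  expect_equal(nrow(hits), 954)
  expect_false(any(c("mock", "neg_ctrl", "death_ctrl") %in%
                   hits$inhibitor_id))
  a <- abs(hits$rz_score)
  expect_true(all(diff(a[!is.na(a)]) <= 1e-12))
  md <- S4Vectors::metadata(hits)
  expect_true(is.numeric(md$xMedian) && is.numeric(md$mad))
  expect_identical(hits$significant, !is.na(hits$rz_score) &
                     abs(hits$rz_score) >= 2.5)

  # an inhibitor missing a cell line is excluded with a warning
  drop <- tbl$scores[!(tbl$scores$inhibitor_id == "miR-0100" &
                       tbl$scores$cell_line == "LTED"), ]
  expect_warning(h2 <- callHits(drop), "miR-0100")
  expect_equal(nrow(h2), 953)
})

test_that("hit statistics are invariant to the log-base choice", {
  tbl <- genScreenTable(screenScenario(noiseSd = 0.03), seed = 8)
  byId <- function(h) h[order(h$inhibitor_id), ]
  h2 <- byId(callHits(tbl$scores, screenStatsConfig(logBase = 2)))
  h10 <- byId(callHits(tbl$scores, screenStatsConfig(logBase = 10)))
  he <- byId(callHits(tbl$scores, screenStatsConfig(logBase = exp(1))))
  expect_equal(h2$rz_score, h10$rz_score, tolerance = 1e-12)
  expect_equal(h2$rz_score, he$rz_score, tolerance = 1e-12)
  expect_identical(h2$significant, h10$significant)
  # the LFC column itself rescales by log(10)/log(2)
  expect_equal(h2$lfc, h10$lfc * log2(10), tolerance = 1e-12)
})

test_that("zero-hit noiseless screens produce no categories and no MAD", {
  sc <- screenScenario(noiseSd = 0, planted = defaultPlantedHits()[0, ])
  tbl <- genScreenTable(sc, seed = 1)
  expect_warning(hits <- callHits(tbl$scores), "MAD is 0")
  expect_true(all(hits$category == "none"))
  expect_false(any(hits$significant))
})
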