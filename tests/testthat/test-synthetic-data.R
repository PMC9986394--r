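# Generators: determinism, truth bookkeeping, boundary behaviour.

test_that("field generator honours counts, bounds and determinism", {
  # empty case: pure background, zero-nucleus truth
  f0 <- genFieldImage(nNuclei = 0, seed = 3, imageShape = c(64L, 64L))
  expect_identical(nNuclei(f0$truth), 0L)
  expect_identical(dim(hoechst(f0$image)), c(64L, 64L))

  # forced apoptotic count and placement inside bounds
  f <- genFieldImage(nNuclei = 100, apoptoticFraction = 0.2, seed = 7)
  expect_length(apoptoticIds(f$truth), 20L)
  ctr <- nucleusCenters(f$truth)
  expect_true(all(ctr[, "row"] >= 1 & ctr[, "row"] <= 512))
  expect_true(all(ctr[, "col"] >= 1 & ctr[, "col"] <= 512))
  expect_equal(apoptoticFraction(f$truth), 0.2)

  # non-overlap under the min-separation rule
  d <- as.matrix(dist(ctr))
  diag(d) <- Inf
  expect_gte(min(d), 14)  # 2 * radius + 4 at default radius 5

  # bit-identical reruns; intensities are valid 16-bit
  f2 <- genFieldImage(nNuclei = 50, apoptoticFraction = 0.1, seed = 11)
  f3 <- genFieldImage(nNuclei = 50, apoptoticFraction = 0.1, seed = 11)
  expect_identical(hoechst(f2$image), hoechst(f3$image))
  expect_identical(caspase(f2$image), caspase(f3$image))
  expect_true(all(hoechst(f2$image) >= 0 & hoechst(f2$image) <= 65535))

  # impossible density fails loudly
  expect_error(
    genFieldImage(nNuclei = 500, seed = 1, imageShape = c(64L, 64L)),
    "cannot place")
})

test_that("screen table generator plants effects and keeps layout stable", {
  sc0 <- screenScenario(noiseSd = 0)
  tbl <- genScreenTable(sc0, seed = 1)
  smp <- tbl$scores[tbl$scores$role == "sample", ]
  expect_equal(nrow(smp), 954 * 3 * 3)
  expect_setequal(unique(tbl$scores$role),
                  c("sample", "mock", "neg_ctrl", "death_ctrl"))
  expect_true(all(tbl$scores$apoptotic_score >= 0 &
                  tbl$scores$apoptotic_score <= 1))

  # noiseless planted pan hit: every replicate exactly at the planted score
  panId <- sc0@planted$inhibitor_id[sc0@planted$category == "pan"][1]
  panRows <- smp[smp$inhibitor_id == panId, ]
  expect_equal(panRows$apoptotic_score, rep(0.60, 9))

  # seeds change scores, not layout
  scn <- screenScenario(noiseSd = 0.05)
  a <- genScreenTable(scn, seed = 1)$scores
  b <- genScreenTable(scn, seed = 2)$scores
  expect_identical(a[, c("well", "cell_line", "inhibitor_id", "replicate")],
                   b[, c("well", "cell_line", "inhibitor_id", "replicate")])
  expect_false(identical(a$apoptotic_score, b$apoptotic_score))
  expect_identical(genScreenTable(scn, seed = 1)$scores, a)
})

test_that("DEG/target generator plants exactly the requested direct targets", {
  fx <- genTargetsAndDegs(nGenes = 400, nTargets = 80, nPlantedDirect = 5,
                          nSigDegs = 20, seed = 2)
  expect_length(fx$truth, 5L)
  expect_gte(length(fx$sources), 2L)
  expect_equal(sum(fx$degs$pvalue < 0.05), 20)
  un <- unique(toupper(unlist(fx$sources)))
  sig <- fx$degs$gene[fx$degs$pvalue < 0.05]
  expect_setequal(intersect(sig, un), fx$truth)

  # empty planting, determinism, infeasibility
  fx0 <- genTargetsAndDegs(nGenes = 100, nTargets = 20, nPlantedDirect = 0,
                           nSigDegs = 5, seed = 2)
  expect_length(fx0$truth, 0L)
  expect_identical(genTargetsAndDegs(seed = 9), genTargetsAndDegs(seed = 9))
  expect_error(
    genTargetsAndDegs(nGenes = 50, nTargets = 45, nPlantedDirect = 2,
                      nSigDegs = 20, seed = 1),
    "infeasible")
})

test_that("dose-response generator builds HSA-null and planted surfaces", {
  # additive surface: surplus identically zero by construction
  g <- genDoseResponse(c(0, 1, 2, 3), c(0, 1, 2))
  expect_equal(max(abs(surplus(hsaSurplus(g$dr)))), 0)

  # planted surplus appears where planted and nowhere else
  pl <- matrix(0, 4, 3); pl[3, 2] <- 0.15
  gp <- genDoseResponse(c(0, 1, 2, 3), c(0, 1, 2), surplus = pl)
  s <- surplus(hsaSurplus(gp$dr))
  expect_equal(s[3, 2], 0.15)
  expect_equal(max(abs(s[-(3 + (2 - 1) * 4)])), 0)

  expect_error(genDoseResponse(numeric(0), c(0, 1)), "non-empty")
  expect_error(
    genDoseResponse(c(0, 1), c(0, 1), effectA = c(0.2, 0.1),
                    effectB = c(0, 0.1)),
    "start at 0")
})
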