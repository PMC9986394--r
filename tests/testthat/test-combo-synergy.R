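# Effect normalisation and highest-single-agent surplus.

test_that("normalisation maps viability readings to inhibition fractions", {
  dA <- c(0, 1); dB <- c(0, 1, 2)
  raw <- matrix(1, 2, 3)
  expect_equal(effect(normalizeEffects(raw, dA, dB)), matrix(0, 2, 3))

  raw2 <- matrix(c(1, 0.5, 0.8, 0, 0.9, 0.4), 2, 3)
  e <- effect(normalizeEffects(raw2, dA, dB))
  expect_equal(e[2, 2], 1)        # zero reading = complete inhibition
  expect_equal(e[1, 1], 0)        # untreated anchor

  # readings above control clamp to 0 with a note
  raw3 <- matrix(c(1, 1.2, 0.9, 0.5), 2, 2)
  expect_message(e3 <- effect(normalizeEffects(raw3, c(0, 1), c(0, 1))),
                 "clamped")
  expect_equal(e3[2, 1], 0)

  expect_error(normalizeEffects(raw, dA, dB, control = 0), "positive")
})

test_that("HSA surplus is observed effect minus the best single agent", {
  # forced arithmetic: 0.8 combination vs singles 0.5 and 0.3
  eff <- matrix(c(0, 0.3, 0.5, 0.8), 2, 2)
  dr <- new("DoseResponseMatrix", dosesA = c(0, 1), dosesB = c(0, 1),
            effect = eff)
  s <- surplus(hsaSurplus(dr))
  expect_equal(s[2, 2], 0.8 - 0.5)
  expect_equal(s[1, ], c(0, 0))
  expect_equal(s[, 1], c(0, 0))

  # surplus never exceeds the effect (reference >= 0)
  expect_true(all(s <= eff))
})

test_that("surplus is invariant to an added HSA-consistent dose column", {
  g <- genDoseResponse(c(0, 1, 2), c(0, 1, 2),
                       effectA = c(0, 0.2, 0.4), effectB = c(0, 0.1, 0.3),
                       surplus = {m <- matrix(0, 3, 3); m[2, 2] <- 0.1; m})
  s0 <- surplus(hsaSurplus(g$dr))

  # append a dose-B column whose combinations equal the HSA reference
  effB3 <- 0.5
  newCol <- pmax(c(0, 0.2, 0.4), effB3)
  eff <- cbind(effect(g$dr), newCol)
  dr2 <- new("DoseResponseMatrix", dosesA = c(0, 1, 2),
             dosesB = c(0, 1, 2, 3), effect = unname(eff))
  s2 <- surplus(hsaSurplus(dr2))
  expect_equal(s2[, 1:3], s0)
  expect_equal(s2[, 4], c(0, 0, 0))
})

test_that("averaging replicates commutes with the linear surplus operator", {
  # the surplus operator is linear in the combination cells at fixed
  # single-agent anchors, so replicates share anchors and vary interiors
  set.seed(7)
  base <- genDoseResponse(c(0, 1, 2), c(0, 1, 2),
                          effectA = c(0, 0.2, 0.4),
                          effectB = c(0, 0.1, 0.3))$dr
  mk <- function() {
    eff <- effect(base)
    eff[2:3, 2:3] <- pmin(pmax(eff[2:3, 2:3] + rnorm(4, 0, 0.05), 0), 1)
    new("DoseResponseMatrix", dosesA = dosesA(base), dosesB = dosesB(base),
        effect = eff)
  }
  reps <- replicate(4, mk(), simplify = FALSE)

  sOfMean <- surplus(hsaSurplus(averageReplicates(reps)))
  meanOfS <- Reduce(`+`, lapply(reps, function(d)
    surplus(hsaSurplus(d)))) / 4
  expect_equal(sOfMean, meanOfS, tolerance = 1e-12)

  # replicate list accepted directly, SE attached
  avg <- averageReplicates(reps)
  expect_equal(dim(attr(avg, "se")), c(3L, 3L))
  expect_equal(surplus(hsaSurplus(reps)), sOfMean)

  expect_error(averageReplicates(list(reps[[1]],
    genDoseResponse(c(0, 1), c(0, 1))$dr)), "same dose grid")
})
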