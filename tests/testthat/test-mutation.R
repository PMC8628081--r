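zero <- mutationRates(0, 0, 0, 0, 0, 0.1)

test_that("the mutation scan with all rates zero is the identity", {
  set.seed(11)
  for (i in 1:20) {
    g <- randomGenome(sample(0:40, 1))
    expect_identical(genomeToString(mutateGenome(g, zero)), genomeToString(g))
  }
})

test_that("forced point events follow the scan semantics", {
  g5 <- Genome(1:5)
  set.seed(1)
  # deletion at every position empties the genome
  allDel <- mutationRates(0, 1, 0, 0, 0, 0.1)
  expect_length(mutateGenome(g5, allDel), 0)
  # duplication at every position doubles it, each element adjacent-duplicated,
  # because fresh copies are not re-scanned within the pass
  allDup <- mutationRates(1, 0, 0, 0, 0, 0.1)
  expect_equal(as.numeric(mutateGenome(g5, allDup)),
               as.numeric(rbind(1:5, 1:5)))
  # inactivation at every position turns everything non-coding, same length
  allInact <- mutationRates(0, 0, 1, 0, 0, 0.1)
  out <- mutateGenome(Genome(c(1:3, teElement(0.5))), allInact)
  expect_equal(as.numeric(out), rep(0, 4))
})

test_that("single-element operators behave positionally", {
  g <- Genome(c(1, 2, 3))
  expect_equal(as.numeric(applySingleDuplication(g, 2)), c(1, 2, 2, 3))
  te <- teElement(0.73)
  gt <- applySingleDuplication(Genome(c(1, te, 2)), 2)
  expect_equal(as.numeric(gt), c(1, te, te, 2))  # phi copied exactly
  # duplicate then delete the copy restores the original
  dupThenDel <- as.numeric(gt)[-3]
  expect_equal(dupThenDel, c(1, te, 2))

  expect_equal(as.numeric(applyInactivation(Genome(c(1, 2)), 1)), c(0, 2))
  expect_equal(as.numeric(applyInactivation(Genome(te), 1)), 0)  # phi discarded
  expect_equal(as.numeric(applyInactivation(Genome(0), 1)), 0)
  expect_error(applyInactivation(Genome(1), 2))
})

test_that("large-scale events duplicate, delete or invert a segment", {
  g <- Genome(1:4)
  expect_equal(as.numeric(applyLargeScale(g, 1, "inversion", 4)), 4:1)
  g40 <- Genome(rep(0, 40))
  expect_length(applyLargeScale(g40, 5, "deletion", 10), 30)
  expect_length(applyLargeScale(g40, 5, "duplication", 10), 50)
  # tandem copy sits right after the template segment
  gd <- applyLargeScale(Genome(1:6), 2, "duplication", 2)
  expect_equal(as.numeric(gd), c(1, 2, 3, 2, 3, 4, 5, 6))
  # segments are truncated at the (linear) genome end
  expect_equal(as.numeric(applyLargeScale(Genome(1:4), 3, "inversion", 10)),
               c(1, 2, 4, 3))
  expect_length(applyLargeScale(Genome(1:4), 3, "deletion", 10), 2)
})

test_that("inversion conserves length and the element multiset", {
  set.seed(5)
  for (i in 1:50) {
    g <- randomGenome(sample(2:40, 1))
    pos <- sample(length(g), 1)
    out <- applyLargeScale(g, pos, "inversion", sample(length(g), 1))
    expect_length(out, length(g))
    expect_equal(sort(as.numeric(out)), sort(as.numeric(g)))
  }
})

test_that("large-scale segments average a quarter of the genome", {
  set.seed(20)
  L <- replicate(10000, drawSegmentLength(40))
  expect_true(all(L >= 1 & L <= 19))
  expect_lt(abs(mean(L) / 40 - 0.25), 0.01)
})

test_that("phi mutation steps by exactly phiStep, clamped to [0,1]", {
  near <- function(x, vals, tol = 1e-9)
    vapply(x, function(z) any(abs(z - vals) < tol), logical(1))
  forced <- mutationRates(phiMut = 1, phiStep = 0.1)
  set.seed(3)
  out <- replicate(2000, elementPhi(mutatePhi(teElement(0.5), forced)))
  expect_true(all(near(out, c(0.4, 0.6))))
  expect_lt(abs(mean(out) - 0.5), 0.02)                   # symmetric steps
  expect_equal(unique(round(abs(out - 0.5), 9)), 0.1)     # unique |step|

  low <- replicate(200, elementPhi(mutatePhi(teElement(0.05), forced)))
  expect_true(all(near(low, c(0, 0.15))))  # downward step clamps at 0
  hi <- replicate(200, elementPhi(mutatePhi(teElement(0.98), forced)))
  expect_true(all(near(hi, c(0.88, 1))))   # upward step clamps at 1

  # phi stays a probability under arbitrarily many mutations
  phi <- teElement(0.5)
  for (i in 1:500) {
    phi <- mutatePhi(phi, forced)
    expect_gte(elementPhi(phi), 0); expect_lte(elementPhi(phi), 1)
  }
  expect_error(mutatePhi(nonCodingElement(), forced))
})

test_that("scan offers each TE a phi mutation on genome replication", {
  forced <- mutationRates(0, 0, 0, 0, phiMut = 1, phiStep = 0.1)
  set.seed(9)
  g <- Genome(c(1, teElement(0.5), 0, teElement(0.5)))
  out <- mutateGenome(g, forced)
  phis <- elementPhi(as.numeric(out))
  phis <- phis[!is.na(phis)]
  expect_length(phis, 2)
  expect_true(all(abs(phis - 0.4) < 1e-9 | abs(phis - 0.6) < 1e-9))
})
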