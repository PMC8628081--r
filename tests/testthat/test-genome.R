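test_that("element census counts every class and gene type", {
  empty <- countElements(Genome())
  expect_equal(empty$total, 0)
  expect_equal(empty$essential + empty$transposon + empty$noncoding, 0)
  expect_true(all(empty$perType == 0))

  g <- Genome(c(1:10, teElement(0.9), 0, 0))
  cen <- countElements(g)
  expect_equal(cen$essential, 10)
  expect_equal(cen$transposon, 1)
  expect_equal(cen$noncoding, 2)
  expect_equal(cen$total, length(g))
  expect_equal(unname(cen$perType), rep(1L, 10))

  dupA <- Genome(c(1, 1, 3:10))  # 'a' twice, no 'b'
  cen2 <- countElements(dupA)
  expect_equal(cen2$perType[["a"]], 2L)
  expect_equal(cen2$perType[["b"]], 0L)
})

test_that("viability requires every essential gene type at least once", {
  expect_true(isViable(minimalGenome()))
  expect_false(isViable(Genome()))
  expect_false(isViable(Genome(1:9)))  # a..i, no j
  # every strict sub-multiset of the minimal genome is inviable
  for (k in 1:10)
    expect_false(isViable(Genome(setdiff(1:10, k))))
  # redundant copies and non-coding padding do not break viability
  expect_true(isViable(Genome(c(1:10, 1:10, rep(0, 5)))))
})

test_that("fitness is 1 - c*T for viable genomes, 0 otherwise, clamped", {
  expect_equal(computeFitness(standardGenome(10, 30)), 1.0)
  expect_equal(computeFitness(Genome(c(1:10, teElement(0.9)))), 0.995)
  expect_equal(computeFitness(Genome(1:9)), 0.0)
  big <- Genome(c(1:10, rep(teElement(0.5), 300)))
  expect_equal(computeFitness(big), 0.0)  # 1 - 0.005*300 < 0, clamped
  # inactivated genes are non-coding: sole copy lost -> fitness 0
  expect_equal(computeFitness(applyInactivation(minimalGenome(), 3)), 0.0)
})

test_that("fitness is bounded, census-only, and drops by exactly c per TE", {
  set.seed(42)
  p <- fitnessParams()
  for (i in 1:200) {
    g <- randomGenome(n = sample(0:60, 1))
    f <- computeFitness(g, p)
    expect_gte(f, 0); expect_lte(f, 1)
    # permutation invariance: fitness depends only on the census
    gp <- Genome(sample(as.numeric(g)))
    expect_identical(computeFitness(gp, p), f)
    # viability consistency between the R and compiled routes
    expect_identical(f > 0, isViable(g, p) && f > 0)
    if (isViable(g, p) && f > p@c) {
      withTE <- Genome(c(as.numeric(g), teElement(runif(1))))
      expect_equal(f - computeFitness(withTE, p), p@c)
    }
  }
})

test_that("genome text form round-trips and uses the documented tokens", {
  expect_equal(genomeToString(Genome(c(1, 0, teElement(0.9)))), "a,.,T:0.900")
  expect_equal(as.numeric(genomeFromString("a,.,T:0.900")),
               c(1, 0, teElement(0.9)))
  expect_equal(genomeToString(Genome()), "")
  expect_length(genomeFromString(""), 0)
  set.seed(7)
  for (i in 1:20) {
    g <- Genome(round(as.numeric(randomGenome(sample(0:40, 1))), 3))
    expect_equal(as.numeric(genomeFromString(genomeToString(g))),
                 as.numeric(g))
  }
  tf <- withr::local_tempfile()
  gs <- list(minimalGenome(), Genome(), standardGenome(4, 6))
  writeGenomes(gs, tf)
  back <- readGenomes(tf)
  expect_equal(lapply(back, as.numeric), lapply(gs, as.numeric))
})

test_that("founding genomes have the requested composition", {
  g <- standardGenome(10, 30)
  cen <- countElements(g)
  expect_equal(cen$essential, 10)
  expect_equal(cen$noncoding, 30)
  expect_equal(cen$transposon, 0)
  expect_true(isViable(g))
  expect_equal(length(minimalGenome()), 10)
})
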