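zero <- mutationRates(0, 0, 0, 0, 0, 0.1)

test_that("lysis partitions the genome into fragments of 3 to 8 elements", {
  expect_length(lyse(Genome()), 0)
  set.seed(4)
  # conservation: concatenated fragments equal the genome, for any input
  for (i in 1:30) {
    g <- randomGenome(sample(0:60, 1))
    frags <- lyse(g)
    expect_equal(unlist(lapply(frags, as.numeric)), as.numeric(g),
                 ignore_attr = TRUE)
  }
  # length law over many lysed 40-element genomes
  nonFinal <- integer(0); final <- integer(0)
  for (i in 1:2000) {
    L <- lengths(lyse(standardGenome(10, 30)))
    if (length(L) > 1) nonFinal <- c(nonFinal, L[-length(L)])
    final <- c(final, L[length(L)])
  }
  expect_true(all(nonFinal >= 3 & nonFinal <= 8))
  expect_equal(max(nonFinal), 8L)
  expect_equal(min(nonFinal), 3L)
  expect_true(all(final >= 1 & final <= 8))  # remainder may be short
})

test_that("eDNA fragments degrade with rate q and diffuse to Moore neighbours", {
  pool <- list(elements = rep(list(c(0, 0, teElement(0.5))), 50),
               site = rep(13L, 50))  # centre of a 5x5 grid
  set.seed(6)
  gone <- stepEdna(pool, ednaParams(u = 0, D = 0, q = 1), 5, 5)
  expect_length(gone$site, 0)

  same <- stepEdna(pool, ednaParams(u = 0, D = 0, q = 0), 5, 5)
  expect_equal(same$site, pool$site)
  expect_equal(same$elements, pool$elements)

  moved <- stepEdna(pool, ednaParams(u = 0, D = 1, q = 0), 5, 5)
  # site 13 of a 5x5 grid is row 3, col 3; its Moore neighbourhood:
  moore <- c(7L, 8L, 9L, 12L, 14L, 17L, 18L, 19L)
  expect_true(all(moved$site %in% moore))
  expect_length(moved$site, 50)
})

test_that("diffusion wraps around the torus", {
  pool <- list(elements = list(0), site = 1L)  # corner of a 4x4 grid
  set.seed(10)
  dests <- sort(unique(replicate(300,
    stepEdna(pool, ednaParams(D = 1, q = 0), 4, 4)$site)))
  cornerMoore <- sort(c(2L, 4L, 5L, 6L, 8L, 13L, 14L, 16L))
  expect_equal(dests, cornerMoore)
})

test_that("fragment survival is geometric with mean 1/q", {
  set.seed(19)
  n0 <- 4000
  pool <- list(elements = rep(list(0), n0), site = rep(1L, n0))
  p <- ednaParams(D = 0.01, q = 0.02)
  for (i in 1:50) pool <- stepEdna(pool, p, 10, 10)
  expected <- n0 * (1 - 0.02)^50
  se <- sqrt(n0 * (1 - 0.02)^50 * (1 - (1 - 0.02)^50))
  expect_lt(abs(length(pool$site) - expected), 4 * se)
})

test_that("uptake consumes fragments and integrates only TEs", {
  set.seed(23)
  g <- minimalGenome()
  none <- uptakeAndIntegrate(g, list(c(0, 1, 0)), ednaParams(u = 0))
  expect_identical(as.numeric(none$genome), as.numeric(g))
  expect_false(any(none$consumed))

  # certain uptake of a TE-free fragment: consumed, genome untouched
  inert <- uptakeAndIntegrate(g, list(c(0, 1, 0)), ednaParams(u = 1))
  expect_true(all(inert$consumed))
  expect_identical(as.numeric(inert$genome), as.numeric(g))
  expect_equal(inert$integrated, 0)

  # certain uptake of a phi = 1 TE always integrates it
  hot <- uptakeAndIntegrate(g, list(teElement(1)), ednaParams(u = 1), b = 0)
  expect_equal(countElements(hot$genome)$transposon, 1)
  expect_equal(hot$integrated, 1)
})

test_that("integration after uptake damages the insertion site per b", {
  set.seed(29)
  p1 <- fitnessParams(nFunctions = 1)
  damaged <- 0L; n <- 2000
  for (i in seq_len(n)) {
    res <- uptakeAndIntegrate(Genome(1), list(teElement(1)),
                              ednaParams(u = 1), b = 1)
    expect_length(res$genome, 2)
    if (!isViable(res$genome, p1)) damaged <- damaged + 1L
  }
  # insertion position uniform over {before, after}: damage half the time
  se <- sqrt(0.25 / n)
  expect_lt(abs(damaged / n - 0.5), 4 * se)
})
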