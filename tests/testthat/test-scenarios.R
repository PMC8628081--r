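test_that("outcome classification separates the three fates", {
  mkTS <- function(n, te, pool = 0) {
    data.frame(t = seq(0, by = 50, length.out = length(n)), nCells = n,
               meanTE = te, poolTE = pool)
  }
  dead <- mkTS(c(100, 40, 0), c(2, 5, NA))
  expect_equal(classifyOutcome(dead), "hosts_extinct")
  teFree <- mkTS(c(100, 100, 100), c(1, 0.2, 0))
  expect_equal(classifyOutcome(teFree), "tes_extinct")
  steady <- mkTS(rep(100, 40), rep(1, 40), rep(10, 40))
  expect_equal(classifyOutcome(steady), "coexistence")
  # strong final-quartile trend: apparent coexistence, not steady
  ramp <- mkTS(rep(100, 40), 2^seq(0, 10, length.out = 40), 0)
  expect_equal(classifyOutcome(ramp), "undecided")
})

test_that("scenario runs are reproducible byte for byte", {
  ov <- list(width = 12, height = 12, steps = 60, nSeeds = 1,
             nonCodingValues = 30, sampleEvery = 20)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- runScenario("ecology_sweep", seed = 5, outDir = d1, overrides = ov)
  r2 <- runScenario("ecology_sweep", seed = 5, outDir = d2, overrides = ov)
  expect_identical(r1$summary$outcome, r2$summary$outcome)
  f1 <- file.path(d1, "timeseries_nc30_seed1.csv")
  f2 <- file.path(d2, "timeseries_nc30_seed1.csv")
  expect_identical(readLines(f1), readLines(f2))
  # the run directory documents its configuration
  cfg <- readSimConfig(file.path(d1, "config.yaml"))
  expect_s4_class(cfg, "SimConfig")
  # ecological sweeps disable all mutational parameters
  expect_identical(TEcoevo:::ratesList(cfg@rates)[1:5],
                   list(singleDup = 0, singleDel = 0, inactivation = 0,
                        largeScale = 0, phiMut = 0))
})

test_that("the evolutionary scenario starts from 10 + 30 founders", {
  ov <- list(width = 10, height = 10, steps = 20, nSeeds = 1, sampleEvery = 10)
  res <- runScenario("evolve", seed = 3, overrides = ov)
  ts0 <- res$timeSeries[[1]][1, ]
  expect_equal(ts0$meanEssential, 10)
  expect_equal(ts0$meanNonCoding, 30)
  expect_equal(ts0$nCells, 100)
})

test_that("configurations round-trip through YAML", {
  cfg <- simConfig(width = 33, height = 21, c = 0.004, phi = 0.75, b = 0.5,
                   mode = "mixed_edna", reproduction = "sexual",
                   initNonCoding = 12, epsilon = 0.7)
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeSimConfig(cfg, tf)
  back <- readSimConfig(tf)
  expect_equal(TEcoevo:::configToList(back), TEcoevo:::configToList(cfg))
})

test_that("checkpointing resumes the exact trajectory", {
  cfg <- simConfig(width = 10, height = 10, sampleEvery = 5)
  set.seed(71)
  straight <- runWorld(inoculate(newWorld(cfg)), 30)

  set.seed(71)
  half <- runWorld(inoculate(newWorld(cfg)), 15)
  tf <- withr::local_tempfile(fileext = ".json")
  saveWorld(half, tf)
  rm(half)
  set.seed(9999)  # clobber the RNG; loadWorld must restore it
  resumed <- runWorld(loadWorld(tf), 15)

  expect_identical(timeSeries(resumed), timeSeries(straight))
  expect_identical(resumed@cells, straight@cells)
  expect_identical(resumed@fragSite, straight@fragSite)
  expect_identical(lineageRecords(resumed), lineageRecords(straight))
  expect_equal(resumed@t, 30L)
})
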