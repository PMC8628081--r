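zero <- mutationRates(0, 0, 0, 0, 0, 0.1)

quietCfg <- function(...) {
  simConfig(rates = zero, d = 0, u = 0, j = 0, sampleEvery = 1, ...)
}

test_that("competition is fitness-proportional with the epsilon rule", {
  expect_true(is.na(compete(numeric(0))))
  # lone fully fit competitor with epsilon 0 always wins
  set.seed(31)
  expect_true(all(replicate(50, compete(1, 0)) == 1L))
  # f = {1, 1}, eps = 1: each wins 1/3 of the time, nobody 1/3
  n <- 30000
  draws <- replicate(n, compete(c(1, 1), 1))
  freq <- c(sum(draws == 1L, na.rm = TRUE) / n,
            sum(draws == 2L, na.rm = TRUE) / n,
            mean(is.na(draws)))
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 4.5 * se))
  # all competitors unfit: nobody can win
  expect_true(is.na(compete(c(0, 0, 0), 1)))
})

test_that("cross-over splits both genomes in the middle", {
  g10 <- Genome(1:10); g12 <- Genome(c(1:10, 0, 0))
  expect_length(crossoverGenomes(g10, g12), 11)  # 5 + 6
  expect_equal(as.numeric(crossoverGenomes(g10, g10)), 1:10)
  child <- reproduceSexual(g10, g10, zero)
  expect_equal(as.numeric(child), 1:10)  # identical parents, no mutation
  # TEs in the right half of parent 2 are inherited without transposition
  p2 <- Genome(c(1:6, rep(teElement(0.9), 4)))
  kid <- crossoverGenomes(g10, p2)
  expect_equal(countElements(kid)$transposon, 4)
})

test_that("asexual reproduction is replication through the mutation scan", {
  set.seed(37)
  g <- standardGenome()
  expect_identical(as.numeric(reproduceAsexual(g, zero)), as.numeric(g))
})

test_that("an empty world stays empty and a quiescent world is invariant", {
  cfg <- quietCfg(width = 8, height = 8)
  set.seed(41)
  w0 <- runWorld(newWorld(cfg, fill = FALSE), 5)
  expect_equal(nCells(w0), 0)
  expect_length(w0@fragSite, 0)

  # d = 0, no TEs, no mutations, full grid: an absorbing state
  w1 <- newWorld(cfg)
  before <- vapply(w1@cells, genomeToString, character(1))
  w1 <- runWorld(w1, 5)
  expect_equal(vapply(w1@cells, genomeToString, character(1)), before)
  expect_equal(nCells(w1), 64)
})

test_that("occupancy stays consistent and time series cross-checks", {
  cfg <- simConfig(width = 12, height = 12, sampleEvery = 5)
  set.seed(43)
  w <- inoculate(newWorld(cfg))
  w <- runWorld(w, 40)
  expect_length(w@cells, 144)
  ts <- timeSeries(w)
  expect_equal(ts$nCells[nrow(ts)], nCells(w))
  # the identity meanLength = sum of the three mean counts, every sample
  alive <- ts$nCells > 0
  expect_equal(ts$meanLength[alive],
               ts$meanEssential[alive] + ts$meanTE[alive] +
                 ts$meanNonCoding[alive])
})

test_that("runs are deterministic given the seed", {
  cfg <- simConfig(width = 15, height = 15, sampleEvery = 10)
  runOnce <- function() {
    set.seed(97)
    w <- inoculate(newWorld(cfg))
    runWorld(w, 120)
  }
  a <- runOnce(); b <- runOnce()
  expect_identical(timeSeries(a), timeSeries(b))
  expect_identical(a@cells, b@cells)
  expect_identical(teAbundance(a), teAbundance(b))
  expect_identical(lineageRecords(a), lineageRecords(b))
})

test_that("certain death closes every inoculated lineage with its TE output", {
  cfg <- simConfig(width = 6, height = 6, d = 1, u = 0, j = 0, rates = zero,
                   inoculumSize = 6, sampleEvery = 1)
  set.seed(47)
  w <- inoculate(newWorld(cfg))
  expect_equal(nrow(w@openLineages), 36)
  w <- runWorld(w, 1)
  # every cell died; no survivors existed to repopulate the next phase
  recs <- lineageRecords(w)
  expect_equal(nrow(recs), 36)
  expect_equal(sum(recs$teProduced), 36)  # one TE per inoculated genome
  expect_true(all(recs$tExtinct >= recs$tInfected))
  expect_true(all(recs$generations == 0))
})

test_that("sexual and mixed modes run and conserve what they should", {
  set.seed(53)
  sx <- simConfig(width = 12, height = 12, reproduction = "sexual",
                  sampleEvery = 10)
  ws <- runWorld(inoculate(newWorld(sx)), 50)
  expect_gt(nCells(ws), 0)

  # mixed_cells with no death/birth/mutation: genomes permute but are conserved
  mc <- quietCfg(width = 8, height = 8, mode = "mixed_cells")
  wm <- newWorld(mc)
  before <- sort(vapply(wm@cells, genomeToString, character(1)))
  wm <- runWorld(wm, 3)
  expect_equal(sort(vapply(wm@cells, genomeToString, character(1))), before)
})
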