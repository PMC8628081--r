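zero <- mutationRates(0, 0, 0, 0, 0, 0.1)

test_that("time-series samples summarise the population correctly", {
  cfg <- simConfig(width = 5, height = 5, rates = zero)
  w <- newWorld(cfg)  # uniform 10 essential + 30 non-coding founders
  rec <- recordTimeSeries(w)
  expect_equal(rec$nCells, 25)
  expect_equal(rec$meanEssential, 10)
  expect_equal(rec$meanTE, 0)
  expect_equal(rec$meanNonCoding, 30)
  expect_equal(rec$meanLength, 40)
  expect_equal(rec$meanFitness, 1)
  expect_true(is.na(rec$meanPhi))  # no TEs anywhere

  lone <- sparseWorld(cfg, list("7" = minimalGenome()))
  rec1 <- recordTimeSeries(lone)
  expect_equal(rec1$nCells, 1)
  expect_equal(rec1$meanLength, 10)
  expect_equal(rec1$meanFitness, 1)

  emptyRec <- recordTimeSeries(newWorld(cfg, fill = FALSE))
  expect_equal(emptyRec$nCells, 0)
  expect_true(is.na(emptyRec$meanLength))
})

test_that("engine samples agree with the independent R computation", {
  cfg <- simConfig(width = 15, height = 15, sampleEvery = 25)
  set.seed(59)
  w <- runWorld(inoculate(newWorld(cfg)), 100)
  ts <- timeSeries(w)
  engineRow <- ts[nrow(ts), ]
  expect_equal(engineRow$t, w@t)  # last sample is the final state
  rRow <- recordTimeSeries(w)
  rownames(engineRow) <- rownames(rRow) <- NULL
  expect_equal(engineRow, rRow, tolerance = 1e-12)
})

test_that("snapshots map the grid losslessly", {
  cfg <- simConfig(width = 6, height = 4, rates = zero)
  w <- newWorld(cfg, fill = FALSE)
  m0 <- exportSnapshot(w, "occupancy")
  expect_equal(dim(m0), c(4, 6))
  expect_true(all(is.na(m0)))

  # checkerboard occupancy round-trips exactly
  sites <- which((row(matrix(0, 4, 6)) + col(matrix(0, 4, 6))) %% 2 == 0)
  chk <- matrix(FALSE, 4, 6)
  for (r in 1:4) for (cc in 1:6) {
    if ((r + cc) %% 2 == 0) {
      w@cells[[(r - 1) * 6 + cc]] <- as.numeric(minimalGenome())
      chk[r, cc] <- TRUE
    }
  }
  m1 <- exportSnapshot(w, "occupancy")
  expect_equal(!is.na(m1), chk)
  expect_true(all(m1[!is.na(m1)] == 1))

  mlen <- exportSnapshot(w, "genome_length")
  expect_true(all(mlen[!is.na(mlen)] == 10))

  tf <- withr::local_tempfile(fileext = ".txt")
  mte <- exportSnapshot(w, "te_count", file = tf)
  back <- as.matrix(utils::read.table(tf))
  dimnames(back) <- NULL
  expect_equal(back, mte)
  expect_error(exportSnapshot(w, "unknown_channel"))
})

test_that("lineage records respect their invariants in a live run", {
  cfg <- simConfig(width = 15, height = 15, sampleEvery = 50)
  set.seed(61)
  w <- runWorld(inoculate(newWorld(cfg)), 300)
  recs <- lineageRecords(w, includeOpen = TRUE)
  expect_gt(nrow(recs), 0)
  expect_true(all(recs$tExtinct >= recs$tInfected))
  expect_true(all(recs$teProduced >= 0))
  expect_true(all(recs$generations >= 0))
  open <- attr(recs, "open")
  expect_true(all(open$members >= 1))
  # every living cell with a lineage id points at an open record
  ids <- unique(w@lineageId[w@lineageId > 0])
  expect_true(all(ids %in% open$id))
  expect_setequal(ids, open$id)
})
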