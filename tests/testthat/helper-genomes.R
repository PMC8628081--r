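# shared fixture builders

randomGenome <- function(n = 20, pTE = 0.2, pNC = 0.3, nFunctions = 10) {
  if (n == 0) return(Genome())
  v <- numeric(n)
  u <- runif(n)
  te <- u < pTE
  nc <- !te & u < pTE + pNC
  ess <- !te & !nc
  v[te] <- -1 - runif(sum(te))
  v[ess] <- sample(nFunctions, sum(ess), replace = TRUE)
  Genome(v)
}

# a world with explicit cells placed on an otherwise empty grid;
# cells is a named list: site index -> genome
sparseWorld <- function(cfg, cells) {
  w <- newWorld(cfg, fill = FALSE)
  for (s in names(cells)) w@cells[[as.integer(s)]] <- as.numeric(cells[[s]])
  w@timeSeries <- recordTimeSeries(w)
  w
}
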