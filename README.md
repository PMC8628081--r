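# TEcoevo

Individual-based simulation of the coevolution of transposable elements
(TEs) and the architecture of their host genomes.

## The problem

Prokaryotes carry TEs yet keep small, streamlined genomes; eukaryotes carry
vast TE-rich intergenic deserts.  A mechanistic question sits underneath:
when TEs spread horizontally through environmental DNA and integration can
destroy the gene at the insertion site, does selection on *cells* or on
*lineages* shape how much non-coding DNA a genome keeps?  TEcoevo is a
spatial eco-evolutionary model built to ask exactly that.  Cells with
linear genomes — essential genes `a`–`j`, TEs with heritable transposition
rates φ, and non-coding DNA — live on a toroidal grid, compete locally for
vacant sites in proportion to fitness

    f = 0                 if any essential gene type is missing
    f = max(0, 1 − c·T)   otherwise,  c = 0.005, T = number of TEs

die and lyse into an extracellular DNA pool, from which TEs reinfect the
next cells (integration with the TE's own φ, insertion damage with
probability b).  Genomes mutate at replication (single and large-scale
duplications/deletions/inversions, inactivation, φ-steps of ±0.1), so gene
content, genome size and TE behaviour all evolve together.  The package is
aimed at researchers in molecular evolution who want the model's
primitives, its full simulation engine, lineage-level observers, and the
canned experiments (ecological phase sweep, de novo streamlining, damage
and HGT controls, sexual vs asexual comparison) as reproducible runs.

## A worked example

```r
library(TEcoevo)

g <- Genome(c(1:10, teElement(0.9)))   # all ten essential genes + one TE
computeFitness(g)
#> [1] 0.995

set.seed(7)
cfg <- simConfig(width = 30, height = 30, sampleEvery = 100)
w <- inoculate(newWorld(cfg))          # full grid, 5x5 central TE inoculum
w <- runWorld(w, 500)
w
#> TEWorld 30x30 (toroidal), t = 500
#>   cells: 897 / 900 sites occupied
#>   TEs: 1972 cellular, 3849 in eDNA pool (7004 fragments)
#>   lineages: 34 infected alive, 185 extinct on record
#>   mode: spatial / asexual_hgt

tail(timeSeries(w)[, c("t", "nCells", "meanTE", "meanNonCoding", "meanFitness")], 2)
#>     t nCells    meanTE meanNonCoding meanFitness
#> 5 400    898 0.7193764      30.99555   0.9952895
#> 6 500    897 2.1984392      31.88852   0.9832219
```

The time series tracks mean per-genome composition, genome length, mean φ,
fitness and the eDNA pool; `lineageRecords(w)` returns one row per extinct
infected lineage (infection and extinction times, generations survived, TE
copies released by lysis), and `exportSnapshot(w, "te_count")` renders the
grid.  `runScenario("ecology_sweep")`, `"evolve"`, `"sexual_compare"`,
`"b_sweep"`, `"no_hgt"` package the experiments; a command-line front end
lives at `inst/scripts/tecoevo` (subcommands `run`, `sweep`, `resume`,
`summarise`).

See the vignette (`vignettes/te-host-coevolution.Rmd`) for the model in
full: the update schedule, the mutation operators, the eDNA uptake
scheduling variants and their consequences, and what desk-scale runs can
and cannot show.

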