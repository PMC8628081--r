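---
title: "Modelling transposable element–host genome coevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transposable element–host genome coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEcoevo)
```

## The model

TEcoevo is an individual-based model of single-celled, initially asexual
organisms whose genomes coevolve with autonomous transposable elements
(TEs), in the spirit of insertion-sequence elements: selfish, autonomous,
without insertion-site preference, moving both vertically and — through an
extracellular DNA pool — horizontally.

Cells live on a toroidal `width × height` grid, at most one per site.  A
genome is a linear sequence of three element kinds:

* **essential genes** of `nFunctions = 10` distinct types (`a`–`j`); a cell
  is viable iff every type is present at least once;
* **TEs**, each carrying a heritable transposition rate
  $\varphi \in [0, 1]$;
* **non-coding DNA**, costless and functionless.

Fitness is
$$f = \begin{cases} 0 & \text{any essential type missing,} \\
\max(0,\, 1 - c\,T) & \text{otherwise,}\end{cases}$$
with $T$ the number of TEs and $c = 0.005$ per copy.  There is deliberately
no cost on genome size: redundant gene copies and non-coding stretches are
free, so any evolution toward compact genomes cannot come from replication
costs.  The published fitness expression is linear in $T$; we clamp it at
zero because it is used as a competition weight (a weight below zero has no
interpretation in the sampling scheme).

Each timestep applies, in fixed order: (1) death — non-viable cells plus a
fraction $d = 0.02$ of viable cells die and lyse, spilling their genome
into the local eDNA pool as fragments of 3–8 elements; (2) eDNA turnover —
each fragment degrades with probability $q = 0.02$ and otherwise hops to a
random Moore neighbour with probability $D = 0.01$; (3) competition — for
every empty site, up to eight Moore neighbours compete; neighbour $i$ wins
with probability $f_i / (\sum_j f_j + \varepsilon)$, so with probability
$\varepsilon / (\sum_j f_j + \varepsilon)$ the site stays empty; the
winner's genome is replicated through the mutation scan and the daughter
placed on the site; (4) eDNA uptake with TE integration; (5) within-genome
transposition — each TE, once per step, transposes with probability
$\varphi j$, inserting a copy at a uniform position; (6) viability refresh.
All empty sites are filled synchronously from the same pre-phase occupancy,
so a daughter never reproduces in the step of its own birth.  The update
order is a design choice of this package (the narrative order of the
original description): it makes lysis products available to the very next
generation and collects insertion-damage casualties at the following death
phase.

Insertion damage is the model's central coupling: with probability `b`
(default 1) the coding element displaced at the insertion site is
inactivated — converted to non-coding, staying in the genome.  Inactivated
is inactivated: both damaged genes and damaged TEs become plain non-coding
positions, which is also how the gene-inactivation mutation is represented.
Inserting next to non-coding DNA never does damage.  With `b = 0` TEs
insert cleanly between elements.

## Mutation operators

At every replication the genome is scanned left to right.  Each position is
offered, in fixed order, a large-scale event, a single duplication, a
single deletion, and an inactivation (0.001 each per position); the first
event that fires is applied and the scan moves on — each element mutates at
most once per replication, and copies created by a duplication are not
re-scanned within the pass.  Duplications are tandem.  Large-scale events
duplicate, delete or invert (equal probability) a contiguous segment whose
length is uniform on $[1, \lfloor G/2\rfloor - 1]$, truncated at the genome
end; the mean segment is a quarter of the genome, which is the calibration
the event-size distribution is tested against.  (The distribution itself is
underdetermined — only its mean is anchored — and the uniform family is the
simplest choice; note that $U[1, \lfloor G/2\rfloor]$ would put the mean at
$G/4 + 1/2$, visibly off 25% on the 40-element reference genome, which is
why the upper bound is $\lfloor G/2\rfloor - 1$.)  Every TE replication —
transposition, uptake integration, or the host replicating its genome —
carries a probability 0.01 of a $\varphi$ mutation of exactly ±0.1, clamped
to $[0, 1]$ since $\varphi$ is used as a probability.

## Horizontal transfer and the uptake-scheduling question

Dead cells fragment into pieces of 3 to 8 elements (a terminal remainder
shorter than its draw is kept, so fragments always partition the genome —
conservation is worth more than purity of the length law at the last
piece).  Fragments sit at the site of lysis.  Only TEs can cross from a
taken-up fragment into the recipient genome — each with probability equal
to its own $\varphi$, at a uniform position, with the usual insertion
damage; essential-gene and non-coding eDNA is inert, because the model has
no sequence homology to recombine over.

How uptake is *scheduled* turns out to govern the model's epidemiology, and
the package exposes three schedulings (`uptakeMode`):

* `"per_fragment"` (default): every fragment co-located with a living cell
  is taken up with probability $u = 0.01$ per step.  Since a fragment
  persists $1/q = 50$ steps on average, about a third of the pool at
  occupied sites is eventually absorbed.  Sites where an infected cell
  lysed re-infect successive occupants, so local TE concentrations can
  grow into self-reinforcing hotspots; TE loads in infection waves reach
  tens of copies per genome.
* `"per_cell"`: a cell's uptake machinery handles at most one fragment per
  step (probability $u$; the fragment is chosen uniformly from the cell's
  own site and Moore neighbourhood).  Influx no longer scales with local
  pool size; at the standard rates horizontal spread is subcritical and
  TEs introduced in a small inoculum are lost by drift.
* `"at_birth"`: only daughters, in the step of their birth, sample the
  local pool (transformation tied to replication).  Weaker still.

The default follows the stated per-fragment rate.  The variants document
how sensitive the coexistence region is to this single scheduling choice —
an observation we found more instructive than any parameter sweep.

## Reproduction modes

* `asexual_hgt`: clonal replication through the mutation scan, plus eDNA
  uptake — the model's bacterium.
* `sexual`: two parents are sampled from the competitors of an empty site
  (fitness-proportionally, with the same $\varepsilon$ rule; if the second
  draw returns nobody, or only one neighbour lives, the single parent is
  copied clonally), and the child genome is the left half of parent 1
  joined to the right half of parent 2, each split at
  $\lfloor L/2 \rfloor$; DNA uptake is disabled.  Cross-over lets TEs
  change lineage without transposing, i.e. without any risk of killing the
  new host.
* `clonal`: neither uptake nor sex; TEs can only persist vertically.

Mixing controls (`mode`): `mixed_cells` assigns every cell a random site
after each replication round, destroying all spatial structure;
`mixed_edna` shuffles only the fragment pool.

## Parameters

All defaults are the standard parameterisation: grid 150×150 (toroidal),
10 essential functions, $c = 0.005$, $d = 0.02$, $u = 0.01$, $j = 0.01$,
$D = 0.01$, $q = 0.02$, initial $\varphi = 0.9$, $b = 1$, structural
mutation rates 0.001 per position, $\varphi$-mutation 0.01 per TE
replication with step 0.1.  $\varepsilon$ defaults to 1: a lone fully fit
competitor then wins an empty site half of the time, while a neighbourhood
of unfit cells rarely reproduces.  $\varepsilon$ is not pinned by the
source model description; sensitivity pilots (0.5–8) did not change the
qualitative fates reported below, because the decisive feedbacks run
through uptake and insertion damage rather than through colonisation speed.

The founding genome interleaves `initEssential = 10` essential genes evenly
with `initNonCoding = 30` non-coding positions; inoculation adds one TE
($\varphi = 0.9$) at a random position — damage-free, modelling the arrival
of an established element — to every cell of a 5×5 central block, each
founding a tracked lineage.

## Observers and lineages

Time series (every `sampleEvery = 50` steps by default) record population
size, mean per-genome counts of the three element classes, mean genome
length, mean $\varphi$ over all cellular TEs, mean fitness, and the
fragment and TE content of the pool.  A *lineage* starts when a previously
uninfected cell first acquires a TE; all its descendants — including ones
that lose the TEs again — belong to it until the last member dies, at which
point a record is closed carrying the infection and extinction times, the
maximal generation depth reached since infection (replication events along
a line of descent; wall-clock extinction time is also derivable from the
two timestamps), and the cumulative number of TE copies the lineage
released into the pool by lysis.  Grid snapshots export occupancy, TE
count (log-scaled colouring) or genome length as plain numeric matrices
and optional raster images; empty sites are distinct (NA / black).

## Scenarios, problem sizes, and what desk-scale runs can show

`runScenario()` packages the experiments: the ecological phase sweep
(mutations disabled, fixed $\varphi$, founding non-coding content swept),
the evolutionary run, its mixed-cells control, the sexual / asexual /
clonal comparison, the insertion-damage (`b`) sweep including the
damage-free control, and the no-HGT control.  Scenario defaults run at
desk scale — a 75×75 torus for ecological sweeps and comparisons — chosen
as the smallest grids where the relevant contrast is expressed; the
source parameterisation calls its 150×150 grid *minimal* for sustaining
local extinctions, wavefronts and multiple coexisting strains
simultaneously, and that caveat is measurable here: under the default
uptake scheduling the evolutionary scenario's initial TE expansion wave
can overrun grids much smaller than that before streamlined refuges
emerge, so evolutionary-scenario results at desk scale must be read with
the grid size in mind.  The tests and the reproduction script state the
exact problem sizes they use; they are the package's documented study
conditions, not tuned quantities.

What passing desk-scale tests show — and what they do not: the synthetic
worlds here have no nutrient structure, no seasonality, no sequence-level
homology, and every cell follows identical update rules, so agreement at
desk scale demonstrates the mechanisms (insertion damage, abortive
lineage death, eDNA-mediated reinfection, recombination unlinking TEs
from their damage) rather than any quantitative prediction for real
microbial communities.

## Numerical and degenerate-input choices

Fitness clamps at zero (competition weights must be non-negative).
$\varphi$ clamps to $[0,1]$.  Empty genomes are legal, never viable, lyse
into nothing.  Segment draws truncate at the linear genome end.  Insertion
at the append position displaces nothing and can do no damage.  The
sexual-mode cross-over of an odd-length parent gives the extra element to
the right half.  Determinism: every stochastic choice draws from R's RNG,
so `set.seed()` makes whole-world trajectories reproducible, and world
archives embed the RNG state so a resumed run continues the exact
trajectory.

## Known limitations

TE loads and pool sizes are unbounded above by construction; in the
supercritical uptake regime memory and runtime grow with the infection
wave.  The lineage ledger tracks infection lineages only (uninfected
genealogy is not recorded).  The model has no nucleotide sequences, no
homologous recombination, no TE families, no insertion-site preference,
and no explicit cost of genome replication — all deliberate abstractions
inherited from the modelled system.
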