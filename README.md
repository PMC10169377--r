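# apisim

Individual-based simulation of honeybee (*Apis mellifera*) populations and
breeding programs in R.

Honeybees break the assumptions of generic breeding-program simulators:
males are haploid (drones develop from unfertilised eggs and their sperm is
clonal), sex is decided by heterozygosity at the complementary sex
determination (**csd**) locus (diploid homozygotes are killed as brood),
queens mate once with many drones and store their sperm for life, and
selection acts on *colonies* — whose phenotypes combine a queen effect and
the summed effects of tens of thousands of workers. apisim models all of
this at the level of individual genomes, for researchers who want to test
breeding schemes, mating designs (drone congregation areas vs. mating
stations), conservation strategies, or statistical methods on simulated
honeybee data before deploying them.

## The model in brief

* **Genomes.** Tracked biallelic segregating sites with a genetic map
  proportional to physical position (`Morgan = bp × 2.3e-7` by default).
  Meiosis is Haldane: per chromosome, `Poisson(length in Morgans)`
  crossovers, uniform on the map, no interference. Identity-by-descent to
  founder haplotypes is tracked through every crossover.
* **Founders.** A built-in structured coalescent simulates three subspecies
  (*carnica*, *ligustica*, *mellifera*) under a divergence model and returns
  exactly the requested number of segregating sites per chromosome;
  alternatively, phased haplotypes are imported from VCF or a 0/1 matrix.
* **csd.** A window of `log2(nCsdAlleles)` fully linked SNPs; founder
  windows are edited to carry the desired allele richness. Homozygous brood
  is removed at egg creation: the theoretical loss for a queen with csd
  words `{a1, a2}` and fathers `f_1..f_k` is
  `pHomBrood = (1/(2k)) Σ_j ([f_j = a1] + [f_j = a2])`, realized losses are
  binomial, and the queen's cumulative `nHomBrood()` counter tracks them.
* **Colonies and events.** `Colony` holds queen + fathers, workers, drones,
  virgin queens, plus location, event flags, and a production status;
  `MultiColony` vectorizes management over apiaries. Events: `swarm()`,
  `split()`, `supersede()`, `collapse()`, `downsize()`, `combine()`,
  `reQueen()`, `buildUp()`.
* **Quantitative genetics.** Additive traits with correlated queen and
  worker effects (`addTraitA()`), effects scaled so the base virgin-queen
  population hits the target means/variances; drones scored as doubled
  haploids; colony value = queen effect + Σ worker effects by default
  (`calcColonyValue()`), with custom mappings supported. `calcGRM()` gives
  the VanRaden method-1 genomic relationship matrix.

## A worked example

```r
library(apisim)

founders <- simulateFounderGenomes(nCar = 10, nChr = 3, nSegSites = 100)
SP  <- newSimParamBee(founders, nWorkers = 100, nDrones = 10,
                      nCsdAlleles = 32, seed = 42)
basePop <- createVirginQueens(founders)          # 10 virgin queens
colony  <- createColony(basePop[1])
dca     <- createDrones(basePop[2:5], nInd = 100)  # a drone congregation area
grp     <- pullDroneGroupsFromDCA(dca, 1, nFathers = 15)
colony  <- cross(colony, drones = grp$groups[[1]])
colony  <- buildUp(colony)
colony
```

```
Colony
  id: 1
  location: NA
  queen: 1
  fathers: 15 | workers: 100 | drones: 10 | virgin queens: 0
  swarmed: FALSE | split: FALSE | superseded: FALSE | collapsed: FALSE | productive: TRUE
```

Mating promoted the first virgin queen to queen (her 15 mates are now
"fathers", stored in her spermatheca), and the default build-up added 100
workers and 10 drones, switching the colony to productive.
`createVirginQueens()` warns along the way that 20 founder haplotypes can
carry at most 20 of the 32 requested csd alleles — expected at this toy
scale. All 20 installed alleles are distinct, so the queen and her mates
share none: `pHomBrood(colony)` is `0` and all 100 requested workers
survived. Mating close relatives instead drives `pHomBrood()` up to 0.25
(brother mating) and the realized worker count correspondingly down.

A complete breeding-program demonstration — founders, correlated
queen/worker traits, crossing, yearly swarming/collapse, colony-value
selection, apiary replenishment, CSV/log outputs — is available as
`runBreedingDemo(demoConfig())`.

## Documentation

The methods vignette (`vignettes/honeybee-simulation.Rmd`) describes the
genome and csd models, event semantics, trait scaling, the synthetic-data
generator's scope, numerical choices, and known limitations. Every exported
function carries roxygen documentation with examples.
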