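---
title: "Simulating honeybee populations with apisim: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating honeybee populations with apisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apisim)
```

# What apisim simulates

apisim is an individual-based, forward-in-time simulator of honeybee
(*Apis mellifera*) populations and breeding programs. Every simulated bee
carries a phased genome; colonies are first-class objects holding a queen
(with the drones she mated with stored in her spermatheca), workers, drones,
and virgin queens; apiaries collect colonies for vectorized management. The
simulator covers the biological features that make honeybees awkward for
generic breeding simulators:

* **Haplodiploidy.** Females (queens, workers) are diploid and develop from
  fertilised eggs; males (drones) are haploid and develop from unfertilised
  eggs. A drone's genome is a single meiotic gamete of his mother, and his
  sperm is clonal — all his daughters share his entire genome, which creates
  the strong within-patriline relatedness typical of the species.
* **Complementary sex determination (csd).** Diploid individuals develop as
  females only when heterozygous at the csd locus; homozygotes become
  inviable diploid drones that workers kill. apisim models the locus as a
  window of completely linked biallelic SNPs and removes homozygous brood at
  egg creation.
* **Polyandry.** A virgin queen mates once, with several drones (6–24 in
  nature), at a drone congregation area (DCA) or a mating station, and
  stores their sperm for life. Mating is a caste transition: the virgin
  queen becomes a queen, the drones become "fathers" and die.
* **Colony life history.** Swarming, splitting, supersedure, collapse,
  downsizing, combining, and requeening, with a production flag that follows
  beekeeping logic (a colony is productive only after build-up, and stops
  being productive when it swarms, collapses, is downsized, or is the split
  part of a division).
* **Colony-level quantitative genetics.** Traits are defined per individual,
  with correlated queen-effect and worker-effect components; colony values
  are mapped from individual values (by default: queen effect of the queen
  plus the sum of worker effects over workers, the additive model used for
  honey yield).

# The genome model

Tracked loci are abstract biallelic segregating sites with physical (bp) and
genetic (Morgan) coordinates. The genetic map is proportional to physical
position: `mapPos = bp * recombRate`. The default recombination rate is
2.3e-7 per bp, the published genome-wide estimate for the species, over a
250 Mbp genome in 16 chromosomes. (Two headline figures circulate for the
total map length under these numbers — 23 Morgans and the 57.5 Morgans the
rate implies; apisim treats the per-bp rate as authoritative and derives
every chromosome's genetic length from it.)

Meiosis follows the Haldane model: per chromosome, a Poisson number of
crossovers with mean equal to the chromosome's genetic length, positions
uniform on the genetic map, no interference, no obligate chiasma, and a fair
coin for the starting haplotype. This is the simplest standard model and the
only one consistent with a purely rate-based map. Identity-by-descent is
tracked exactly: every allele in every generation carries the label of the
founder haplotype it descends from, and label breakpoints coincide with
crossovers.

## Founder genomes

`simulateFounderGenomes()` draws founder haplotypes from a structured
coalescent under a three-subspecies divergence model: an ancestral
population splits into *A. m. mellifera* and the common ancestor of
*A. m. ligustica* and *A. m. carnica*, which then split. Within small
blocks of sites (10 by default) genealogies are shared (complete linkage);
between blocks they are independent — a reasonable approximation for a
genome whose chromosomes are several Morgans long. Mutations are placed on
the genealogy proportionally to branch length, one per site, which
guarantees that **exactly** the requested number of segregating sites is
returned per chromosome (every branch below the root subtends a proper,
non-empty subset of haplotypes).

The real demographic parameters of the three subspecies are not established
well enough to hard-code; the split times (0.3 and 0.6 coalescent units by
default) are package choices that produce clearly larger between- than
within-subspecies divergence, and they are user-overridable. Users with real
data can bypass the coalescent entirely with `importHaplotypes()` (phased
VCF or a plain 0/1 matrix; drone-derived haplotypes are duplicated into
fully homozygous diploid founders).

## The csd locus

The number of possible csd alleles is `2^L` where `L` is the window length
in SNPs; `newSimParamBee(nCsdAlleles = ...)` therefore requires a power of
two (default 128, i.e. a 7-SNP window; the window sits on chromosome 3 where
the real locus resides, or chromosome 1 for small demonstration genomes).
Non-recombination within the window is implemented by giving all window
sites a single genetic position — the window then behaves as one locus in
every meiosis, exactly and without rejection sampling.

Because real populations carry many intermediate-frequency csd alleles
(balancing selection), `editCsdAlleles()` rewrites the founder window
haplotypes: a complement-closed set of distinct words is assigned
round-robin across haplotypes, which makes allele frequencies as uniform as
integer counts allow, keeps every window site segregating, and leaves every
founder heterozygous. When more alleles are requested than founder
haplotypes exist, the function warns and installs as many as fit.

`pHomBrood()` computes the theoretical brood homozygosity of a mated queen
with csd words `{a1, a2}` and father words `f_1..f_k` as
`(1/(2k)) * sum_j([f_j = a1] + [f_j = a2])`, i.e. each egg carries one
maternal word with probability 1/2 and is homozygous when the clonal
paternal word matches. The value is bounded by 1/2. Realized losses are
binomial: `createWorkers()` and colony-derived `createVirginQueens()` form
the requested number of eggs, remove csd homozygotes, and do **not** top the
brood back up; the queen's cumulative `nHomBrood()` counter is updated on
every brood creation. The classic inbreeding benchmark — a queen mated to
drone sons of her own mother — gives 25% expected homozygous brood, which
the test suite checks both analytically and against the binomial
distribution of survivors.

Each egg samples its father uniformly from the spermatheca; no paternity
skew is modelled (nothing in the data we target constrains it).

# Castes, colonies, events

Base virgin queens are created one per founder by two meioses of that
founder's diploid genome; the second gamete is redrawn until its csd word
differs from the first, so base females are viable by construction. (This
"selfing" start inflates base-population inbreeding relative to the
founders — see the note on trait scaling below.) Drones may be created from
virgin queens only to bootstrap a simulation before any queen exists;
workers never reproduce.

Colony events follow beekeeping semantics:

* `swarm(p)`: the old queen leaves with `round(p * nWorkers)` workers (the
  swarm keeps the colony id — identity follows the queen); the remnant
  keeps the rest plus all drones and rears fresh virgin-queen daughters of
  the departed queen. Both halves are non-productive and flagged swarmed.
* `split(p)`: the beekeeper removes workers into a new, non-productive hive
  that also receives reared virgin queens; the queen's side (the remnant)
  keeps the id and its production status.
* `supersede()`: the queen is removed and replaced by daughter virgin
  queens; production continues.
* `collapse()`: flags the colony dead but keeps all members readable (for
  post-mortem genetic analysis); any further mutating operation errors.
* `downsize(p)` (default p = 0.85): winter preparation — removes a worker
  share plus all drones and virgin queens; the queen stays.
* `combine(strong, weak)`: the strong colony absorbs the weak colony's
  workers and drones and keeps its own queen and id; the weak queen is
  discarded.

Worker shares are rounded with round-half-to-even — deterministic and
unbiased. Event proportions and caste counts accept samplers
(`makeCountSampler()`, `makeProportionSampler()`); the strength-aware beta
sampler has mean `strength / (strength + refStrength)`, a monotone function
of colony strength, so stronger colonies swarm with a larger worker share.

Counts not printed in the sources this package follows are package defaults,
chosen to be configurable demonstrations rather than biology: 100 workers
and 10 drones per built-up demo colony, 10 virgin queens reared per event,
15 mates per queen, swarm/split/downsize proportions 0.5 / 0.3 / 0.85.

`MultiColony` operations apply colony-by-colony in order, so a vectorized
call is exactly the sequence of scalar calls — a property the test suite
relies on. Selection among colonies (`selectColonies()`) ranks by a supplied
value vector with deterministic smaller-id tie-breaks.

# Quantitative genetics

Traits are strictly additive: `gv = intercept + sum(effect * dosage)` over
QTL sampled uniformly among tracked sites (excluding the csd window).
Per-QTL effect vectors for multiple traits are drawn from a multivariate
normal with the user's genetic correlation matrix; haploid drones are scored
as doubled haploids (dosage 0/2) so all values share the diploid scale.
Dominance and epistasis are out of scope — the statistical decomposition of
genetic values in a haplodiploid, colony-structured population is an open
methodological question that this package deliberately leaves to future
work.

**Scaling.** Effects are centred and scaled so that the *base virgin-queen
population* hits the requested trait means and variances. This choice
matters: base virgin queens carry two gametes of a single founder, which is
one generation of selfing (inbreeding coefficient 1/2) and inflates additive
variance by about half relative to the founders themselves. Scaling against
the founders would therefore miss the targets systematically. `addTraitA()`
simulates an internal calibration sample of selfed-founder offspring
(at least 400) and solves for the per-trait scale and intercept; the user's
actual base population then matches the targets up to Monte-Carlo noise.
With few, partially linked QTL the *realized* genetic correlation of a
single replicate scatters noticeably around the target; the tests therefore
average over 20 replicates.

Phenotypes are `gv` plus a multivariate normal environmental deviate
(variances `varE`, correlations `corE`), redrawn on every `setPheno()`
call. The default colony value is
`queenEffect(queen) + sum(workerEffect(workers))` — linear, order-invariant,
and additive under worker-set union; a mean-based variant and fully custom
mapping functions are supported for phenotypes where the additive model is
contested (e.g. defensive behaviour).

# Genomic data

`get*Haplo()` / `get*Geno()` extract haplotype and dosage matrices for
segregating sites, QTL, or SNP-chip loci (chips are sampled disjoint from
QTL and the csd window), for any population, colony caste, or apiary, with
`individual_haplotype` row labels and `chromosome_locus` column labels.
Drones appear once in haplotype output but as 0/2 dosages in genotype
output, keeping genotype matrices ploidy-uniform. `calcGRM()` implements the
VanRaden method-1 genomic relationship matrix, `Z Z' / (2 * sum(p(1-p)))`
with frequencies from the supplied matrix by default (base-population
frequencies can be passed explicitly).

# Reproducibility and numerical choices

One root seed (in `newSimParamBee()`, or the `seed` of a run configuration)
drives R's RNG; a simulation trace is exactly reproducible given the seed
and the call sequence, and the demo program writes byte-identical outputs
for identical configurations. Degenerate inputs are handled explicitly:
zero-length chromosomes transmit whole parental haplotypes; zero-count
requests return empty populations; monomorphic-only dosage matrices are
rejected by `calcGRM()`; `truncPoisson` samplers use the inverse-CDF form so
they never return zero.

Problem sizes in the examples, tests, and the demo program (tens of sites,
colonies of tens to a hundred workers, apiaries of three) are chosen for
fast demonstration; they are two to three orders of magnitude below real
colonies, and nothing in the implementation depends on them.

# What the synthetic data does and does not show

The built-in coalescent emulates neutral divergence of three subspecies with
uniform-rate recombination and no selection, migration, or recent pedigree
structure; csd allele frequencies are made uniform by construction rather
than by simulating balancing selection. Tests passing on such data validate
the *mechanisms* — inheritance, filtering, event bookkeeping, value
calculation — not the realism of any particular population. Analyses whose
conclusions depend on realistic linkage disequilibrium, allele-frequency
spectra, or demographic history should import real haplotypes instead.

# Known limitations

* No spatial model: DCAs pool drones regardless of colony location, and no
  environmental gradients exist (colony locations are stored but unused).
* No laying workers, drifting, robbing, disease, or mortality other than
  the collapse event; no brood age structure within a season.
* No mutation after the founders; allele diversity can only decrease.
* Additive traits only; no dominance/epistasis and no breeding-value
  decomposition.
* The demographic stand-in behind the founder simulator is not calibrated
  to real subspecies data.
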