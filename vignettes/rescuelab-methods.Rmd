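---
title: "Models and methods behind rescuelab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rescuelab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescuelab)
```

rescuelab simulates and analyses a long-term genetic-rescue experiment of
the kind run with *Drosophila melanogaster*: a large, genetically diverse
laboratory base population (BP) maintained as 32 bottles of 80 flies under
circular mixing; thirty populations of 50 individuals (N50) founded from
it and kept for 31 generations, long enough for substantial purging of
partially recessive deleterious variation; and, from each surviving N50,
three sets of lines of eight individuals (N8) followed for 33 generations —
a non-rescued control, lines rescued with single males from another N50 at
line generations 2 and 3, and lines rescued with BP males. The package
provides the forward-time simulator of this design and the estimators used
to analyse such experiments: the inbreeding depression rate with bootstrap
errors, diversity statistics (nucleotide diversity, Watterson's theta,
heterozygous positions, Tajima's D), a sliding-window runs-of-homozygosity
(ROH) caller with a false-positive-controlled minimum-SNP rule,
derived-allele load profiles, and line-survival summaries.

## The genetic model

Individuals are diploid over a set of biallelic loci laid out on four
autosomal arms (2L, 2R, 3L, 3R) spanning 110 Mb. Fitness is multiplicative
across loci: a deleterious allele with selection coefficient $s$ and
dominance $h$ multiplies fitness by $(1-hs)$ in heterozygotes and $(1-s)$
in homozygotes. Three locus classes are simulated:

* **Deleterious** loci draw $s$ from a gamma distribution (shape 0.33,
  mean 0.05, truncated to $(0,1]$) with dominance declining with severity,
  $h(s) = 0.5\,e^{-13 s}$, and arise at 0.2 new mutations per gamete per
  generation. These magnitudes follow the standard Drosophila
  mutation-parameter literature; the package's claims are directional, not
  calibrated to a particular mutation-accumulation estimate.
* **Lethals** ($s = 1$, $h = 0.02$) arise at 0.015 per gamete and carry
  most of the load expressed under fast inbreeding.
* **Lab-adaptation** loci (50, unlinked) carry beneficial alleles with
  $s = 0.1$, $h = 0.5$ and initial frequency 0.02: alleles advantageous in
  the laboratory environment that were rare at capture. They implement the
  hypothesis that a large population adapts to captivity faster than small
  derivatives, in which rare adaptive alleles are easily lost at founding.

Neutral loci carry the annotation categories used by the load module.
Standing variation at founding uses the deterministic mutation–selection
balance approximation ($q \approx u/(hs)$, or $\sqrt{u/s}$ under weak
dominance) for selected loci and the $1/q$ equilibrium spectrum for
neutral loci, rather than a long burn-in; this keeps desk-scale replicates
affordable, at the cost of ignoring linkage disequilibrium present in a
real equilibrium population.

New deleterious and lethal mutations are recurrent over a finite,
pre-allocated locus set (the per-gamete Poisson rate spread across loci)
instead of an infinite-sites scheme, so arrays stay fixed-size.
Recombination is modelled as Poisson crossovers along a 100-kb-bin genetic
map (mean 2 cM/Mb, suppressed toward arm ends), with free assortment
between arms; both sexes recombine. The crossover kernel is compiled code,
as is usual for forward simulators.

## Demography and rearing

Each generation, every female is mated to a male of her group drawn
uniformly at random — this is what makes a rescue male, competing with the
four resident males for virgin females, sire one fifth of the progeny on
average. Juveniles per female are Poisson(`p_max`, default 90), the reared
pool is capped at `rearing_capacity` (default 5) times the census — vial
crowding — and each juvenile survives to adulthood with probability equal
to its fitness, which is where selection acts. Breeders are then drawn
uniformly from the survivors (additional batches are reared when viability
losses leave a sex short, so census sizes are conserved). A line is extinct
when its progeny pool is empty or contains a single sex only. The marginal
offspring number per pair is therefore Poisson with mean `p_max` times
mean offspring viability.

Pedigree inbreeding is tracked exactly through a kinship-matrix recursion
for every N50 population and line (cross-checked in the test suite against
an independent recursive pedigree implementation). The effective size
realized by this mating system is estimated from the pedigree itself with
`estimate_ne()`: the probabilities that a random male and female breeder
share a mother or a father are computed from the realized sibship counts,
and the asymptotic decay rate of the dioecious mean-kinship recursion
$u_{t+1} = (1-q)u_t + \tfrac{q}{2}u_{t-1}$ converts them into an
inbreeding-rate $N_e$. Because mates of the founder generation cannot yet
be related, the first cohort has $F = 0$ and closed-form comparisons of
the form $F_t = 1 - (1 - 1/2N_e)^t$ are accurate only up to a transient of
about one generation; the validation suite compares at the horizon, where
the transient is within Monte-Carlo error of 20 replicates. For lines
founded from related N50 individuals the closed form does not apply at all
(founder kinship is already high), which is why drift checks run on the
N50 tier and on freshly founded test populations.

## Productivity assays and the depression rate

The simulated assay mirrors the paired-vial design: in the outbred scheme
the evaluated offspring descend from crosses of unrelated pairs (design
$F = 0$); in the inbred scheme a full-sib couple is mated so the evaluated
eggs carry design $F = 0.25$ relative to their population. (The
experimental protocol reaches the same expected $F$ through full-sib then
cousin matings so that mothers and eggs are equally inbred; since the
model has no maternal effects, the single full-sib mating is equivalent.)
Vial counts are Poisson with mean `p_max` times mean offspring viability,
under mean-centred multiplicative lognormal vial noise (SD 0.3 on the log
scale), which reproduces the right-skew of real productivity
distributions. Default vial numbers (81 outbred, 56 inbred) are the sizes
of the real late-generation assay.

The inbreeding depression rate is estimated as
$\delta = \ln(P_O/P_I)/F$ — the proportional decline of the trait mean per
unit inbreeding. Its bootstrap SE resamples the two schemes independently
with replacement at their original sizes (1000 replicates by default);
independent resampling matches the estimator's structure, and replicates
with a non-positive resampled mean are redrawn and counted rather than
clamped. The calibration test shows the bootstrap SE within a few percent
of the Monte-Carlo SD of $\delta$ over fresh datasets. The companion
`expected_inbreeding()` exposes $F_t = 1-(1-1/2N_e)^t$ and the model-based
projection $w_{rel} = e^{-\delta F_t}$; note that combining a
base-population $\delta$ near 2 with $N_e = 25$ under this mapping does
*not* reproduce the "36%" net-decline projection sometimes quoted for such
designs (it yields roughly 64%), so the function reports the components
and leaves the projection to the user. Scheme means are compared with a
two-sided Mann–Whitney test: exact enumeration when both samples are small
(min(n, m) <= 8) and tie-free, the tie- and continuity-corrected normal
approximation otherwise.

## Diversity statistics

All statistics treat the data as polarized biallelic dosages from $n$
haploid sequences (two per sequenced male, autosomes). Nucleotide
diversity is the unbiased per-site mean pairwise difference
$2d(n-d)/(n(n-1))$ averaged over analysed sites, with per-site sample
sizes under missingness. Watterson's $\theta = S/a_1$ corrects the
segregating-site count by the number of sequences; for biallelic data the
total mutation count (Eta) equals $S$, and the package reports integer $S$
(fractional Eta values in some published tables come from upstream
multi-allelic handling and are not reproduced). Tajima's D uses the
canonical constants at the modal per-site sample size and is undefined at
$S = 0$; sites with more than 15% missingness are expected to be removed
upstream by the loader's filter policy.

## ROH calling

The caller follows the PLINK-style scanning scheme: windows of 30
consecutive SNPs are homozygous if they contain at most 1 heterozygous and
5 missing calls (the scanning tool's documented defaults; the four
parameters changed in the source analysis — window 30, threshold 0.05,
gap 50 kb, density 1 SNP/50 kb — are the package defaults, with the
published alternatives available as presets); each SNP's hit rate is the
fraction of covering windows that are homozygous; SNPs at or above the
0.05 threshold are run-eligible; maximal eligible runs are split at gaps
over 50 kb and filtered by the minimum SNP count, the 100-kb minimum
length, and the density rule, in that order (the order matters only for
pathological inputs and is fixed for reproducibility). Segment bounds are
the first and last SNP, 1-based inclusive. The minimum SNP count uses the
false-positive-controlled rule
$l = \lceil \ln(\alpha/(N_{SNP} N_{ind})) / \ln(1-\bar h) \rceil$ with
$\alpha = 0.05$ and the observed mean heterozygosity $\bar h$ (ceiling, so
published-style integers such as 32 and 24 arise from the continuous
formula); the mean heterozygosity behind published minimum counts is
typically not printed, so the rule is validated on constructed inputs.
$F_{ROH}$ divides the summed ROH length by the analysed genome length
(110 Mb). The caller is verified against a brute-force window enumerator
on hundreds of random matrices.

Note that ROH calling needs realistic SNP density (one SNP per few
hundred bp in the real data); the reduced simulated genomes used for fast
validation are far sparser than the 100-kb minimum length requires, so ROH
analyses of simulator output should use configurations with dense neutral
loci.

## Derived-allele load

The derived count of an individual in an annotation category is the sum of
its derived-allele dosages over that category's sites, including sites
fixed for the derived allele in the sample. Counts are normalised by the
individual's fourfold-synonymous count (a putatively neutral category, so
technical noise cancels) and standardized by the reference line's mean
normalised ratio, making the reference line exactly one in every category.
Line means carry SD/sqrt(n) standard errors (n = sequenced individuals);
a bootstrap alternative was considered and rejected for transparency at
n = 12. Sites are stratified into recombination-rate quartiles from the
100-kb map (top quartile "high", bottom "low"), with ties broken by
genomic position and boundary ties resolved to the lower stratum;
within-stratum profiles re-normalise with that stratum's fourfold sites
only. Between-line differences are tested with Welch's t on the
per-individual standardized ratios (the published analysis reports
significance without naming a test); a seeded permutation test is provided
as an option.

## Line survival

Survival curves report the percentage of lines not yet extinct at each
generation per treatment. Lines duplicated at generation 7 count as
independent lines from then on; a duplicate inherits its source's
pre-duplication history, which keeps curves non-increasing while matching
the rising line numbers of duplicated designs. Interval extinction rates
divide extinctions in an interval (default: thirds of the 33 generations)
by line-generations at risk, expressed as a percentage; published
per-third rates of this kind do not state their denominator, so this
definition is documented and applied consistently to simulated and
observed records rather than matched to any printed value.

## Validation scale and reproducibility

Stochastic validation uses a reduced design — 8 bottles of 20 flies, 5 N50
populations of 20 run for 15 generations, 10 lines per treatment run for
15 generations, a 1,100-locus genome — chosen so that 20-replicate checks
of drift, purging direction and rescue-survival direction complete in
minutes. At this scale the purging signal (lower delta in the N50 tier
than in the BP) appears in about 85% of replicates, and extinction is
rare, so the rescue-survival comparison is dominated by ties; the full
design sharpens both at proportionally higher cost. Every source of
randomness descends from one master seed through counter-based child
seeds per population, line and generation, so identical configurations
reproduce bit-identical results and additional replicates never perturb
existing ones.

What passing these checks shows — and what it does not: the estimators are
exact on their defined inputs (verified against independent oracles and
published summary arithmetic), and the simulator reproduces neutral drift
and the qualitative selection phenomena it models. The generator does not
emulate linkage disequilibrium at founding, maternal effects on
productivity, density-dependent larval competition beyond a rearing cap,
X-linked variation, or sequencing error, so agreement on synthetic data
does not by itself certify behaviour on real sequencing data.

## A small worked example

```{r example, eval = FALSE}
cfg <- reduced_experiment_config()
sim <- simulate_experiment(cfg, mutation_model(), seed = 1)

# depression rates at the line-founding generation
pr <- subset(sim$productivity, population_id == "N50" &
               generation == cfg$n50_generations)
estimate_delta(subset(pr, scheme == "outbred"),
               subset(pr, scheme == "inbred"),
               F = 0.25, n_boot = 1000, seed = 1)

# survival curves per treatment
autoplot(survival_curve(sim$survival, horizon = cfg$n8_generations))

# diversity of the two sequenced line snapshots
lapply(sim$snapshots, diversity_summary)
```
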