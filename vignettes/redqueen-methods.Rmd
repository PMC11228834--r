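---
title: "Constructionist simulations of multiallelic selection in a deteriorating environment"
author: "redqueen package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructionist simulations of multiallelic selection in a deteriorating environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redqueen)
```

## The question

Classical analyses of viability selection at a single diploid locus ask which
fixed sets of genotype fitnesses admit a stable polymorphism of all $n$
alleles.  For randomly drawn viabilities the answer is bleak: the fraction of
fitness sets whose interior equilibrium is both feasible (all $p_i^* > 0$) and
stable collapses with $n$ — about a third for $n = 2$, a handful per $10^5$
sets at $n = 5$, essentially none at $n = 6$ (the `random_set_scan()` module
reproduces this baseline).  That smallness has often been read as evidence
against selective maintenance of the abundant allelic variation seen in
nature.

The *constructionist* rejoinder is that populations do not sample parameter
space uniformly: they are carried into its unusual corners by their history.
If one novel mutant arises each generation, most die instantly, a few invade,
and occasionally a resident is displaced, then the number of alleles — and the
structure of the fitness sets actually realised — evolves.  This package
simulates that process, and adds a deteriorating ("Red Queen") environment in
which the viabilities of *extant* genotypes decay each generation while
novel mutants arrive undecayed, so that standing variation is perpetually
running to stand still.

## The model

One autosomal locus in a diploid population with discrete, non-overlapping
generations.  Viability selection follows the standard recursion

$$\bar w\, p_i' = p_i \sum_{j=1}^{n} w_{ij} p_j,
  \qquad \bar w = \sum_{i,j} w_{ij} p_i p_j,$$

where $w_{ij} = w_{ji} \in [0,1]$ is the viability of the phenogenotype
$A_iA_j$.  A rare mutant allele $A_{n+1}$ invades an infinite population
exactly when its marginal fitness $m_{n+1} = \sum_j w_{j,n+1} p_j$ exceeds
$\bar w$ (`can_invade()`), and one selection step multiplies its frequency by
$m_{n+1}/\bar w$ — an equivalence that is enforced as a property test.

**Mutant fitness generation.**  Two generators are provided:

* *uniform*: every new viability $w_{i,n+1}$ is an independent draw from
  $U[0,1]$; the run starts from a single allele with $w_{11} = 0.5$.
* *generalized dominance*: each allele carries a primary effect
  $X_i \sim U[0,1]$, motivated by the fact that a genotype's product is
  largely determined by its alleles' own contributions, and
  $$w_{ij} = \alpha\,(X_i + X_j) + (1 - 2\alpha)\,Y_{ij},$$
  with interaction effects $Y_{ij} \sim U[0,1]$ drawn once at mutant creation
  and folded into $w$ (never stored).  The weight $\alpha \in [0, 1/2)$
  (default $1/3$) induces a correlation
  $\alpha^2 / (1 - 4\alpha + 6\alpha^2)$ between viabilities of genotypes
  sharing an allele — exactly $1/3$ at $\alpha = 1/3$, and $0$ at
  $\alpha = 0$, where the two generators coincide in distribution.  The
  single-allele start is then $w_{11} = 2\alpha X_1 + (1-2\alpha) Y_{11}$.

**Environmental decay.**  Either every viability is multiplied by a constant
$d \le 1$ each generation (with primary effects decaying alongside,
$X_i' = d X_i$, so that future mutants combine decayed residents with fresh
interaction draws), or each distinct genotype pair receives an independent
factor $d_{ij} \sim N(\mu, \sigma^2)$, resampled every generation.  The
reference stochastic configuration $N(0.999, 0.001^2)$ leaves 15.87% of
genotypes transiently *improving* ($d_{ij} > 1$) while decaying on average.
Decayed viabilities are clamped into $[0,1]$; the clamp matters only in the
stochastic model, where upward excursions from $w \approx 1$ would otherwise
leave the admissible range.  Under stochastic decay the primary effects are
left unchanged: the random factors attach to genotypes, not alleles, and
there is no per-allele analogue of $d_{ij}$.

**Mutation, drift, extinction.**  Exactly one novel mutant enters per
generation, at frequency $p_0 = 5\times10^{-5}$ (infinite mode) or $1/(2N)$
(finite mode); residents are rescaled by $1 - p_0$.  Finite populations then
draw the next generation as a multinomial sample of $2N$ gene copies, and an
allele sampled to zero copies is extinct immediately.  In infinite
populations, frequencies strictly below $5\times10^{-5}$ are rounded to zero
and the alleles removed; because the cut equals $p_0$, a mutant survives its
first generation precisely when its marginal fitness (weakly) exceeds
$\bar w$.  Survivor frequencies are renormalized to sum to one — the
recursion requires a proper frequency vector, and the removed mass is at most
a few parts in $10^4$.

## The per-generation cycle and its conventions

Each generation applies, in order: (1) environmental decay of extant
viabilities; (2) creation of the novel mutant — fresh viabilities first, then
introduction at $p_0$; (3) deterministic selection; (4) multinomial drift when
finite; (5) extinction.  Two placement conventions deserve comment, since the
verbal model fixes neither:

* **Decay precedes mutant creation.**  A mutant's freshly drawn viabilities
  are therefore not decayed in its birth generation.  This realises the Red
  Queen asymmetry — old genotypes deteriorate, newcomers arrive at full
  strength — which is the mechanism that raises invasion rates under decay.

* **Recording precedes the infinite-mode sweep.**  The trajectory and the
  census count every allele still *present* ($p_i > 0$) after the
  generation's selection (and drift; drift zeros are removed first, as
  extinction by drift is unambiguous).  The sub-threshold rounding sweep is
  then the first thing that acts on these frequencies going into the next
  generation.  The census therefore observes the population at its natural
  observation point — after the generation's dynamics, before the
  housekeeping that prepares the next one — and a census-generation mutant
  that failed to invade is still counted at its sub-threshold frequency.
  Under this convention the long-run census statistics reproduce the
  classical constant-environment benchmark (mean $n \approx 6$ after $10^4$
  generations with uniform fitnesses and $d = 1$); recording after the sweep
  would lower every mean allele count by roughly the one failing mutant per
  generation.  The two conventions have bit-identical dynamics — only the
  observation point moves.

Both the compiled (C++) engine and the pure-R engine implement this cycle
consuming R's random-number stream in exactly the same order, so a common
seed produces the same realization from either path; the test suite asserts
this across all mode combinations.  Replicate batches spawn per-replicate
seeds deterministically from a master seed (`sample.int` under the master
seed), so a `(config, seed)` pair is fully reproducible.

## Census statistics

An allele is *common* when its frequency strictly exceeds 0.01.  The location
of a polymorphism among its common alleles is summarised by

$$I = \sum_{c=1}^{n_c} \left(p_c - \tfrac{1}{n_c}\right)^2,$$

the squared Euclidean distance to the centroid of the simplex; rare alleles
are excluded because they drag the location toward the faces of state space
without being an important part of the polymorphism.  The common frequencies
are renormalized to sum to one before computing $I$: the reference point
$1/n_c$ is the centroid of the $(n_c-1)$-simplex, and the broken-stick null
lives on that full simplex, so comparability requires renormalization (in
practice the rare mass is tiny and the correction negligible).  The null
distribution of $I$ is generated by the broken-stick method — $n_c - 1$
uniform break points on $[0,1]$, frequencies the gaps between adjacent points
— which samples the simplex uniformly; $10^4$ null draws per $n_c$ is the
default and gives the null mean to three digits.

Fitness structure is summarised per census by the *unweighted* means of the
extant homozygote viabilities $w_{ii}$ and of the distinct heterozygote
viabilities $w_{ij}$, $i<j$, with their Pearson correlation taken across
replicates.  Unweighted means describe the fitness *sets* the process has
assembled; frequency-weighted versions would conflate set structure with the
current position on the simplex.

A by-product of the evenness machinery worth flagging: in these simulations
the censused polymorphisms are typically *less* even than broken-stick
chance.  The census states coincide (to numerical precision) with the
feasible, stable interior equilibria of their own common-allele viability
submatrices — they are genuine attractors — but the equilibria assembled by
recurrent invasion frequently carry one or two marginally common alleles
($p^* \sim 0.02$–$0.05$), which inflates $I$ relative to the uniform-simplex
null.  Freshly drawn random *stable* fitness sets, by contrast, have markedly
more even equilibria (mean $I \approx 0.09$ for four alleles, against a null
mean of $0.15$): history selects stranger corners of parameter space than
uniform sampling of stable sets does.

## The equilibrium baseline

For a fixed symmetric viability matrix the interior equilibrium solves
$W p^* \propto \mathbf 1$; `interior_equilibrium()` computes
$p^* = W^{-1}\mathbf 1 / (\mathbf 1^T W^{-1} \mathbf 1)$, flags feasibility
(strict positivity) and stability by the spectral criterion — a feasible
interior equilibrium attracts iff $W$ has exactly one positive eigenvalue,
equivalently iff $p^*$ globally maximises $\bar w = p^TWp$ on the simplex.
The spectral test is cheaper and numerically cleaner than linearising the
map; its equivalence with the dynamics is guarded by a property test that
iterates the recursion from the simplex centre on random 3-allele sets
(`iterate_selection()`, $10^5$-step cap, $10^{-6}$ agreement tolerance) and by
a grid search over the simplex for the maximisation claim.  Matrices with an
eigenvalue of magnitude below $10^{-10}$ are treated as degenerate and
redrawn in the scan — a measure-zero event for continuous draws.
Boundary equilibria are deliberately out of scope: the scan asks only
whether *all* $n$ alleles are maintained.

## Numerical and design choices

* Frequencies are renormalized at every step that can disturb the sum;
  property tests assert $|\sum p - 1| < 10^{-12}$ across all operations.
* The extinction cut is strict (`p < threshold` removed), so a mutant whose
  marginal fitness exactly equals $\bar w$ survives; ties are measure-zero.
* $\bar w = 0$ raises an error rather than being silently repaired; it cannot
  occur with $U[0,1]$ viabilities except on a null set.
* The RNG is R's default Mersenne Twister through the standard API; any
  seedable high-quality generator would do, since results are statistical
  rather than bit-reproducible against any particular historical stream.
* TSV output serialises numbers at 17 significant digits, so
  write-then-read round trips are exact; census tables carry the full
  configuration as `#` manifest lines.

## What the generator emulates, and what it does not

The simulator *is* the data generator: all inputs are parameters, and the
study conditions are its defaults — runs of $10^4$ generations from a single
allele, one mutant per generation, $p_0 = 5\times10^{-5}$ or $1/(2N)$,
common cut $0.01$, $\alpha = 1/3$, decay grid
$d \in \{0.995, 0.999, 0.9999, 1\}$, $N \in \{10^3,\dots,10^6\}$.  It
captures single-locus viability selection with recurrent mutation and drift,
and nothing else: no linkage or multi-locus structure, no fertility or sexual
selection, no frequency dependence or explicit coevolution (decay is a fixed
environmental clock, not a feedback), no mutational spectrum (every mutant's
fitnesses are exchangeable draws), and non-overlapping generations.  Passing
tests therefore validate the arithmetic and the stated protocol, not the
biological realism of any of those idealisations.

Where test and example problem sizes are smaller than a production study —
replicate batches of 200 rather than $10^4$, scans of $10^5$ random sets —
the choice reflects what a desk machine executes in seconds while keeping
Monte Carlo standard errors (about $0.1$–$0.2$ alleles on a mean of 6–9)
well inside the tolerances asserted; all sizes are parameters, and nothing
in the code is specific to the reduced scale.

## Known limitations

* Under constant decay $d = 0.9999$ the long-run mean census allele number
  settles near $8.3$ (200-replicate batches, seeds varied), noticeably above
  the constant-environment value ($\approx 6.0$) but below the steepest
  published accounts of the same scenario; the discrepancy resists every
  protocol permutation we examined (decay placement, census timing,
  lingering-mutant rules) and may trace to generator or implementation
  details of historical codes that their descriptions do not fix.
* The evenness finding above (censuses less even than the broken-stick null)
  is robust in these simulations across decay rates and drift, and is the
  package's computed result; readers comparing against accounts that report
  the opposite should check which ensemble of fitness sets — constructed or
  randomly sampled — is being conditioned on.
* Runs are single-threaded; replicate batches are embarrassingly parallel
  but the package deliberately leaves scheduling to the caller to keep seed
  semantics transparent.

## A worked miniature

```{r example}
cfg <- sim_config(generations = 2000,
                  decay = decay_model("constant", d = 0.999))
sim <- run_simulation(cfg, seed = 1)
sim
tail(sim$trajectory, 3)

cb <- run_replicates(cfg, replicates = 20, seed = 1)
summary(cb)

set.seed(1)
random_set_scan(3, 2000)
```
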