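---
title: "Genetic cues of relatedness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic cues of relatedness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gencue)
```

## The model

`gencue` studies social evolution in a population spread over two habitats
that differ in social group size, and hence in within-group relatedness.
Groups in habitat $i$ are founded by $N_i$ haploid individuals drawn from
the habitat's dispersal pool; founders then reproduce asexually, each of the
$N_i$ offspring group members being a copy of a uniformly chosen founder.
Two offspring group members therefore share a founder -- are identical by
descent since founding -- with probability

$$r_i = 1/N_i.$$

The offspring play a public-goods game: an individual investing $z \in
[0,1]$ in a group with mean investment $\bar z$ receives payoff

$$w_i(z, \bar z) = W_i + b_i \bar z - c_i z^2,$$

a linear shared benefit against a quadratic private cost. Payoffs act as
fecundities, so they are truncated at zero wherever they enter the life
cycle (the raw quadratic can be negative for extreme $(z,\bar z)$; all
reference equilibria sit in the positive region, and truncation is
reported when active). Offspring migrate between habitats (rate $m_{ji}$
from habitat $i$ to $j$), mate at random within the dispersal pool through
a brief sexual phase with recombination, and found the next generation of
groups; each habitat is regulated to a fixed census capacity. The census
point is after group formation, just before the game.

A *cue locus* carries two alleles $x_1, x_2$ that induce investment
phenotypes $z_1, z_2$. Spatial heterogeneity can hold this polymorphism in
a migration--selection balance, in which case carrying $x_k$ is
statistically informative about the carrier's habitat -- the allele is a
*genetic cue* of relatedness. *Modifier loci* alter the phenotypes the cue
alleles induce; their linkage to the cue locus (recombination rate
$\rho \in [0, 0.5]$) determines whose evolutionary interests they serve.

### Rare-mutant payoffs in closed form

Because the benefit is linear in $\bar z$, all expectations over group
compositions collapse to closed forms. A rare mutant lineage founds groups
with exactly one mutant among the $N$ founders; the number $K$ of mutant
offspring in such a group is Binomial$(N, 1/N)$, and a randomly sampled
mutant individual sits in a group size-biased by $K$, giving the self-weight
$E[K^2]/E[K] = 1 + (N-1)r$. The expected payoff of a random rare mutant
expressing $z'$ is

$$\bar w_i' = W + \frac{b}{N}\Big[\tfrac{2N-1}{N} z' +
  \big(N - \tfrac{2N-1}{N}\big)\tilde z_i\Big] - c z'^2,$$

with $\tilde z_i = p_{i1} z_1 + p_{i2} z_2$ the mean resident phenotype.
Its derivative at the resident,

$$d_{ik} = \frac{b_i}{N_i}\big(1 + (N_i - 1) r_i\big) - 2 c_i z_k,$$

is the per-habitat ingredient of all selection gradients. The same
size-biasing gives the expected payoff of a random *resident* of cue class
$k$; both closed forms are verified against brute-force enumeration over
all founder draws and offspring copy-assignments for $N \le 6$
(`enumerate_mutant_payoff()`, `enumerate_class_payoff()`), and the
coefficients of $z$ and $\tilde z$ sum to one exactly.

### Resident dynamics and invasion analysis

`find_resident_equilibrium()` iterates the deterministic life cycle over
the four classes (habitat, cue allele) to its fixed point. A mutant
modifier that makes allele $x_k$ induce $z_k'$ instead of $z_k$ is then
analysed through its $4\times4$ projection matrix with entries

$$A_{(j,l),(i,k)} = \phi_j\, m_{ji}\, \bar w_i'(z_k')\, h_{jlk},
\qquad h_{jlk} = (1-\rho)\delta_{lk} + \rho\, p_{jl},$$

where $\phi_j$ is the founding probability in pool $j$ and $h$ is the cue
inheritance: with probability $1-\rho$ the offspring inherits the parental
cue allele, otherwise it receives a random allele from the pool. Invasion
fitness is $F = \log\lambda$ of this matrix. Two structural identities
anchor the construction: the resident-as-mutant matrix has $\lambda = 1$
with the equilibrium class abundances as right eigenvector (verified to
$10^{-8}$ over random parameter draws), and the reproductive-value form of
the selection gradient,

$$\frac{\partial F}{\partial z_k'} =
  V_{1k}\, d_{1k}\, p_k\, q_{1k} + V_{2k}\, d_{2k}\, p_k\, q_{2k},$$

equals central finite differences of $F$ to $10^{-6}$. Here $q_{ik} =
n_{ik}/(n_{1k}+n_{2k})$ is the probability of being in habitat $i$ given
linkage to $x_k$ (the Bayesian information content of the cue), $p_k$ the
dilution factor, and $V_{ik}$ the offspring reproductive values assembled
from the left Perron eigenvector.

At full linkage the projection matrix is block-diagonal in the cue-allele
lineages and its leading eigenvalue is a double root (both lineages are
stationary at an interior equilibrium), so eigenvectors from a dense solve
are arbitrary mixtures. `selection_gradient()` therefore switches at
$\rho = 0$ to the per-allele $2\times2$ habitat blocks, whose sensitivities
are well defined; the finite-difference oracle does the same.

## Equilibrium search and the collapse of the polymorphism

A dimorphism $(z_1, z_2)$ is *protected* when each phenotype, as a rare cue
allele, invades a monomorphism of the other. Because a cue allele is fully
linked to itself, this test uses the 2-class habitat-only matrix and does
not involve $\rho$ (`coexistence_test()`). Evolutionary equilibria are
found by following the selection gradient in small projected steps through
$(z_1,z_2)$-space, re-solving the resident equilibrium at each step
(`ascend_to_equilibrium()`), with a Newton polish once the gradient is
small.

Three terminal states are distinguished: `converged` (gradient norm below
$10^{-6}$, default step $0.01$ on the phenotype scale), `collapsed` (the
path exits the protected region and the resident loses one cue allele),
and `merged` (the pair contracts onto the diagonal $z_1 = z_2$). Pairs
closer than $10^{-3}$ -- or closer than $5\times10^{-3}$ and still
contracting after ten consecutive steps -- are classified as merged: below
that separation the dimorphism is numerically and biologically
indistinguishable from a monomorphism at the singular strategy. For
habitat-symmetric game parameters the monomorphic singular strategy has the
closed form $z^* = b\,[\,(2N_1-1)/N_1^2 + (2N_2-1)/N_2^2\,]/(4c)$
($= 0.42375$ at the reference parameters), independent of $m$ and $\rho$;
`monomorphic_singular_strategy()` computes it from the matrix machinery and
recovers the closed form to $10^{-8}$.

At the reference parameters the gradient-path outcome is dimorphic up to
$m = 0.125$ (at tight linkage) and monomorphic -- merged or collapsed, for
every $\rho$ -- from $m = 0.15$ on. This *evolutionary* threshold is the
meaningful notion of polymorphism loss: the static mutual-invasibility
region is still non-empty at $m = 0.15$ (and indeed at $m = 0.20$; it
empties only near full mixing), but modifier evolution steers the
dimorphism out of it. `collapse_threshold()` implements the scan; it
reports the smallest migration rate at which every gradient path ends
monomorphic. Tight linkage is the case most favourable to divergence, so
$\rho = 0$ locates the threshold and additional $\rho$ values confirm its
independence of linkage.

### Numerical choices

The resident equilibrium reduces to two per-habitat allele frequencies.
The solver combines plain fixed-point iteration, vector-Aitken
extrapolation of the slow geometric mode, and a damped Newton iteration
with two safeguards worth documenting. First, the monomorphic boundaries
are always fixed points of the map; whether they attract is decided
analytically up front (growth eigenvalue of the missing allele when rare),
and iterates are clamped just inside any repelling boundary so that
accelerated steps cannot land on an absorbing state that the dynamics
would never reach. Acceptance of accelerated steps is judged on a
per-capita-scaled residual, since near a repelling boundary the raw
residual is small although the point is wrong. Second, the residual is not
monotone along curved Newton paths, so a watchdog accepts the full Newton
step after repeated rejections provided the destination is itself close to
equilibrium on the scaled measure. Near-diagonal dimorphisms are almost
neutral; their slow mode cannot be pinned beyond about $10^{-9}$ in double
precision, and residuals below that are treated as converged (the default
target is $10^{-12}$).

The founding ratios $\phi_j$ are reported as capacity/pool ratios and can
exceed one; only products $\phi_j \bar w_i$ enter any result, so the
absolute fecundity scale cancels throughout.

## The individual-based simulator

`run_simulation()` executes the exact stochastic counterpart of the life
cycle -- per-group game, fecundity-proportional multinomial offspring
production, per-offspring migration, random mating in the pool with
per-locus recombination relative to the cue locus, founder sampling to
capacity, one asexual within-group generation -- for populations of
haploid individuals carrying the cue allele and a real-valued modifier
genome. The core loop is compiled (Rcpp) and driven by R's RNG, so a seed
fixes the trajectory bit-for-bit.

The genotype-phenotype map is the sigmoid liability model
$z = 1/(1 + e^{-(a_0 + a_g x)})$ with allelic effect values $x_1 = -1$,
$x_2 = +1$ at the cue locus; the symmetric coding keeps $a_0$
interpretable as the liability midpoint. Four architectures determine
$a_0$ and $a_g$ (`cue_architecture()`): **A** -- single $a_g$ locus at
recombination $\rho$ to the cue, $a_0$ fixed; **B** -- single evolvable
loci for both $a_0$ and $a_g$; **C** -- $a_0$ as the difference between
the summed non-negative expressions of five positive- and five
negative-effect unlinked loci, $a_g$ from five unlinked additive loci;
**D** -- as C plus two unlinked threshold loci capping each expression
sum, $a_0 = \min(S^+, T^+) - \min(S^-, T^-)$, a concrete reading of an
expression-limit mechanism.

Choices that the analytical model does not pin down:

* **Mutation.** Modifier loci mutate at $5\times10^{-3}$ per locus per
  gamete with a zero-mean Gaussian kernel of s.d. $0.2$; the cue allele
  flips at $10^{-4}$. Small enough not to distort equilibria, large enough
  to supply variation at the reduced scale.
* **Fixed baseline of architecture A.** $a_0 = \mathrm{logit}(z^*)$, so
  the sigmoid midpoint sits at the monomorphic singular strategy and the
  two cue alleles can reach phenotypes on either side of it.
* **Initial conditions.** Cue alleles start at frequency $1/2$ in both
  habitats; $a_g$ starts at $1.5$, placing the initial dimorphism
  $(0.14, 0.77)$ inside the protected region near the low-migration
  equilibria, so that runs measure the stationary state rather than a
  long approach transient.
* **Scale.** The default experiment uses $4\,000$ individuals for
  $5\,000$ cycles with 10 replicates (the polymorphism-transfer experiment
  runs $20\,000$ cycles, since the transfer completes within the first
  quarter of that horizon); summaries average the final 20% of recorded
  points. A `paper` scale of $40\,000 \times 40\,000$ is available through
  the command-line wrapper for full-size runs.

Agreement with the analytic engine is checked per condition: where the
analytic outcome is a dimorphism, replicate-averaged per-cue-allele mean
phenotypes are compared with $(z_1^*, z_2^*)$; where the analytic outcome
is merged (e.g. $m = 0.10$, $\rho = 0.5$), replicates are expected to lose
the cue polymorphism, per-allele means become undefined, and the
population mean is compared with the singular phenotype.

What the simulator emulates is the model's own finite-population version,
not field data: fixed capacities, discrete non-overlapping cycles, a
strictly brief sexual phase, and free recombination between all modifier
loci in the multilocus architectures. Passing tests therefore show
consistency of the stochastic and analytic treatments of the same
idealised life cycle, and say nothing about demographic stochasticity,
overlapping generations or linkage disequilibrium among modifiers in real
systems.

### The polymorphism transfer and its detection

At $m = 0.10$ with free recombination, unlinked modifiers favour a nearly
merged dimorphism; once they achieve it, selection on additive
determinants of $a_0$ turns disruptive and the polymorphism is transferred
from the cue locus to the $a_0$ locus, whose alleles become the new cue.
`transfer_signature()` scores an end state as transferred when (i) the
$a_0$ values split into two clusters (2-means, both weights $> 0.15$,
centres $> 1$ apart), (ii) the original cue locus has collapsed (minor
allele frequency $< 0.1$), (iii) the cue locus explains less than 5% of
liability variance -- assessed only while the locus is genuinely
polymorphic (minor allele at 1% or more), since at mutation-boundary
frequencies a handful of fresh mutant carriers are outliers rather than
population structure -- and (iv) the phenotype distribution is
multimodal.
Criterion (iii) deserves a note: once the cue locus fixes, only the sum
$a_0 + a_g \bar x$ is visible to selection, so the numerical value of
$a_g$ performs a neutral random walk along that ridge and, at reduced
population size, wanders far from zero well within the run. The decay of
$a_g$ toward zero *during* the transfer is visible in the recorded
trajectory; the identifiable end-state content of "$a_g$ became
irrelevant" is that the cue locus no longer predicts the liability, which
is what (iii) measures.

## Information metrics

`empirical_cue_information()` turns a (habitat $\times$ cue allele) table
-- analytic abundances or a simulated census -- into the conditional
habitat probabilities $q_{ik}$ and the mutual information between cue
state and habitat in bits (at most 1 bit for two habitats).
`habitat_logistic_regression()` fits habitat-1 membership on the liability
by maximum likelihood; complete separation, which the near-step
regressions of strongly diverged populations approach, is detected and
reported with the slope capped at $\pm 50$. For continuous (multilocus)
genotypes, runs are ranked by the mutual information between the liability
discretised into 20 equal-width bins and the habitat
(`information_ordering()`); the binning is a documented operationalisation
-- no formal information measure is prescribed by the underlying theory --
and 20 bins keep the estimator's positive bias small relative to the
between-architecture differences at the census sizes used.

## A worked tour

```{r tour, eval = FALSE}
mod <- cue_model(m = 0.05, rho = 0)      # reference parameters
eqm <- ascend_to_equilibrium(c(0.2, 0.6), mod)
eqm$z                                    # dimorphic equilibrium
sweep_equilibria(mod, m_values = c(0.01, 0.05, 0.10),
                 rho_values = c(0, 0.25, 0.5))
collapse_threshold(mod)                  # 0.15

cfg <- sim_config(cue_model(m = 0.05, rho = 0), "A",
                  pop_size = 4000, cycles = 5000, seed = 1)
sim <- run_simulation(cfg, replicates = 10)
sim$summary

eq <- find_resident_equilibrium(eqm$z, mod)
empirical_cue_information(eq)
```

## Limitations

The analytic engine is specific to two habitats and two cue alleles, to a
benefit linear in the group mean (the closed forms rely on it), and to the
rare-mutant, single-mutant-founder approximation. Boundary equilibria are
flagged rather than analysed; second-order classification of singular
points (branching versus stability) is outside scope -- dimorphisms are
assessed by mutual invasibility only. The simulator's mutation kernel and
initial conditions are package choices documented above, and quantitative
end states of the multilocus architectures (C, D) depend on them; only the
qualitative contrasts between architectures are treated as results.
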