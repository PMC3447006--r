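---
title: "Simulating and analysing divergence selection across ploidies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing divergence selection across ploidies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidysel)
```

## The experiment being modelled

`ploidysel` models a four-generation artificial-selection experiment on
flowering time in fireweed (*Chamerion angustifolium*), a species with
naturally co-occurring diploid and autotetraploid populations. Three groups
are compared: diploids, extant autotetraploids, and neotetraploids newly
synthesized by colchicine doubling of diploids. For each group, a base
population of maternal seed families is reared, the earliest-flowering
plants are selected (two replicate selected lines plus one randomly chosen
control line), selected parents are reciprocally crossed to non-relatives
within their line, and a fixed number of offspring per seed family forms
the next generation. The question is how whole-genome duplication changes
*evolvability*, operationalised as realized heritability

$$b_T = \frac{R_c(T)}{S_c(T)}, \qquad
  S_c = \sum_i S_i, \quad R_c = \sum_i R_i,$$

where $S_i$ is the directional selection differential of round $i$ (cohort
mean minus selected-group mean, among fertile plants, oriented positive
toward earliness) and $R_i$ the per-generation evolutionary response
measured as the change in divergence from the control line.

The raw field data behind the published experiment are not archived, so
the package pairs the estimators with a forward genetic simulator that
reproduces the experiment's design and the statistical structure its
analysis assumes. The published per-line flowering-time means ship as a
packaged fixture (`flowering_means_reference()`), which is enough to
recompute the end-of-experiment divergences exactly.

## The trait model

The simulated trait (days from germination to first flower) is additive
polygenic:

$$P = \mu_{\mathrm{cytotype}} + \beta_{g}
      + \frac{2}{\mathrm{ploidy}} \sum_{\ell}\sum_{j} e_{\ell j}
      + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_E^2).$$

* **Loci.** 100 unlinked biallelic loci of equal effect, founder frequency
  0.5 — an infinitesimal-style default; counts, effects and frequencies
  are configurable per locus.
* **Dosage scale.** Summed allele effects are multiplied by
  $2/\mathrm{ploidy}$, so doubling a genome leaves a genotype's value (and
  the population mean and variance) unchanged at the moment of synthesis;
  cytotype differences in absolute flowering time are carried by the
  baseline term $\mu$ (defaults 44.5 / 47.4 / 50.5 days for diploids,
  neotetraploids and tetraploids, the observed base-population means). A
  raw-dosage mode is available.
* **Environmental blocks.** $\beta_g$ is a per-generation constant shared
  by every plant of a generation (defaults 0, −3.7, +3.5, +1.1, −6.0
  days), mimicking the large rearing-environment swings between
  generations observed in the source experiment. These cancel exactly in
  the control-corrected response; `estimate_response()` is invariant to
  adding any constant to all phenotypes of a generation, and the test
  suite asserts this.
* **Meiosis.** Diploids segregate disomically. Tetraploids draw two of
  their four allele copies per locus uniformly without replacement (random
  chromosome segregation); with probability $\alpha \in [0, 1/6]$ the
  gamete instead carries two copies of one uniformly chosen parental
  allele (double reduction). $\alpha$ defaults to 0; the gamete engine is
  tested against exhaustive enumeration of all unordered draws.
* **Sterility.** Independent Bernoulli per plant: base-population rates of
  35% (diploid), 28% (neotetraploid) and 5% (tetraploid) as observed in
  field-derived and colchicine-converted material, and 6% from generation
  1 onward — later, greenhouse-reared generations of the source experiment
  were far less sterile than their base populations. Sterile plants are
  excluded from every mean, SD, CV and selection, but stay in the
  pedigree.
* **Mortality.** Independent Bernoulli per seedling at rate 0.1, chosen so
  realized family and individual counts land in the observed ranges; only
  realized counts, not a rate, are reported for the original experiment.

### Calibration

`calibrate_architecture(h2, cytotype)` solves for the per-copy effect size
and $\sigma_E$ such that the founder cohort has phenotypic variance
$(\mathrm{CV}\cdot\mu/100)^2$ and narrow-sense heritability `h2`. Under
the dosage scale above, founders drawn at Hardy–Weinberg frequencies have
additive variance $(4/\mathrm{ploidy})\,L\,p(1-p)\,d^2$; neotetraploid
founders synthesized by doubling diploid draws have $2\,L\,p(1-p)\,d^2$
instead, because the duplicated copies are perfectly correlated at
synthesis. Default means and CVs are the observed base values (44.5 days /
7.9% diploid, 47.4 / 6.4 neotetraploid, 50.5 / 12.3 tetraploid).

### Founding the neotetraploid base

`synthesize_neotetraploid()` models colchicine conversion as exact genome
doubling (AB → AABB): deterministic, frequency-preserving, and introducing
no new alleles. For *experiment-level* simulations, however,
`run_experiment()` founds ploidy-4 populations at tetrasomic
Hardy–Weinberg by default (`neo_founders = "hwe"`) rather than from
doubled diploid draws. The reason is a subtlety of doubled genotypes: a
random pair of a doubled founder's four alleles is identical by descent
with probability 1/3, and this excess identity decays by a factor of about
3 per generation of tetrasomic random mating. Base-population heritability
in a doubled cohort is therefore a transient quantity that no later
generation experiences, which makes it the wrong anchor for
estimator-calibration runs. The doubling-based founding remains available
(`neo_founders = "doubled"`) for studying exactly that transient.

## The breeding design

The packaged design configurations mirror the experiment's counts:

| | diploid | neotetraploid | tetraploid |
|---|---|---|---|
| base maternal families × members | 113 × 2 | 29 × 2 | 105 × 2 |
| selected per line per round (M) | 24 | 20 then 24 | 24 |
| partners per parent (k) | 3 | 4 then 3 | 3 |
| seed-family pairs per round | 36 | 40 then 36 | 36 |
| offspring per family | 4 (2 in generation 4) | same | same |

Base maternal families are maternal half-sib by default (fireweed is
highly outcrossing); a full-sib option exists. Selection takes the M
earliest-flowering fertile plants subject to **at most one per maternal
family**, with next-rank replacement — the experiment's rule for limiting
inbreeding. The control line draws M fertile plants at random under the
same family rule, from the entire base population in round one. In the
base round the earliest 2M plants are dealt to the two selected lines with
maternal siblings sent to different lines.

The crossing design pairs each selected parent with exactly k non-relative
partners, producing $Mk/2$ parent pairs; each pair contributes one seed
family with a randomly chosen dam/sire orientation (its reciprocal is the
discarded member of the seed-family pair). Internally the design is built
as $\lfloor k/2 \rfloor$ independent random Hamiltonian cycles plus, for
odd k, a perfect matching, each repaired by random 2-opt or partner swaps
until no mated pair is related. "Non-relative" is checked to pedigree
depth 1 (no shared parent) by default: in a closed line of 24 parents
every individual shares some ancestor with every other within two or three
generations, so a full-depth rule admits no design at all, while the low
mean inbreeding coefficients of the real lines (0.011–0.047) indicate that
only close-kin avoidance was practised. `are_relatives()` itself searches
the entire pedigree by default.

The neotetraploid first round is special, following the experiment: its
small base (41 fertile plants) supports a single selected line of 20, and
a control of 20 drawn from the whole base (the two therefore share
individuals); each parent is crossed to 4 partners, and 35 of the 40
created pairs are sampled to found each of N1, N2 and the control. The
experiment's report is ambiguous between "36 chosen with replacement" (its
text) and "35 of 40" (its table footnote); the package follows the
footnote, sampling 35 without replacement independently per line. The
final generation is reared reduced — 15 families of 2 per line — matching
the common-garden regrow; a full regrow-all-generations mode is out of
scope.

Every (line, round) stage runs on its own named random stream derived from
the master seed, so a run is reproducible byte-for-byte and editing one
part of a config does not scramble unrelated stages.

## Estimators

* **Selection differential.** $S_i$ = fertile cohort mean − selected-group
  mean, on the cohort the selection acted on.
* **Response.** Divergence $D_t$ = control mean − selected-line mean at
  generation $t$ ($D_0 = 0$; the three lines share the base cohort), and
  $R_i = D_i - D_{i-1}$. Control correction, rather than reference to the
  base mean, is essential because the between-generation environmental
  blocks are several times larger than the per-generation response.
* **Realized heritability.** $b_T = R_c/S_c$ at the final generation by
  default; a through-origin regression of $R_c(t)$ on $S_c(t)$ across
  generations is available (`method = "regression"`) since either reading
  of the cumulative definition is defensible. Control lines, with
  $S_c \approx 0$, return a named undefined result rather than a number.
* **Sampling error.** The package uses the drift-free approximation
  $\mathrm{Var}(b_T) = \sigma^2_P\,(1/M + 1/N)/S_c^2$ with t limits on
  $N-1$ degrees of freedom, $N$ the harmonic mean of per-generation cohort
  sizes and $\sigma^2_P$ the base population's fertile-plant phenotypic
  variance. This ignores genetic drift between generations and is
  validated only loosely — the suite reports its ratio to the replicate
  spread of simulated $b_T$ rather than asserting it; treat the analytic
  SE as an order-of-magnitude summary.
* **Variation.** CV = $100\,s/\bar{x}$ on fertile plants, with confidence
  limits from inverting the noncentral t distribution in its
  noncentrality parameter (expanding-bracket bisection to $10^{-8}$); the
  interval is exact for normal data, asymmetric upward at finite n, and
  its coverage is verified at 95% ± 1% by simulation. The sample size
  behind the published intervals is not stated, so comparisons against
  them are soft.
* **Inbreeding.** Wright's path-counting method, with recursive
  common-ancestor inbreeding and path (not ancestor) deduplication,
  applied disomically to all ploidies exactly as the original analysis
  did; a tetrasomic identity generalisation is deliberately not attempted.
  The implementation is checked against a gene-dropping Monte-Carlo oracle
  on both hand-built and simulated pedigrees.

## What recovery runs can and cannot show

Replicated simulations (`run_replicates()`) at the experiment's exact
counts recover the *qualitative* published structure: selected lines
diverge monotonically from controls while absolute means swing with the
environmental blocks; divergence is monotone in configured $h^2$; null
architectures ($\sigma^2_A = 0$) centre $b_T$ on zero; and the small
neotetraploid founder pool accumulates more inbreeding than the diploid
design.

Quantitatively, however, realized heritability under this breeding design
is *not* an unbiased estimate of the founder population's $h^2$, and the
package makes no attempt to force it to be. Two mechanisms attenuate it:

1. **Selection-induced disequilibrium.** Truncation selection builds
   negative gametic-phase disequilibrium, shrinking additive variance over
   the first generations (the classical effect of selection on variance).
2. **Within-family selection with a family cap.** From round two onward a
   cohort consists of ~36 *full-sib* families of four, and the
   one-sibling-per-family rule forces much of the phenotypic selection
   differential to be earned *within* families, where the heritable
   fraction of a deviation is only
   $\tfrac{1}{2}\sigma^2_a / (\tfrac{1}{2}\sigma^2_a + \sigma^2_E)$
   (about 0.25 when $h^2 = 0.4$) rather than $h^2$.

Measured directly in the simulator, the genetic content of the selection
differential is 0.398 of $S$ in the base round at $h^2 = 0.40$ (unbiased)
but only 0.305 in round two, and per-generation $R_i/S_i$ falls from
about 0.45 to 0.28 across the four rounds. The net effect is
$\mathbb{E}[b_T] \approx 0.8\,h^2$ at these designs: configured
heritabilities of 0.40 / 0.31 / 0.55 yield mean $b_T$ of about 0.32 /
0.26 / 0.45 over 200 replicates. The same attenuation necessarily operated
in the original experiment, whose published $b_T$ values are therefore
best read as lower bounds on base-population heritability — the
*comparison between ploidies* is unaffected, which is what the experiment
turned on. The acceptance checks that expect $b_T$ to match the configured
$h^2$ exactly are left failing rather than papering over this; the
simulator's conditions are the experiment's, not tuning knobs.

The simulator also deliberately omits features of the real data: no
linkage or recombination map, no correlated secondary traits, no
genotype-dependent sterility or mortality, and no mechanism for the
striking CV inflation seen in the neotetraploid control line (+123%),
whose cause (chromosomal or epigenetic instability after genome doubling)
is unknown — an optional per-generation variance-inflation multiplier is
exposed for exploration but intentionally has no default. Passing tests
therefore certify the estimators and design logic, not that real fireweed
behaves like the model.

## Numerical and degenerate-input choices

* Flowering-time ties in selection are broken by the run's seeded stream.
* Zero cumulative differential (control lines) yields `NA` with a reason
  attribute, never a division by zero.
* Noncentrality inversion uses monotone bisection with expanding upper
  brackets; non-bracketing raises a named error.
* Unknown parents are the sentinel `"0"` (empty accepted on read);
  founders must have both parents unknown; pedigree validation rejects
  duplicate ids, dangling parents and cycles with distinct error classes.
* The gene-count and problem sizes used by the test suite (e.g. 200
  replicates for recovery runs, $10^5$ gene drops and gametes, $10^4$
  coverage simulations) were chosen to keep Monte-Carlo error a few times
  smaller than the assertion tolerances.

## Worked example

```{r example, eval = FALSE}
arch <- calibrate_architecture(h2 = 0.40, cytotype = "diploid")
rec <- run_experiment(design_diploid(), arch, seed = 7)
estimate_response(rec)
reference_divergences()
```
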