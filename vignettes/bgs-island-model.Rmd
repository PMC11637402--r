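---
title: "Background selection in an island model: theory, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background selection in an island model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgsisland)
```

## The problem

Purifying selection at linked sites reduces the effective population
size experienced by neutral variation — *background selection*. Its
strength is summarised by $B = N_e/N_{e0}$. In a subdivided population
the story is richer than under panmixia: the $B$ experienced *locally*
by a subpopulation governs local drift and hence $F_{ST}$, while total
metapopulation diversity $\pi_T$ responds through the global effective
size. Two regimes matter. In the **background selection regime** (strong
selection, rare mutation) deleterious alleles sit at deterministic
mutation–selection balance and the classical formulas apply. In the
**interference selection regime** (weak selection, appreciable drift)
deleterious alleles fluctuate, interfere with one another, and fix at a
non-trivial rate; classical theory then badly overestimates the effect.
This package implements a quantitative-genetic treatment that covers
both regimes in a finite island model, and adds a *migration effect*
that classical treatments lack.

## Local theory

A neutral lineage linked to selected segment $i$ suffers excess variance
in reproductive success equal to $V_{A,i} Q_i^2$, the segment's additive
fitness variance times a linkage inflation factor accumulating the
association over generations. With $S$ segments,

$$N_{f,local} = N_{local}\, e^{-\sum_i V_{A,i} Q_i^2 / 2}.$$

**The migration effect.** Within a focal deme, the association between a
neutral lineage and its deleterious background ends when selection
removes the carrier, when recombination separates the alleles — or when
the carrier emigrates. The per-generation autocorrelation is therefore
$C(\tau) = [Z(1-r)(1-m)]^\tau$ and its summed square

$$Q_\infty^2 = \left[\frac{1}{1 - Z(1-r)(1-m)}\right]^2 ,$$

where $Z$ is the decay factor of the fitness-variance association
($Z = 1-t$ under strong selection) and $m$ the total emigration
probability. The $(1-m)$ term is what makes migration *attenuate*
background selection locally: at $m \gtrsim t$ most deleterious-allele
associations are exported before selection completes its work, so
$B_{local} \to 1$ even though selection still removes the alleles from
the metapopulation as a whole. Averaging $Q_\infty^2(r)$ over a segment
of map length $M$ with the neutral site at its centre gives the closed
form $1/[(1-a)(1-a(1-M/2))]$ with $a = Z(1-m)$, which the tests verify
against numerical quadrature to $10^{-6}$ relative error.

**Weak selection.** When drift fixes deleterious alleles at rate
$R = 4 N_f U t/(e^{4N_f t} - 1)$ per generation ($U$ the gametic rate of
the segment), fixed alleles stop contributing variance:
$V_A = (U_{dip} - 2R)\,t$ and $Z = 1 - U_{dip} t/(U_{dip} - 2R)$, with
$U_{dip} = 2U$ the diploid region rate. The two conventions fit
together: as $t \to 0$, $R \to U$ (the classical neutral substitution
rate) and $V_A \to 0$, recovering the neutral limit, while at $R = 0$
the exponent collapses to $2U/(2t+M)$ — the classical deterministic
region formula. This pairing is deliberate: reading both rates on the
same (gametic) scale would push $V_A$ negative at half the neutral
fixation rate and make the solver disagree with the deterministic
formula by ~26% under strong selection, so the package uses the reading
under which the two theories meet. `solve_local_equilibrium()` iterates
the $N_f$ and $R$ equations to a joint fixed point (damped fixed-point
iteration, inner tolerance $10^{-12}$ relative); with
`interference_rescale = TRUE` the reference size is itself rescaled by
the current $B$ (selected sites experience background selection too) as
an outer fixed point with tolerance $10^{-8}$ and a 500-iteration cap.
Non-convergence is an error, never a silent result; $V_A$ and $Z$ are
clamped at zero only in the pathological drift-dominated corner and the
clamp is reported in the per-segment diagnostics.

**Heterozygosity-effective size.** Equilibrium diversity mixes neutral
mutations of all ages, and young mutations have not yet accumulated the
asymptotic association, so the size relevant to $\pi$ exceeds $N_f$:

$$Q^2(\tau) = \left[\frac{1-a^\tau}{1-a}\right]^2,\qquad
N_f(\tau) = N e^{-\sum_i V_{A,i} Q_i^2(\tau)/2},\qquad
B_{het} = \frac{1}{2N}\sum_{\tau \ge 0}\ \prod_{i=1}^{\tau}
\left(1 - \frac{1}{2N_f(i)}\right).$$

The survival factor $1 - 1/(2N_f)$ per generation (diploid genome
copies) is the unique choice for which the neutral limit gives exactly
$B_{het} = 1$. The $\tau$-sum runs to $10\,N_{local}$ generations and is
closed with the analytic geometric tail at the asymptotic $N_f$ — the
horizon itself is conventional, and adding the exact tail removes the
truncation error entirely in the neutral limit rather than leaving a
$\sim e^{-5}$ mass unaccounted. $M > 0$ segments average $Q^2(\tau)$
over $r$ by 64-node Gauss–Legendre quadrature.

## Metapopulation predictions

With offspring production (drift) occurring before migration and
measurement after migration — the event order is load-bearing — the
equilibrium predictions with $m^2$ terms retained are

$$F_{ST} = \left[1 + \frac{d(d-1)(4-2m) N_{local} B_{local} m}{(d(1-m)-1)^2}\right]^{-1},
\qquad
G_{ST} = \left[1 + \frac{d^2 (4-2m) N_{local} B_{local} m}{(d(1-m)-1)^2}\right]^{-1}.$$

Three neutral evaluations (d = 10, $N_{local}$ = 500; $m$ = 0.00045,
0.009, 0.09 giving $F_{ST} \approx$ 0.50, 0.047, 0.0042) pin the
denominators down against transcription error; both reduce to the
familiar $1/(1 + 4N_e m\, d/(d-1))$ as $m \to 0$. Total diversity comes
from $N_{e,global} = N_{global}/(1 - G_{ST})$ and the saturating
infinite-alleles form
$\pi_T = 4 N_{e,global} B_{global} \mu / (1 + 4 N_{e,global} B_{global}\mu)$,
with $\pi_S = \pi_T (1 - G_{ST})$ and $\pi_B = \pi_S/(1-F_{ST})$.

Two genuinely open design points, decided as follows:

- **$B_{global}$** is not pinned down by the prediction recipe beyond
  "the global effect of background selection". We compute it by running
  the same local solver in panmictic mode ($m = 0$, interference
  rescaling on, heterozygosity variant) at size $N_{e,global}$: for
  total diversity the metapopulation behaves as one panmictic unit of
  that size. It is insensitive to the exact size here because $R \approx 0$
  at these parameters.
- **$\pi_B$** could be derived from $\pi_S$ and Hudson $F_{ST}$ or from
  $\pi_T$ and $G_{ST}$; `predict_pi()` emits the Hudson route
  ($\pi_B = \pi_S/(1-F_{ST})$) and keeps $\pi_T$, $G_{ST}$ alongside so
  the other is one division away.
- The heterozygosity variant $B_{het}$ feeds the $F_{ST}$/$G_{ST}$
  formulas by default (diversity-based quantities respond to the
  heterozygosity-effective size); `predict(fit, which_B = "fitness")`
  switches to $N_f$-based predictions.

```{r}
fit <- bgs_island_model(d = 10, N_local = 500, m = 0.009,
                        t = 0.015, U = 7e-3, M = 0)
coef(fit)
predict(fit)
```

## The forward simulator

`simulate()` / `run_replicates()` drive a compiled forward-time diploid
Wright–Fisher island-model simulator reproducing the reference design:
$d$ demes of $N_{local}$ diploids; a genome of $L_{neutral}$ neutral
sites (internally non-recombining) flanked by two blocks of
$L_{selected}/2$ selected sites with total map length $M$; fitness
$w = (1-t)^k$ over $k$ deleterious allele copies; per-gamete Poisson($U$)
deleterious and Poisson($\mu L_{neutral}$) neutral mutations; soft
selection (fitness-proportional parent sampling within demes, selfing at
random-mating rates); reproduction, then migration, then measurement.
Defaults are the full reference conditions (10 × 500, $U = 7\times10^{-3}$,
$\mu = 10^{-5}$, $50 N_{global}$ generations, 750 replicates); the
`scale` argument shrinks deme size while preserving $4N\mu$ and
$4Nm\,d/(d-1)$ for desk-scale runs.

Implementation choices a user should know about:

- **Neutral mutation model**: infinite alleles per site, each event a
  novel label, because the prediction formula is the saturating
  infinite-alleles form; $\pi$ per site is $1 - \sum_a p_a^2$ with
  distinct-pair (sample size) correction.
- **Neutral block as a persistent structure**: since the block never
  recombines internally, all neutral sites share one genealogy; gametes
  transmit an immutable block id into a copy-on-write mutation-chain
  table and alleles are resolved only at measurement. This is exactly
  equivalent to copying allele arrays every generation and orders of
  magnitude faster. The corollary — one genealogy for the whole block —
  also means replicate-to-replicate variance of $\pi$ is that of a
  single locus, which is why validation uses many replicates rather
  than many sites.
- **Migration as symmetric exchange**: for each deme pair a
  Binomial($N_{local}$, $m/(d-1)$) number of whole individuals swap
  demes after reproduction. Each individual emigrates with probability
  $m$; deme sizes and metapopulation allele counts are conserved
  exactly, which the tests assert.
- **Selected sites**: biallelic with irreversible mutation (repeat hits
  are no-ops; at $\mu_{del} = 10^{-5}$ per site this is negligible).
  When $M = 0$ the whole genome is one non-recombining unit and only
  per-haplotype deleterious counts are tracked — fitness is unaffected,
  but individually fixed sites are then not identifiable, so
  `fixed_deleterious` is reported `NA` on that fast path. Fixed alleles
  generate no spurious selection either way because sampling weights
  are normalised by the deme minimum load.
- **Estimators**: Hudson $F_{ST} = 1 - \bar\pi_S/\bar\pi_B$ as a ratio
  of site-averages (the standard recommendation; average-of-ratios is
  noisier and biased), over sites passing a pooled minor-allele-
  frequency filter of 0.05; MAF is pooled across the metapopulation and
  equals one minus the majority-allele frequency at multi-allelic
  sites. All haplotypes are used (no subsampling).

## What the tests show — and what they do not

The suite validates, at documented scaled-down sizes, that: neutral
simulations reproduce the island-model $F_{ST}$ prediction across three
migration regimes (prediction inside the replicate 95% percentile
interval, 50 replicates of $20N_{global}$ generations at
$N_{local} = 100$); a single panmictic deme reproduces the saturating
$4N\mu/(1+4N\mu)$; strong selection ($N_{local}t = 7.5$, $m = 0$)
reduces $\pi$ by the classical deterministic factor within ~10%; and
with $m > t$ simulated $F_{ST}$ under background selection is
statistically indistinguishable from the neutral prediction. Scaled
runs preserve the governing products ($N t$, $4Nm$, $4N\mu$) but not
interference intensity, which grows with absolute population size — so
desk-scale agreement does not by itself certify the theory at
$N_{e,global} \sim 10^4$; the deterministic pipeline anchors cover that
parameter point analytically. Real genomes additionally violate the
fixed-$t$, uniform-map, single-region assumptions; none of the tests
speak to distributions of selection coefficients, dominance other than
semi-dominance (associative overdominance under recessivity can even
reverse the sign of the effect), or non-island demographies such as
stepping-stone models.

Known quantitative limits of the theory itself, visible in the
package's own outputs: near $N_{local} t \approx 2.5$ the solver's $B$
is least accurate (a long-standing gap in background-selection theory),
and at $N_{global} t \lesssim 50$ with tight linkage the pipeline
overpredicts $\pi_T$ somewhat because interference is handled only
through the rescaling approximation. The predicted fractional
reductions of diversity at $N_{global}t = 50$ (about 0.28 for $\pi_T$
and 0.45 for $\pi_S$ at $m = 4.5\times10^{-4}$; about 0.45 for $\pi_T$
at $m = 0.09$) sit slightly below the simulated reductions for exactly
that reason.

## Numerical conventions

Problem sizes used by the shipped tests were chosen once as the
smallest sizes at which each comparison has statistical teeth: 50
replicates for stochastic suites, $N_{local} = 100$ scaled demes,
$20N_{global}$-generation burn-ins (several coalescent times at these
sizes), 100–700 simulated sites. Solver tolerances are $10^{-12}$
(inner), $10^{-8}$ (outer); quadrature is 64-node Gauss–Legendre;
percentile intervals are type-7 quantiles at 2.5/97.5%. All randomness
flows from a single master seed through per-replicate child seeds, so
every table in the package's output is bit-reproducible.
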