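---
title: "Methods: the breakpoint anti-median construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the breakpoint anti-median construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antimedian)
```

## The genome model

A signed circular genome on $n$ genes is represented by its adjacency set.
Each gene has two distinguishable ends, a tail and a head, so there are
$2n$ gene ends; an adjacency is an unordered pair of distinct ends, and a
genome is a perfect matching of the $2n$ ends into $n$ adjacencies.  The
graph whose edges are the $n$ gene edges (tail--head of each gene) plus
the $n$ adjacency edges decomposes into disjoint cycles, the circular
chromosomes.  Pairing the two ends of a single gene is permitted and
yields a minimal one-gene circular chromosome.

The package is deliberately circular-only.  For the quantities computed
here the differences between circular, linear, unichromosomal and
multichromosomal models are $\mathcal{O}(n)$ boundary effects that vanish
from all the normalized proportions as $n$ grows, so we implement exactly
the model the closed forms describe and reject linear gene-order input
(`$` / `|` terminators) at parse time rather than silently coercing it.

Internally a gene end is the integer $2g-1$ (tail) or $2g$ (head); only a
stable bijection matters, and this one keeps every hot operation a
vectorized integer computation.

## Distances and scores

The breakpoint distance between two genomes with equal gene content is
$d = n - a$, where $a$ is the number of adjacencies they share.  For a
candidate genome $x$ and a trio $g_1, g_2, g_3$ the *score* is the
normalized distance sum

$$ s(x) = \frac{1}{n}\sum_{i=1}^{3} d(x, g_i) \in [0, 3]. $$

Scores are exact rationals (an integer sum divided by $n$), so analytic
comparisons at matching $n$ need no floating-point slack.  A genome
drawn independently of the trio shares $\mathcal{O}(1)$ adjacencies with
each member, so its score approaches $3$.

The overlap structure of a trio is summarized by the proportion $\psi$ of
adjacencies common to all three genomes and the proportions
$\omega_{1,2}, \omega_{1,3}, \omega_{2,3}$ common to *exactly* each pair.
We use the exclusive convention for the $\omega$'s — the three-way core is
not double-counted — because the score expectation below adds
$\psi + \sum\omega_{i,j}$ linearly.

## The anti-median construction

The median of three genomes minimizes the distance sum, but under the
breakpoint distance the minimizers degenerate onto one of the inputs:
optimality and compromise pull in opposite directions.  The anti-median
restores compromise by *sampling*: build an adjacency set that

1. contains **all** adjacencies in the two-way and three-way overlaps
   (any two overlap sets lie inside a common genome, hence are mutually
   compatible);
2. adds a uniform random sample of $\lfloor n\theta_1 \rceil$ adjacencies
   exclusive to $g_1$, then $\lfloor n\theta_2 \rceil$ exclusive to
   $g_2$, each sampled adjacency required to have two *free* ends (ends
   used by no adjacency already included);
3. adds **every** compatible adjacency exclusive to $g_3$ (the maximal
   third proportion) — or an explicit $\theta_3$ on request;
4. completes the partial assembly to a genome by a uniform random
   matching of the remaining free ends.

All $\theta$ proportions are relative to $n$, not to the exclusive-block
sizes.  Step 3 needs no search: candidates come from one matching, so
they are mutually compatible, and compatibility with the assembly is
per-adjacency — greedy inclusion is exactly maximal.  An explicit
$\theta_3$ (or $\theta_1$, $\theta_2$) exceeding the number of
two-free-end candidates fails loudly with the achievable maximum instead
of silently truncating.  The stage order is fixed $g_1 \to g_2 \to g_3$;
symmetry experiments can simply permute the arguments.

### Expected behaviour

After sampling $\theta_1$ from $g_1$ on a zero-overlap trio, an exclusive
$g_2$ adjacency has two free ends with probability $(1-\theta_1)^2$;
after both stages the $g_3$ proportion still available is

$$ \max\theta_3 = (1 - \theta_1 - \theta_2)^2, $$

and the expected score of the completed genome is

$$ s(x) = 3 - \left(\theta_1 + \theta_2 + (1-\theta_1-\theta_2)^2\right)
        = 3 - \left(\theta_1+\theta_2+1-2\theta_1-2\theta_2
          +2\theta_1\theta_2+\theta_1^2+\theta_2^2\right). $$

Both partial derivatives equal $1 - 2\theta_1 - 2\theta_2$, vanishing on
the ridge $\theta_1 + \theta_2 = 0.5$; the second derivatives are
negative, so the surface is concave with its interior *maximum* on that
ridge — the evenly sampled construction maximizes the distance sum over
maximal samples.  With general overlaps the score becomes
$3 - (\theta_1 + \theta_2 + \max\theta_3 + \sum\omega_{i,j} + \psi)$ and
the stationarity system

$$ \theta_i + \theta_j = 0.5 - \omega_{1,2} - \omega_{1,3} - \omega_{2,3}
   - \psi \quad (i \neq j) $$

has the unique symmetric solution
$\theta_1=\theta_2=\theta_3 = 0.25 - 0.5(\omega_{1,2}+\omega_{1,3}+\omega_{2,3}+\psi)$,
which `antimedian_solution()` obtains by actually solving the $3\times 3$
linear system (feasible only while $\psi + \sum\omega \le 0.5$).  The
"proportional representation" alternative, where each genome samples in
proportion to its overlap contributions, is exposed by
`proportional_scheme()` for comparison only: except in symmetric cases it
violates the stationarity system, and there is no principled reason to
prefer it to an even split.

### The general-overlap maximal third proportion

An open modelling point: with nonzero overlaps the stationarity system is
consistent with

$$ \max\theta_3 = (1 - \psi - \textstyle\sum\omega - \theta_1 - \theta_2)^2, $$

while conditioning on the third genome's *own* shared ends (the ends its
$\psi$, $\omega_{1,3}$, $\omega_{2,3}$ blocks already occupy are never
candidates) gives

$$ \max\theta_3 = \frac{(1 - \psi - \sum\omega - \theta_1 - \theta_2)^2}
                       {1 - \psi - \omega_{1,3} - \omega_{2,3}}. $$

The two coincide at zero overlap.  `max_theta3()` exposes the first as
the default (`model = "stationary"`, the form the solved system requires)
and the second as `model = "conditional"`; `empirical_max_theta3()` is
the arbiter, and the test suite reports the simulated value against both
forms without electing a winner.  In our simulations at
$n = 10^4$ the realized maximum tracks the conditional form when the
third genome carries its own overlap mass.

## The trio generator

`random_genome(n)` draws a uniform perfect matching of the $2n$ ends (a
shuffled end sequence paired off two by two).  Uniform matchings, rather
than uniform signed circular permutations, were chosen because every
quantity used by the model depends only on adjacency statistics — the two
ensembles differ in their chromosome-count distribution but not in any
overlap or distance proportion — and because matchings make the exact
overlap construction below direct.

`random_trio()` realizes a requested profile
$(\psi, \omega_{1,2}, \omega_{1,3}, \omega_{2,3})$ *exactly* in counts,
not in expectation: a random partial matching supplies the four shared
blocks (mutually end-disjoint, since any two blocks lie inside a common
genome), and each genome is completed independently by a uniform matching
of its free ends.  Exact counts, with $n p$ rounded to the nearest
integer, remove one noise source from all analytic comparisons.  Because
independent completions collide with probability $\mathcal{O}(1)$ (the
number of accidental shared adjacencies between two random matchings is
approximately Poisson with mean near $\tfrac{1}{2}$), the generator
detects any deviation from the requested counts and redraws the
completions, up to 100 times; the number of redraws is returned.  The
same feasibility algebra gives the generator's two hard constraints:
each genome's shared mass $\psi + \omega_{i,j} + \omega_{i,k} \le 1$, and
globally $\psi + \sum\omega \le 1$ because the four blocks consume
disjoint ends.

What the generator emulates is precisely the overlap *structure* the
closed forms parameterize; what it does not emulate is how real trios
acquire that structure — correlated rearrangement histories along a tree,
breakpoint reuse, unequal gene content, chromosome-number constraints.
Passing tests therefore demonstrate the construction's statistical
behaviour under its stated model, not its behaviour on any particular
biological data set.

## Numerical choices and problem sizes

* Proportion-to-count conversion uses `round(n * p)`; the
  $\mathcal{O}(1)$ rounding gap is invisible at the $n$ used anywhere a
  proportion is compared.
* Analytic values are double precision; grid comparisons against the
  reference 25-cell table are made at 4 decimal places, the table's
  printed precision.
* Simulation checks run at $n = 10^4$ with 3 replicates and use absolute
  tolerances of $0.02$ on realized proportions and scores (the
  realized-proportion standard deviation at that size is about
  $0.004$) and $0.01$ on the random-genome score baseline.  Property
  sweeps (metric axioms, generator contract, monotonicity) use many small
  genomes ($n \le 50$, or $n$ in the low thousands) under fixed seeds.
* The ridge-dominance check compares empirical scores between grid points
  with $\theta_1+\theta_2 = 0.5$ and points with sums $0.3$ and $0.7$,
  where the analytic gap ($0.04$) is an order of magnitude above the
  simulation noise; adjacent 0.05-grid cells differ by only $0.0025$,
  which a stochastic test could not rank reliably.
* Ties and degenerate inputs: a fully shared trio ($\psi = 1$) forces the
  construction onto the common genome with score 0 and no completion; an
  all-zero request on a zero-overlap trio degenerates to a uniform random
  genome with score near 3; `theta = 0` stages are no-ops.

## Limitations

* Equal gene content, no duplicates, circular chromosomes only.
* The closed forms are asymptotic in $n$; at small $n$ ($\lesssim 10^2$)
  the $\mathcal{O}(1)$ collision and rounding terms are visible.
* The construction's random completion deliberately forgoes
  maximum-matching completion heuristics that could add shared
  adjacencies; the package characterizes the purely statistical sampling
  scheme.
* Median *search*, and iterating anti-medians over the internal nodes of
  a phylogeny (the small phylogeny problem), are out of scope; the
  exported primitives are the building blocks such an iteration would
  use.
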