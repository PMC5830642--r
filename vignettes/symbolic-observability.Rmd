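---
title: "Symbolic observability of rational reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic observability of rational reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symobs)
```

## The model and its assumptions

`symobs` asks whether the full state of a rational ODE system
$\dot x_i = f_i(x_1,\dots,x_d)$ can be reconstructed from a subset of
measured variables and their time derivatives. The exact criterion —
full rank of the Jacobian of the map from state to measurements and
their Lie derivatives — requires symbolic determinants that become
intractable well below the dimensions of realistic biological networks.
The package instead works in a four-symbol abstraction of the Jacobian:
each entry $\partial f_i / \partial x_j$ is replaced by

* `0` if it vanishes identically;
* `1` if it is constant in the state variables (a linear coupling);
* `1b` ($\bar 1$) if it is a non-constant polynomial, or a rational
  function whose denominator does not involve $x_j$;
* `1bb` ($\bar{\bar 1}$) if, after cancelling common polynomial
  factors, its denominator still depends on $x_j$.

The hierarchy encodes how much a coupling degrades observability:
linear couplings leave the observability determinant constant, while
polynomial and especially rational couplings introduce state-dependent
factors, i.e. singular observability manifolds. The approach applies to
vector fields that are rational in the state variables; anything else
(exponentials, non-integer powers of a state) is rejected rather than
guessed.

The observability matrix for a measurement configuration is assembled
by blocks, one per sensor: the unit row selecting the sensor, the
sensor's symbolic Jacobian row, and further rows obtained by the
semiring product $w_j = \bigoplus_i (v_i \otimes \tilde J_{ij})$, one
per additional derivative. The coordinate counts must total $d$; the
package deliberately never considers reconstruction spaces of dimension
above $d$ (Takens-style embeddings are a different trade-off and out of
scope). Both semiring operations are "most severe symbol wins", with
`0` annihilating products; the package stores the operation tables
explicitly and the tests assert their equivalence with the max-severity
shortcut.

The symbolic determinant is expanded over permutations with no signs
and no cancellation. This is intentional: a sign-free expansion counts
every structurally possible contribution, which is what the
observability coefficient
$$\eta = \frac{N_1}{D} + \frac{\bar N}{D^2} + \frac{\bar{\bar N}}{D^3},
  \qquad D = \max(1, N_1) + \bar N + \bar{\bar N}$$
consumes ($T$ terms, each contributing $d$ symbols; $N_1 + \bar N +
\bar{\bar N} = dT$). For rational systems a special condition applies
first: if $\bar N = 0$ and $\bar{\bar N} > 0$, set $\bar N \leftarrow
\bar{\bar N}$. We read the condition as acting on the symbol counts
(the published statement drops its overbars typographically); this
reading reproduces every two-decimal coefficient the benchmark models
report — 0.17, 0.30, 0.48, 0.70, 0.86, 0.93 and all exact 1.00/0.00
cases — while the alternative readings fail on all of them.

## Exact arithmetic choices

Classification must decide, exactly, whether a derivative is zero,
constant, or has $x_j$ in its reduced denominator. Floating point is
unreliable for this, and no computer-algebra system is required:
the package converts each right-hand side into a ratio of multivariate
polynomials with coefficients in a prime field (parameters become
deterministic nonzero residues derived from their names), differentiates
by the quotient rule, and probes reduced numerator/denominator degrees
per variable via univariate GCDs at random specializations of the other
variables. A degenerate specialization can only shrink the reduced
degrees, so the maximum over three draws is taken; the entire pipeline
runs under two independent parameter assignments and keeps the more
severe symbol, so a single unlucky residue cannot demote a coupling.
The modulus (33554393, below $2^{25}$) keeps all products exactly
representable in doubles.

$\eta$ itself is carried as an exact integer fraction and only rounded
— half away from zero — for the two-decimal display field: the 5D
configuration `x1 x5^4` evaluates to exactly $163/343 = 0.4752\ldots$,
which must print as 0.48, and borderline halves (e.g. an exact 0.475)
round up deterministically. For astronomically many terms the fraction
would overflow doubles; past $2^{53}$ the code falls back to ordinary
double rounding, a regime far beyond any matrix this package targets.

The determinant summary is computed by the standard permanent-style
dynamic program over column subsets, aggregating term counts and symbol
tallies per subset, $O(d \cdot 2^d)$ states — a 13-dimensional
coefficient takes milliseconds. A brute-force permutation enumeration
(`det_summary_bruteforce`, $d \le 8$) is kept purely as an independent
oracle and is checked against the recursion on hundreds of random
matrices in the test suite.

## Sensor preselection

Two network criteria prune the search space before any coefficient is
computed. A variable that appears linearly in no other equation
(linear out-strength zero) cannot be reconstructed cheaply from outside
and is *essential*. Among the remaining candidates, two variables that
are mutually and solely linearly coupled form an *exclusive pair*: each
is recoverable only through the other, so one per pair stays measured.
Which one is removed is decided by the non-measured in-strength
(weights 1/2/3 for linear/polynomial/rational couplings from the
candidate set, computed over the full candidate set before any pair is
resolved): the more nonlinearly fed member is removed. Exact ties are
not broken arbitrarily — the report branches, which is precisely what
happens for the 5D model's `{x4, x5}` pair and the 13D model's
`{x1, x8}` pair. Finally a removed variable must actually appear in
some measured equation (reachability), otherwise it is retained: a
candidate seen only by other removed candidates would become invisible.

Counting conventions: a configuration measures $m$ variables and
distributes $d - m$ extra derivative coordinates over them, giving
$\sum_m \binom{d}{m}\binom{d-1}{m-1}$ configurations for $m = 1..d-1$.
The derivative-free full measurement ($m = d$) is excluded from the
default range, which is the convention under which the 5D and 9D space
sizes come out as 125 and 24309. The published reduced-search sizes
(354 at 9D, 2870 at 13D) follow no enumeration rule we could
reconstruct; `reduced_search` therefore reports its own evaluated count
(e.g. 990 for the 13D nine-sensor stratum) alongside its results.

## The synthetic generator

Property tests need arbitrary systems, not just the three fixtures.
`random_symbol_matrix` draws a seeded symbol matrix (nonzero diagonal —
every variable has intrinsic dynamics — plus off-diagonal couplings at
a given density and symbol mixture), and `realize_odes` constructs an
actual rational vector field classifying back to it: `a*x_j` for linear
couplings, a seeded product `a*x_j*x_k` with a partner among the same
equation's polynomial couplings (or `a*x_j^2` when it has none — a
partner outside that set would contaminate another entry), and a
saturating `a*x_j/(K + x_j)` for rational couplings, all with fresh
parameter names so terms cannot cancel. The central round-trip property
— classify ∘ realize = identity — is exercised on 200 seeded systems.
The generator makes no attempt at dynamical realism (stability,
oscillations, attractors): it emulates coupling *structure* only, which
is all the symbolic theory consumes. Passing tests therefore certify
the algebra and the search machinery, not the behaviour of any
particular biological model beyond its Jacobian structure.

Problem sizes used by the default suite: oracle equivalence on 500
random matrices with $d \le 7$, round trips on 200 systems with
$d \le 6$, enumeration cardinality on 200 random ranges with
$d \le 8$, and full evaluation of the 125-configuration 5D space —
a few tens of seconds in total.

## Known limitations and documented discrepancies

* The three univariate 5D coefficients `x2^5`, `x3^5`, `x4^5` are
  printed in the source literature as 0.08, 0.02, 0.09; the
  construction as specified (repeated Lie-row propagation saturates
  these rows to all-`1bb`) yields 0.18, 0.12, 0.18. The discrepancy is
  documented rather than patched: no variant of the propagation rules
  we tried reproduces those three values without breaking the dozen
  values that do reproduce.
* The printed 9D symbol matrix disagrees with the printed 9D equations
  in a handful of column-5/6 entries; the package derives the Jacobian
  from the equations (the published out-strength walkthrough is only
  consistent with the derived matrix) and ships the hand-typed variant
  as `fixture_model("rayleigh_benard9d", jacobian = "printed")` for
  comparison. Relatedly, the out-strength of `x9` is reported as 2
  (it enters two equations linearly), not the published 1.
* Sign cancellations are invisible by construction: a system whose
  observability determinant vanishes through exact cancellation of two
  nonlinear terms will be scored optimistically. This is a known and
  rare failure mode of the symbolic approach.
* `eta` compresses all structure into one scalar; two configurations
  with equal $\eta$ can have singular manifolds of very different
  practical relevance. The determinant summary (`T`, `N1`, `Nbar`,
  `Ndbl`) is always reported alongside for this reason.
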