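# symobs

Symbolic observability analysis of rational reaction networks in R.

## The problem

A dynamical system `ẋ = f(x)`, `x ∈ R^d`, is *observable* from a set of
measured variables when every state can be uniquely inferred from those
measurements and their time derivatives. Formally, measuring `s = h(x)`
and stacking the gradients of its successive Lie derivatives gives the
observability matrix

    O_s(x) = [ dh; dL_f h; … ; dL_f^{d-1} h ],

and the system is observable iff `rank(O_s) = d`. For nonlinear models —
gene circuits, cell-cycle networks, fluid truncations — the analytic
determinant of `O_s` quickly outgrows any computer-algebra system, and
the number of candidate measurement configurations (which variables to
measure, and how many derivatives of each) explodes combinatorially:
`Σ_m C(d,m)·C(d−1,m−1)`, about 5.2·10⁶ already at `d = 13`.

`symobs` implements the symbolic alternative. Every Jacobian entry
`∂f_i/∂x_j` is abstracted to one of four symbols — `0` (absent), `1`
(linear), `1̄` (nonlinear polynomial), `1̄̄` (rational with `x_j` in the
denominator) — and the observability matrix is assembled in this algebra
by symbolic Lie-row propagation. Its determinant is expanded without
signs or cancellation; the counts `N₁`, `N̄`, `N̄̄` of the three nonzero
symbols over all `T` surviving permutation terms yield the *symbolic
observability coefficient*

    η_s = N₁/D + N̄/D² + N̄̄/D³,   D = max(1, N₁) + N̄ + N̄̄,

(with `N̄ ← N̄̄` first whenever `N̄ = 0 < N̄̄`, the rational-system
condition). `η_s ∈ [0, 1]`; `η_s = 1` means full observability, values
above 0.75 are conventionally "good", and `η_s = 0` flags a structurally
rank-deficient reconstruction.

Two graph criteria on the symbolic Jacobian preselect minimal sensor
sets before any coefficient is computed: the linear out-strength
`σ_out^lin(i) = #{j ≠ i : J̃_ji = 1}` (zero ⇒ `x_i` must be measured) and
the non-measured in-strength `σ_in^nm(i) = Σ_{k∈V_nm} w(J̃_ik)` with
weights 1/2/3, which resolves *exclusive pairs* — mutually and solely
linearly coupled candidates of which one must stay measured.

## Worked example

The bundled `goldbeter5d` fixture is Goldbeter's five-variable circadian
model of PER oscillations in Drosophila:

```r
library(symobs)
gold <- fixture_model("goldbeter5d")
print(preselect(gold))
#> sensor preselection
#>   linear out-strength: 1 0 0 1 1
#>   essential (must measure): x2, x3
#>   exclusive pairs: {x4, x5}
#>   in-strength from candidates: x1=3 x4=1 x5=1
#>   branch 1: measure {x2, x3, x5}
#>   branch 2: measure {x2, x3, x4}
```

`x2` and `x3` appear linearly in no other equation, so they must be
measured; `x4` and `x5` are exclusively linearly coupled to each other
(an exact in-strength tie), so each branch keeps one of them. Completing
a branch to dimension 5 with two derivatives and scoring it:

```r
coefficient_for(gold, "x2^2 x3 x5^2")
#> configuration: x2^2 x3 x5^2
#> eta = 1 = 1.00  (exact 125/125)
#> symbolic determinant: T = 1 term(s); N1 = 5, Nbar = 0, Ndbl = 0

coefficient_for(gold, "x2^2 x3^2 x5")
#> configuration: x2^2 x3^2 x5
#> eta = 0.699074 = 0.70  (exact 151/216)
#> symbolic determinant: T = 1 term(s); N1 = 4, Nbar = 0, Ndbl = 1
```

Measuring `(x2, ẋ2, x3, x5, ẋ5)` gives full observability (`η = 1`,
a single all-linear determinant term), while swapping `ẋ5` for `ẋ3`
leaves one rational symbol in the determinant and drops `η` to 0.70 — a
singular observability manifold appears. A search over all 12
completions of the two preselected sensor sets finds exactly the two
fully observable reconstructions:

```r
reduced_search(gold, spec = search_spec(m_min = 3, m_max = 3, min_eta = 1))
#> ranked observability results for 'goldbeter5d' (strategy: preselect; 12 configurations evaluated)
#>         config m eta_2dp T N1 Nbar Ndbl
#> 1 x2^2 x3 x4^2 3       1 1  5    0    0
#> 2 x2^2 x3 x5^2 3       1 1  5    0    0
```

The same machinery runs from the shell via the installed `exec/symobs`
script (`coeff`, `preselect`, `search`, `scan`, `count`, `generate`
subcommands), and `fixture_model("dna13d")` /
`fixture_model("rayleigh_benard9d")` load the 13-variable Novak–Tyson
cell-cycle model and the 9-mode Rayleigh–Bénard truncation.

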