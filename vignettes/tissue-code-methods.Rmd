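---
title: "Rule-based tissue renewal: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based tissue renewal: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuecode)
```

## The model

`tissuecode` implements a deterministic "tissue code" for epithelial renewal:
five rules for the timing, temporal order, spatial direction, number, and
lifespan of cell divisions, with the colonic crypt as the motivating tissue.
Every quantity the package computes follows from these rules; there is no
stochastic component anywhere.

1. **Timing.** One time step is one cell cycle; all divisions are clocked by
   it.
2. **Order.** Division is asymmetric: a mature (M) cell divides every cycle,
   producing one immature (I) daughter. An I cell waits a maturation period of
   `c` cycles, then becomes M *and divides in that same step* (division is the
   maturation event). The immortal clonogenic cell (label 0, generation 0, the
   stem-cell analog) divides every cycle.
3. **Direction.** Each division is aimed along the cell's split angle, which
   both daughters inherit and rotate counterclockwise by `R` degrees per
   division. The default couples direction to timing, `R = 360/c`.
4. **Number.** At whole-maturation age `n_wm` a cell becomes wholly mature
   (W) and never divides again, so each cell performs exactly `n_wm - c`
   divisions. Under steady-state scheduling `n_wm(g) = n_wm0 - g` decreases
   with generation `g`.
5. **Lifespan.** At age `L` a cell dies and vacates its position.

A cell's state is a pure function of its age, generation, and the
parameters: I below age `c`, M in `[c, n_wm)`, W in `[n_wm, L)`, dead at `L`.
The state index never decreases with age, which the test suite checks as a
property over random parameter draws.

## The linear lineage model

`simulate_lineage()` applies rules 1, 2, 4, 5 without geometry. Within a step
parents divide in ascending label order with the clonogenic cell first, and
daughters take consecutive labels continuing the global count, so labels *are*
birth order. This ordering is forced by the reference division-order table the
tests reproduce (at step 13, parents 0–8 produce children 34–42 in order).

With `n_wm = L = Inf` the total count obeys the generalized Fibonacci
(p-number) recurrence

$$N(t) = N(t-1) + N(t-c), \qquad N(t) = t + 1 \ \text{for}\ t \le c,$$

because the cells that divide at step `t` are exactly those born by step
`t - c`; equivalently `M(t) = N(t - c)`. In p-Fibonacci terms
`N(t) = F_{t+c-1}` with seeds `F_0 = … = F_{c-1} = 1` (`p = c - 1`; for
`c = 6` this is OEIS A005708). `p_fib()` evaluates the sequence in exact
arbitrary-precision integers — a deliberately hand-written, addition-only
bignum layer, since counts exceed the 2^53 double-precision integer range
long before the late times at which the M/I ratio is read off
(`lineage_mi_ratio(4, 300)` divides ~40-digit integers).

## Closed-form layer

Dividing the recurrence by `N(t-1)` shows the growth factor tends to the
unique root `rho` in (1, 2] of `rho^c = rho^{c-1} + 1`, and the M/I ratio to
`lambda = rho - 1`, the unique root in (0, 1] of

$$\lambda (1 + \lambda)^{c-1} = 1.$$

Both roots are found by bisection on their bracketing intervals to an
interval width of 1e-12; both polynomials are strictly monotone there, so
bisection cannot fail, and an independent `uniroot()` oracle confirms the
values in the tests. The closed-form inverse `c = 1 - ln(lambda)/ln(1+lambda)`
(`c_from_lambda()`) round-trips to 1e-6 or better. The continuous-model rate
constant is `k2 = lambda^2`, making the ODE growth eigenvalue
`sqrt(k1 k2) = lambda` under `k1 = 1`; `correspondence_table()` regenerates
the six-row `c`/`k2`/`lambda1`/(M/I) table, rounded (by default) to the six
decimals at which such tables are conventionally printed.

## The rosette model

`simulate_rosette()` adds rule 3 and geometry. Positions are sums of the
`360/R` unit direction vectors in the plane (for `R = 60°` this is exactly
the unit triangular lattice); occupancy is keyed by coordinates rounded to
1e-6, far coarser than accumulated float error (~1e-13) and far finer than
the unit lattice spacing. Each division places the daughter one unit step
along the parent's current split angle; if that position is occupied, the
occupant chain is pushed one slot outward along the same ray, stopping at the
first gap (death leaves gaps that later displacement may refill). Two
boundary decisions the figures do not settle:

* **The origin is immovable.** A displacement chain that reaches the origin
  skips over it — the displaced cell takes the next slot on the ray beyond —
  so the clonogenic cell occupies the origin at all times.
* **Displaced cells keep their split angle**; displacement changes where a
  cell is, not what it will do.

A further convention: the daughter is placed along the orientation vector
itself. The dividing line through the cell center perpendicular to the
orientation defines the division plane; interpretations that place the
daughter along that perpendicular differ by a fixed 90° offset and would
rotate the whole structure without changing counts, symmetry, or branch
structure.

Geometry never creates or destroys cells, so rosette totals equal linear
totals step for step — the tests verify this for `c = 2..8` against the
recurrence oracle.

### Symmetry: what holds exactly and what cannot

A rotation by `360/c` about the origin fixes no off-origin lattice point, so
a configuration can be *exactly* `c`-fold symmetric (as a multiset of
position–state pairs, which `symmetry_order()` measures) only when the
non-origin live count is divisible by `c`. Growth from a single ancestor
visits such counts essentially only at `t = c`, when the first leaflet ring
has just closed: the clonogenic cell seeds the `c` branches one per step, and
they remain staggered by one step forever after. `symmetry_order()` therefore
returns `c` at `t = c` (checked for `c = 4` and `c = 6`) and 1 at most later
times; the rotational organization at later times is the right thing to
measure instead with `branch_counts()`: all `360/c` angular sectors are
populated, the branch total satisfies `sum + 1 + c = N(t)` (clonogenic plus
first leaflet layer excluded), and the branch-sum series grows at ratio
`growth_root(c)` (observed within 1e-3 by `t = 28` for `c = 6`; the test
allows 0.01).

### Steady state

With `c = 6`, `n_wm0 = 11`, `L = 35` and generation-linked scheduling
(`crypt_steady_params()`), generation `g` performs `max(11 - g, 6) - 6`
divisions, so generations 5 and beyond are sterile, the production region is
finite, and W cells stream outward until they die at age 35 near the edge.
The simulated population is *exactly* constant (2276 cells) from `t = 105`
on; the test asserts a zero linear trend over `[3L, 6L]`. Lifespan `L`
limits the overall radial extent but not the size of the dividing region:
halving-scale reductions of `L` shrink the structure markedly (radius 36 at
`L = 35` vs 24.5 at `L = 17` by `t = 150`) while the radius of the M-cell
region changes by under 20%.

`project_cylinder()` wraps the plane onto a cylinder of 42 cell widths —
the crypt-wall circumference scale — as `angle = 2*pi*(x mod 42)/42`,
`height = y`. The projection is injective while the structure's diameter is
below the circumference (tests check the cell-level configuration at
`t = 27`); a fully developed steady structure (radius 36) necessarily
self-overlaps after wrapping, which is a property of the projection, not of
the simulation.

## The continuous model

The four-compartment linear system (`continuous_params()`,
`system_matrix()`) is

$$\dot M = k_2 I - k_4 M,\quad \dot I = k_1 M - k_3 I,\quad
\dot W_1 = k_3 I - k_5 W_1,\quad \dot W_2 = k_4 M - k_6 W_2 .$$

Division is production without self-loss (M makes I at `k1`, I makes M at
`k2`); differentiation drains the proliferative pool along two lineages.
This right-hand side is the unique linear four-compartment system whose
proliferative block has trace `-(k3 + k4)` and determinant `k3 k4 - k1 k2`,
i.e. eigenvalues

$$\lambda_{1,2} = \frac{-(k_3+k_4) \pm \sqrt{(k_3+k_4)^2 - 4(k_3 k_4 - k_1 k_2)}}{2},
\qquad \lambda_3 = -k_5, \quad \lambda_4 = -k_6,$$

with `lambda_1` zero/positive/negative according as `k3 k4` equals, is less
than, or exceeds `k1 k2` (`classify_regime()`, tolerance 1e-12 on the
balance). The discriminant is `(k3 - k4)^2 + 4 k1 k2 ≥ 0`, so the spectrum is
always real. With differentiation along only one lineage (`k3 = 0` or
`k4 = 0`) and positive division rates, `lambda_1 > 0` always: one-lineage
systems cannot balance, which is why the model needs two W compartments.
Under the balance `k3 k4 = k1 k2` the steady ratios are
`M/I = k2/k4 = k3/k1`, `W2/M = k4/k6`, `W1/I = k3/k5`
(`steady_state_ratios()`, balance tolerance 1e-9 relative).

`integrate_compartments()` uses `deSolve::lsoda` at `rtol = 1e-10`,
`atol = 1e-12` — comfortably beyond the 1e-8 accuracy the package promises —
rather than an eigen-decomposition, to remain robust at the defective corner
cases (e.g. all off-diagonal rates zero). Tests compare trajectories against
closed forms (`M(t) = cosh(sqrt(k1 k2) t)` in the pure-growth case) and
against the steady ratios for random balanced draws.

## Problem sizes and tolerances in the test suite

* Per-cell simulations are capped so populations stay near or below ~2×10^4
  (linear) and ~2×10^3 (spatial): horizons of 14–30 steps depending on `c`
  for the linear recurrence cross-checks and 9–18 steps for the spatial
  count-equivalence checks, where displacement chains make small-`c` runs
  quadratic in population. These sizes already exercise every rule; longer
  horizons only grow the numbers.
* Late-time ratios are evaluated at `t = 300` through the exact bigint
  recurrence (agreement with the root equation is ~1e-13, asserted at 1e-6).
* Root finding is bisected to 1e-12 and checked against `uniroot()` at 1e-9.
* Closed-form eigenvalues are compared with `eigen()` on 100 random
  nonnegative draws at 1e-10.

## What the models do and do not capture

These are rule simulators, not fitted biological models. They produce exact,
reproducible bookkeeping of an idealized renewal process: no stochastic
division timing, no mechanics or curvature, no signaling feedback, no crypt
fission, and no attempt to match image data cell for cell. Passing tests
demonstrate internal consistency of the rules, the combinatorial identities,
and the discrete-continuous correspondence — not agreement with measured
crypt kinetics beyond the structural analogies described above.
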