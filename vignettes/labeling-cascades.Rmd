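---
title: "Isotopic labeling states, EMU decomposition and steady-state cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopic labeling states, EMU decomposition and steady-state cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocascade)
```

## The model

An isotopic labeling state of a moiety of $n$ isotopic atoms assigns each
atom a *mass shift*: the number of additional neutrons relative to the
element's least-neutron isotope. With $m$ the greatest shift in play, the
determinate per-atom states are $\{0, 1, \dots, m\}$, and three nested state
spaces describe a moiety:

- **Isotopomers** — the $(m+1)^n$ fully determinate state vectors. Their
  fractions form a probability distribution (sum = 1).
- **Cumomers** — state vectors over $\{0,\dots,m, \top\}$, where $\top$ is
  the indeterminate state, the disjunction of all determinate states. A
  cumomer fraction is the cumulative probability of all matching
  isotopomers; the full vector of $(m+2)^n$ cumomer fractions sums to
  $2^n$. Conceptually a cumomer lives in an infinite virtual moiety whose
  non-local atoms are all $\top$; since the $\top$-tail carries no
  information, the package stores only the $n$ local positions.
- **EMU blocks** — the cumomer set partitions into $2^n$ blocks, one per
  atom subset $N$, each block holding the $(m+1)^{|N|}$ cumomers determinate
  exactly on $N$. Each block is itself a probability distribution (sum = 1):
  the state space of the elementary metabolite unit $(metabolite, N)$.

Determinate states, $\top$, and a contradiction element $\bot$ form a
multi-valued logic under conjunction: $\top$ is the identity, $\bot$
absorbs, distinct determinate states conjoin to $\bot$. Conjunction of
cumomers determinate on disjoint atom sets multiplies their fractions;
disjunction adds them. This logic is why cumomer (not isotopomer) vectors
admit a Cartesian product, and why every interpretation of EMU states that
forms a commutative monoid — mass distributions under convolution,
Boolean-function vectors under the product, atom counts under addition — is
a homomorphic image of disjoint union and can serve as the cascade's value
type.

## Conversions and their pitfalls

All conversion matrices have exact 0/1 integer entries; only data are
floating point.

- `ic_matrix(n, m)`: the $n$-fold Kronecker power of the one-atom block
  (identity of size $m+1$ stacked over a ones row). Rows follow the fixed
  state order: determinate states ascending, $\top$ last, atom 1 most
  significant. The ordering matters: placing the indeterminate state *below*
  the determinate states keeps the Kronecker structure aligned with the
  printed conversion-matrix family, whereas the historical convention of
  sorting it first scrambles it.
- `punctured_matrix(n, m, s)`: deleting row $s+1$ of the one-atom block
  before taking Kronecker powers yields a square matrix of determinant
  $\pm 1$ — the generalized Reed–Muller transform onto the cumomers
  punctured at $s$. Its inverse is exact, so
  isotopomer $\leftrightarrow$ punctured conversion round-trips to machine
  precision. The classical cumomer vectors are the puncture at $s = 0$.
- `im_matrix(n, m)`: row $j$ selects the isotopomers of total shift $j$.
  We construct it directly from this defining property (each column has
  exactly one 1, so unit sums are conserved); the equivalent
  convolution-of-interspersed-identities construction requires a per-factor
  column spacing of $(m+1)^{i-1}-1$ to produce consistent dimensions, so
  the direct definition is used as the single source of truth, verified
  bit-exactly against the printed matrix family in the tests.
- The mass matrix is rectangular: mass → isotopomer is **not** offered.
  `pseudoinverse_demo()` exists precisely to show that the Moore–Penrose
  preimage, the minimum-norm solution spreading each mass fraction uniformly
  over its isotopomers, differs from the true preimage whenever same-shift
  isotopomers have unequal fractions.

Two degenerate corners are worth naming. For the empty moiety ($n = 0$) all
spaces collapse to a single state. For a single-isotope element ($m = 0$)
the indeterminate state coincides with the only determinate state;
`ic_matrix()` then returns the trivial $[1]$, matching the printed family,
while `convert_fractions()` keeps the full $2^n$ syntactic cumomer indexing
so that EMU block sums stay well defined in every case.

### Heteronuclear moieties

A moiety mixing elements (say C with shift 1 and H with shift 2) uses a
single moiety-wide $m = \max$ over its atoms. States exceeding an atom's own
element shift are representable *surplus* states and must carry probability
0; `validate_fractions()` enforces this, and marginalization, mass
projection and the MS tensor all check it before discarding those rows.

## Decomposition and the cascade

`decompose_reaction()` implements the power-set construction: for each
product and each non-empty subset of its atoms, one identity equates the
product EMU with the flux times the monoidal product of the reagent EMUs
contributing those atoms. The empty set is excluded on both sides — keeping
it would force $f(\emptyset) = v \cdot f(\emptyset)$ for the monoid
identity. A reaction with products of $n_p$ atoms yields
$\sum_p (2^{n_p}-1)$ identities; the enumeration is exhaustive by design
(the count is intrinsic to the construction), with optional
backward-reachability pruning towards target EMUs as the graph-theoretic
optimization. Factors are sorted by key so decomposition output is
independent of how reagents and products are listed.

`build_cascade()` partitions identities by EMU size and classifies vertices:
*sources* are EMUs of metabolites with declared input labeling or with no
defining identity (the latter default to unlabeled — a delta at shift 0 —
with a warning, the standard convention for untracked inflows); *sinks* are
EMUs never consumed; the rest are intermediates. Multi-factor identities
become edges from virtual convolution vertices whose values are convolutions
of strictly smaller EMUs, which is what makes the system a well-founded
cascade. At each size the linear system

$$\left(\mathrm{diag}(\text{total influx}) - A_{\text{intra}}\right) x =
  B\, a_{\text{sources}}$$

is solved directly. Pool stationarity (per-metabolite influx = efflux,
checked to $10^{-8}$ relative) makes total influx equal total efflux, so the
diagonal is the consistent-mass lumping and is strictly positive for any
subnetwork with throughput; a zero diagonal or a singular solve raises a
structured error naming the size and the strongly connected component
responsible.

Numerical choices: within-size cycles are handled by the direct sparse-free
dense solve rather than explicit inversion (the systems are small — one row
per same-size EMU); the relative residual of each solve must be below
$10^{-10}$; solved vectors are reported trimmed to each EMU's own mass range
$\sum_a \text{shift}_a + 1$. Flux scale invariance (only flux *ratios*
matter at steady state) falls out of the algebra and is property-tested.

## The brute-force oracle

`brute_force_isotopomer_solve()` is deliberately the *naive* method: a
Jacobi-style fixed point on the full joint isotopomer distribution of every
metabolite, with product distributions for condensations (inflowing moieties
are independent — the same assumption the EMU method makes), flux-weighted
mixing, and a $10^{-12}$ max-abs convergence tolerance (cap 50 000 sweeps).
It shares no code path with the cascade beyond the state enumeration, which
is what makes the central equivalence test meaningful: IM-projected oracle
marginals agree with cascade EMU solutions to well below $10^{-8}$ per entry
across hundreds of random networks, including cycles and heteronuclear
tracers.

## The fixture generator

`generate_fixture()` emulates small tracer experiments: 6 metabolites of up
to 3 atoms by default, single-shift carbon tracer, substrates with random
normalized isotopomer labelings, a 0.35 chance of bimolecular condensation
when two equal-rate pools are available, and a 0.25 chance of a two-reaction
futile cycle around an intermediate. Networks are grown from flux-carrying
active metabolites whose supply is always fully consumed (or split across
parallel branches with weights summing to 1), so pool stationarity holds by
construction rather than by post-hoc solving; atom maps are random
bijections with per-line transition labels. All randomness funnels through
one seed, making every fixture byte-reproducible.

What the generator does *not* emulate: measurement noise, natural isotope
abundance, compartmentation, reversible reactions with distinct net/exchange
parameterization, and metabolite symmetry (rotationally equivalent atoms
must be written out as half-weighted parallel reactions, the usual practice).
Passing tests therefore demonstrate the exactness of the algebra and the
solver on well-posed networks, not robustness to noisy or misspecified real
data.

## Measurement models

`high_res_tensor()` aggregates an EMU's isotopomer fractions into per-element
total shifts — one tensor axis per distinct element, in order of first
appearance; `collapse_tensor()` sums its anti-diagonals, recovering exactly
the low-resolution mass distribution `im_matrix()` produces (a tested
commutation). `deconvolve_derivatization()` removes a derivatization agent's
mass distribution by least squares on the banded convolution system,
clipping small negative artifacts at zero with a warning.

`nmr_splitting_integral()` returns the conditional probability of a detected
labeling pattern given the observed nucleus' state, as a quotient of EMU
fractions. Detected atoms that are NMR-indistinguishable are passed as an
equivalence group, expanding to "at least one atom of the group labeled";
with several groups each must contain a labeled atom. Only a single observed
atom is supported: the behavior under several simultaneously fixed observed
nuclei is not defined by the underlying quotient construction, so the
package does not guess one. The conditional is computed from a joint
isotopomer distribution (e.g. the oracle's); it is undefined — and raises an
error — when the observed state has probability zero.

## Problem sizes and runtime

The test suite exercises enumerations exhaustively to $n \le 4$, $m \le 3$,
sum rules on 1000 random vectors, and the cascade/oracle equivalence on 100
seeded fixtures (6 metabolites, ≤ 3 atoms); the full suite runs in about a
minute on one core. These sizes were chosen because the properties under
test are exact algebraic identities — agreement at small, exhaustively
coverable sizes plus the structural induction built into the constructions
(Kronecker powers, size-ascending cascade) is the strongest evidence the
desk-scale ground truth supports. Conversion matrices grow as
$(m+2)^n \times (m+1)^n$, so for large moieties users should work in the
EMU/mass representation (the cascade never materializes whole-metabolite
matrices) rather than converting full isotopomer vectors.

## Known limitations

- Forward simulation only: no flux estimation from measured labeling.
- Steady state only: the non-steady-state residual is what the solver sets
  to zero; time-resolved (isotopically nonstationary) labeling is out of
  scope.
- Conditionally dependent atom labeling (within-moiety correlations imposed
  at the source beyond what a joint input vector expresses) and radioactive
  decay are not modeled.
- No natural-abundance correction of measured MIDs.
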