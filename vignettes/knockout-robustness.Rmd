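---
title: "Knockout robustness of stochastic input–output maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout robustness of stochastic input–output maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knockoutr)
```

## The model

The package works with a fixed, fully finite setting. A *state system*
consists of input nodes $I = \{1,\dots,n\}$ with finite alphabets
$\mathcal X_i$ and a finite output alphabet $\mathcal Y$. The mechanism is a
Markov kernel $\kappa(\boldsymbol x; y)$: every joint input configuration
gets a probability distribution over outputs. Inputs arrive according to a
distribution $\mu$ with support $S$. Everything is an exact probability
table; there is no sampling, no estimation, and no noise model. This is a
deliberate scope decision: the theory characterises robustness of the maps
themselves, and all guarantees below are algebraic identities checked to
numerical precision, not statistical statements.

A *knockout* of a node set $K$ leaves the system running some kernel
$\kappa_J$ on the survivors $J = I \setminus K$. Nothing ties $\kappa_J$ to
$\kappa$ a priori; the package treats the complete family
$(\kappa_J)_{J \subseteq I}$ — the *functional modalities* — as the full
specification of a mechanism.

Three views of robustness are implemented and connected:

1. **Information-theoretic.** `exclusion_dependence()` is the
   $\mu$-averaged KL deviation of $\kappa_J$ from $\kappa$. Its minimiser
   over all kernels on $J$ is the conditional $p(y \mid \boldsymbol x_J)$
   (`optimal_postknockout()`), and the minimum equals
   $I(Y; X_K \mid X_J)$. Requiring this to vanish for all $|K| \le k$
   (`k_exclusion_independent()`) is the definition of a robust pair
   $(\mu, \kappa)$.
2. **Geometric/neutral.** Joining support points at Hamming distance
   $\le k$ partitions $S$ into components; $(\mu, \kappa)$ is robust
   exactly when $\kappa$ is constant on every component, equivalently when
   the joint distribution is a component mixture
   $\sum_N \alpha(N)\,\mu_N(\boldsymbol x)\,\lambda_N(y)$. Both directions
   are implemented: construction (`neutral_kernel()`, `mixture_joint()`)
   and decomposition with a witness on failure
   (`decompose_robust_joint()`).
3. **Mechanistic/Gibbs.** An energy $Q = \sum_A \phi_A(\boldsymbol x_A; y)$
   determines $\kappa$ by Boltzmann–Gibbs normalisation, and a knockout
   deletes every term meeting the removed nodes
   (`modalities_from_interactions()`). Möbius inversion on the subset
   lattice inverts this map for any strictly positive complete family
   (`mobius_invert()`), so the interaction picture is fully general; it is
   unique only up to *gauge* — adding input-only functions to terms.

## Parameters that matter

* `k` (integer, 0–n): the maximal knockout size a statement refers to.
  Everything downstream — adjacency, components, the conditional
  independences, $r = n - k$ — is parametrised by it. There is no default;
  it is part of the scientific question.
* `tol` (nats or probability sup-norm, default `1e-9`): the numerical
  threshold for "zero" in conditional-mutual-information verdicts and for
  "constant" conditionals. The default suits exactly-constructed tables,
  where violations are at machine precision ($10^{-15}$); data read from
  files with fewer digits may need a looser setting. CLI-overridable via
  `--tol`.
* Normalisation tolerance (`1e-9` on read): tables whose rows sum to 1
  within it are renormalised exactly; anything worse is an error, never
  silently fixed.
* Strict-positivity floor (`1e-12`) for logarithms in `mobius_invert()`:
  entries at or below it raise an error. Clamping would silently turn a
  structural zero into an arbitrary large negative energy, corrupting every
  recovered term, so it is refused.
* `eps` in `smooth_kernel()`: deterministic (e.g. Boolean) kernels are
  outside the strictly positive Gibbs class; mixing with the uniform kernel
  at weight $\varepsilon$ is the standard approximation. Using the *same*
  $\varepsilon$ for every member of a family preserves the equalities
  between kernels that robustness asserts, exactly.
* Rank tolerance (`1e-10`) in `solve_protocol()` / `design_report()`:
  singular values below it (relative to the largest) are treated as null
  directions of the experiment design.

## Numerical choices

* **Configuration order.** Joint configurations are enumerated
  lexicographically (first input slowest, labels in alphabet order); all
  matrices use this canonical row order, and all outputs are reproducible
  because of it. Components are named by their lexicographically smallest
  member.
* **Off-support rows.** The optimal post-knockout kernel is only determined
  where $p(\boldsymbol x_J) > 0$; elsewhere any row is optimal. The package
  fills such rows uniformly: the choice is symmetric, stable under
  relabelling, and documented rather than hidden. The same rule fills
  off-support rows of neutral kernels.
* **Infinity.** The KL conventions force $D = \infty$ when the
  post-knockout kernel forbids an observed output. This is represented as
  IEEE `Inf` — an explicit non-finite value with saturating arithmetic —
  never as a large finite sentinel.
* **Gauge fixing.** The canonical interaction representative has zero mean
  over outputs for every $(A, \boldsymbol x_A)$. The projection is linear
  and idempotent, leaves every modality unchanged, and makes round-trip
  comparisons exact. `output_dependence()` (max spread over outputs) is
  zero precisely on pure-gauge terms and is how "contributing" terms are
  counted.
* **Exact rationals.** The coefficients $\alpha_{A,J}$ of the low-order
  representation are alternating binomial sums prone to cancellation; they
  are evaluated in exact rational arithmetic (integer numerator/denominator
  pairs, gcd-reduced; all magnitudes stay far below $2^{53}$ for
  $n \le 16$) and converted to floating point only at energy assembly.
* **Subset lattice.** Subsets are enumerated in bitmask order and keyed by
  comma-joined node names (`"{}"` for the empty set, since empty list names
  are not retrievable in R). Full-lattice operations are guarded at
  $n \le 16$; the practical test scale is $n \le 6$.
* **Least squares.** Protocol solving uses the minimum-norm SVD solution of
  a shared design matrix; the system decouples over output states, and
  because the right-hand sides are centred over outputs, the minimum-norm
  solution is automatically gauge-normalised. A hypothesis set counts as
  identifiable when the null space of the design has no component in its
  coefficient block; identifiable blocks of the minimum-norm solution are
  then unique regardless of what happens in unidentifiable directions.
  Overdetermined consistent protocols reproduce one solution; residuals
  above `1e-8` are flagged as model misfit rather than resolved.

## Design decisions where the ground was open

* The **minimiser freedom off support** (any row is optimal where
  $p(\boldsymbol x_J) = 0$) is resolved by fiat — uniform — because no
  principled choice exists in the theory.
* **Adjacency.** The canonical relation is Hamming distance $\le k$, which
  is what the characterisation theorems are about. A custom adjacency hook
  exists for illustrations (e.g. grid-metric neighbourhoods on two 16-state
  inputs) and is explicitly non-canonical: nothing proved about Hamming
  components transfers to it.
* **Identifiability criterion.** The worked identification examples are
  solvable by inspection; for general partial protocols the package uses a
  rank test on the gauge quotient. Input-only functions are excluded from
  the notion of identifiability altogether, since they never influence any
  modality.
* **Rejection witnesses.** Decomposition and neutrality checks return the
  first offending pair in canonical scan order, so failures are
  reproducible objects, not just booleans.
* At $r = n$ the low-order construction collapses: the generator $\psi_J$
  becomes, up to gauge, the log-kernel of $J$ itself, and the coefficients
  reduce to plain Möbius signs. The implementation verifies this collapsed
  identity numerically rather than assuming it.

## The synthetic generators

All test inputs are produced by seeded generators (`gen_six_node()`,
`gen_neuron()`, `gen_grid_support()`, `gen_random_system()`,
`gen_random_kernel()`), with the RNG algorithm pinned (Mersenne–Twister,
inversion normals) so fixtures are bit-stable across platforms.

* The **six-node system** has binary nodes and interaction terms exactly on
  $\{1,2,3\}, \{3,4\}, \{5,6\}$ with values uniform on
  $[-\text{amplitude}, \text{amplitude}]$ (default amplitude 1 — order-one
  energies keep kernels well away from 0 and 1, the regime where log-domain
  identification is well-conditioned).
* The **neuron** has $\pm 1$ alphabets and singleton terms
  $\tfrac12 w_i x_i y$; every knockout modality has a logistic closed form,
  giving an exact external check on the whole Gibbs pipeline.
* The **grid support** puts two 16-state inputs (256 joint configurations)
  and builds a support with a prescribed number of Hamming components by
  placing disjoint "crosses" in disjoint row/column blocks — a construction
  that makes the component count certain by design rather than by chance.
  $\mu$ is uniform on the support.
* **Random systems** draw exponential input masses (optionally sparsified
  to a target support density) and Gaussian interaction terms on given or
  randomly included hyperedges.

What these generators emulate is the *mathematical* setting: exact tables,
modest $n$, full control of interaction structure. What they do not emulate
is anything statistical about real knockout data — measurement noise,
finite-sample kernels, partially observed supports, unknown alphabets.
Passing tests therefore certify the algebra and the implementation, not
robustness conclusions about any empirical system whose kernels must first
be estimated.

## Problem sizes and test scales

The test suite and the acceptance script run at the scales the theory makes
cheap and exhaustive rather than sampled: random systems with $n \le 4$ and
alphabets up to 3 (100 instances for the exclusion-dependence chain and the
Möbius round trip), neutrality equivalence sweeps over system shapes with at
most 243 input–output states, neurons at $n = 6$ over all 64 knockout sets
(20 weight vectors), the low-order identity at $n = 4, r = 2$, and the
six-node example for identification. Tolerances are `1e-9` for algebraic
identities and `1e-8` for the low-order verification (which composes more
floating-point stages).

## Known limitations

* No estimation of $\mu$ or $\kappa$ from sampled data, and no statistical
  conditional-independence testing; inputs are exact tables by design.
* Deterministic kernels enter the Gibbs machinery only through
  $\varepsilon$-smoothing; recovered interaction magnitudes then scale with
  $\lvert \ln \varepsilon \rvert$ and should be compared, not read as
  physical energies.
* The interaction representation evaluates off the support of $\mu$, which
  amounts to an extrapolation between neutral components. The package
  exposes these values (they are what the Gibbs formulas return) but makes
  no correctness claim about them: for a robust system with disconnected
  support, the full-lattice Möbius recovery can carry order-one terms of
  order $> r$ whose entire content lives off the support. The low-order
  guarantee (`verify_low_order()`) is agreement *on the support*, and that
  is what is tested.
* Whether every family built by `low_order_modalities()` is itself
  k-exclusion independent is not asserted by the theory; empirically,
  generic generators produce families that fail the precondition check, and
  `verify_low_order()` reports this as a distinct verdict instead of
  assuming the converse.
* Full-lattice operations are exponential in $n$ and guarded at $n = 16$;
  identification design matrices grow with
  $\sum_J \lvert \mathcal X_J \rvert$ and are meant for small systems.
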