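---
title: "Correcting isotope labeling data: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting isotope labeling data: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midcorrect)
```

## The correction model

A stable-isotope tracing measurement of one metabolite yields a vector
`v_m` of signals, one per observable labeling state. Each truly labeled
species spreads its signal over several of those states: natural heavy
isotopes of all atoms move signal to higher mass shifts, and isotopic
impurity of the tracer substrate moves signal from nominally labeled
positions to lower shifts. Both effects are per-atom independent
probabilities, so the expected measurement is linear in the true species
abundances `v_c`:

$$ v_m = P \, v_c, \qquad v_c \ge 0 $$

Column *j* of the k × k matrix *P* is the probability distribution of the
*j*-th labeled species over the measured states. The package's job is (a)
constructing *P* per molecule and acquisition mode, and (b) inverting the
system under non-negativity.

Assumptions inherited from this model:

* isotope choices of distinct atoms are independent (no isotope effects on
  fragmentation or ionization);
* only nominal mass shifts matter at unit resolution (mass defect
  ignored); at high resolution, mass defects are fully resolved;
* the signal of a species is proportional to its abundance with the same
  proportionality constant across its isotopologues.

### Building a column: convolution of per-atom distributions

For a fragment carrying `t` tracer labels at nominal resolution, the
column is the convolution of

1. the **impurity distribution** of the `t` labeled positions — each
   carries the tracer isotope with probability equal to the tracer purity
   `p`, otherwise the light isotope; a Binomial(`t`, `p`) mapped to shifts
   `{0, s, ..., t·s}` for tracer shift `s`. At `p = 1` this is the fixed
   point mass at `t·s`;
2. the **natural distribution** of the remaining unlabeled labelable
   positions (the `count`-fold convolution of the element's abundance
   table — a binomial for two-isotope elements, a shift-collapsed
   multinomial otherwise);
3. the natural distribution of every plain (non-labelable) atom,
   including plain atoms of the tracer element.

Purity correction therefore makes *P* genuinely two-directional: natural
abundance populates the upper triangle's transpose (contributions upward
in mass), impurity the other direction. Both are handled by the same
convolution; no separate sequential correction pass is needed, which
matters because the two effects interact within a single column.

In MS/MS mode the product-ion and neutral-loss fragments get independent
distributions, and the entry for measured transition (p, q) given species
(t_prod, t_nl) is `d_prod(q | t_prod) · d_nl(p − q | t_nl)`. In
high-resolution multi-tracer mode only the tracer isotope of each tracer
element contributes (everything else is resolved away), so the column for
label vector `t` is an outer product over tracer elements of
`Binom(t_e, purity_e) ⊕ Binom(N_e − t_e, a_e)` convolutions, with `N_e`
the element's total atom count in the measured ion and `a_e` the natural
abundance of its tracer isotope. Notably, natural ¹⁷O is excluded when
¹⁸O is the tracer: a non-tracer heavy isotope produces a resolvable mass
defect, so it does not interfere with the tracer's label-count ladder.

### Measured bins, binning of multi-shift tracers, dropped mass

The measured states are fixed by the mode formulas (k = n+1,
(n+1)(m+1), Π(nᵢ+1)). For tracers with nominal shift > 1 (e.g. ¹⁸O,
shift 2), MS¹ bins sit at label multiples of the tracer shift; odd
natural-abundance shifts (¹⁷O) fall between bins. All probability mass
outside the measured bins — above the maximum label or off-bin — is
treated as unmeasured and dropped, so column sums may be slightly below
1. The per-column dropped mass is kept as an attribute and reported in
the run log when it exceeds 1e-6, since large dropped mass signals an
inappropriate molecule definition. Row and column orderings are
lexicographic ascending everywhere, making outputs bit-reproducible.

Convolutions are carried out in double precision with no term pruning;
for the molecule sizes this package targets (tens of atoms) sparsity
tricks are unnecessary and keeping every term preserves the closed-form
binomial identities to machine precision.

## Solving under non-negativity

`correct_vector()` delegates the constrained solve to the Lawson–Hanson
active-set algorithm (`pracma::lsqnonneg`), which returns the global
optimum of this convex problem; the test suite verifies the
Karush–Kuhn–Tucker conditions directly and cross-checks against an
independent quadratic-programming solver. When the unconstrained solution
is feasible it is returned exactly, so noise-free simulated data
round-trip to ~1e-15 relative error. The relative residual
`‖P v_c − v_m‖₂ / ‖v_m‖₂` is attached to every fit; it is zero for
representable data and grows with measurement inconsistency.

Operational policies the model itself does not dictate:

* **Missing values** (default): empty cells are replaced by 0 and a
  warning is logged, so one bad cell does not sink a batch. Under
  `strict_na = TRUE` the affected molecule/sample is reported as
  all-missing instead. Both semantics are explicit because neither is
  canonical.
* **Negative measured values** arise from baseline subtraction and are
  clamped to 0 with a warning during validation.
* **Data-quality alert**: relative residual above `residual_warn`
  (default 0.05, i.e. 5% of the measured signal unexplainable by any
  non-negative composition) names the molecule and sample in the run
  log. The default is a pragmatic screening threshold, not a significance
  level.
* An ill-conditioned *P* (condition estimate > 1e12) attaches a warning
  rather than failing: the NNLS solution is still defined, but small
  measurement errors may be amplified.

## The synthetic-data generator

The simulator applies the forward model: `v_m = P v_c` exactly, plus an
optional truncated Gaussian noise term with standard deviation
proportional to each signal (`noise_sd`), reflecting that peak-area
errors scale roughly with peak size. It emulates the *linear-mixing*
structure of real data and nothing else: no chromatographic drift, no
detector saturation, no correlated integration errors between adjacent
isotopologues, no ionization suppression. Passing round-trip tests
therefore demonstrates the correctness of the matrix construction and
solver — it does not certify performance on real spectra whose errors
violate the noise model.

Fixture choices baked into the generator:

* `alanine_mixture()` returns four known isotopomer mixtures
  (concentrations in µM). The two singly labeled isotopomers are pooled
  into m+1: positional isomers are indistinguishable at nominal
  resolution. `tms_alanine()` models the silylated derivative with a
  parameterized number of TMS groups (default 2 → `LabC3 C6H23NO2Si2`),
  since only the plain-atom envelope depends on it.
* `composition_series()` sweeps hypothetical molecules with one labelable
  carbon and growing plain C/Si content, equal true m+0 and m+1
  abundances, and reports the uncorrected ratio; for ten carbons the
  closed form `0.9893¹⁰ / (10·0.0107·0.9893⁹ + 0.9893⁹) ≈ 0.8937` pins
  the value.
* `multitracer_scenario()` uses an asparagine-like molecule (`LabC4
  LabN2` core plus a plain `C4H12O2` backbone) with truth concentrated on
  highly labeled states — 0/0 = 20, 3/0 = 2, 3/1 = 2, 3/2 = 30, 4/1 = 30,
  4/2 = 100, all other states 0 — measured at 98%/98% purity. The values
  are package constants chosen so that the 3/1 state sits between two
  abundant neighbours and visibly accumulates ¹³C impurity signal from
  4/1 plus ¹⁵N impurity signal from 3/2 when purity correction is
  disabled; the directional effect, not the specific numbers, is the
  point.
* `random_dataset()` draws truth components i.i.d. exponential with mean
  100 (arbitrary units) — heavy-tailed enough to produce both dominant
  and near-zero states, which is the regime where the non-negativity
  constraint matters — and requires an explicit seed.

## Element table and grammar decisions

`default_elements()` ships IUPAC-style natural abundances for C, H, N, O,
Si, S (e.g. ¹³C 0.0107, ¹⁵N 0.00364, ²⁹Si 0.04685/³⁰Si 0.03092).
Published abundance tables differ in the 4th–5th decimal; users needing a
specific table supply their own CSV via `read_elements()`. Tracer purity
lives with the element definition (one value per tracer element, a
property of the tracer substrate), overridable per run via the CLI
`--purity EL=VALUE` flag.

The formula grammar marks labelable atoms explicitly (`LabC5C7H20NO2`)
instead of inferring them from position, making definitions order-free
and unambiguous; repeated tokens accumulate. Molecule names may not
contain `_`, which separates the name from the state in measurement keys
(`Pro_3`, `Asp_3.2`, `Asn_3.1`). High-resolution keys join label counts
with `.` — display conventions often use `/`, which is unsafe in file
paths.

## Validation scale and limitations

The test suite verifies every matrix entry against exhaustive enumeration
of per-atom isotope assignments for 50+ randomized molecules (≤ 12 atoms,
elements drawn from C/H/N/O/Si/S, purities 1/0.99/0.98, all three
modes), checks the binomial closed forms to 1e-14, and runs
simulate-then-correct round trips over 100 random truth vectors per mode
at 1e-8 relative tolerance. Molecule sizes in the enumeration tests are
capped so the brute-force oracle enumerates at most ~6·10⁴ assignments
per distribution; the convolution engine itself has no such limit.

Known limitations:

* Only nominal shifts are modeled; isotopic fine structure and
  resolution-dependent partial peak merging (between the unit-resolution
  and fully-resolved extremes) are out of scope.
* Charge states > 1 and adducts are not handled; formulas must describe
  the measured ion.
* No error propagation: corrected values come without confidence
  intervals, and the residual is a diagnostic, not an uncertainty.
* Positional isotopomers are invisible; only isotopologue counts are
  corrected.
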