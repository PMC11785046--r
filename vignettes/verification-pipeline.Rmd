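---
title: "Verifying mechanistic ODE models across simulation engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying mechanistic ODE models across simulation engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(verikit)
```

## The problem

Model repositories hold thousands of manually curated kinetic models encoded
in SBML. SBML specifies the model — species, compartments, parameters,
reactions — but not the computational experiment that produced a published
figure. SED-ML fills that gap: it declares which model to load, which values
to change, what time course to run, and which outputs to collect. When the
same SED-ML experiment is executed on two independently developed simulation
engines and the numbers agree, the model has been *verified*: the result is a
property of the model and experiment, not an artifact of one code base.
(Verification is distinct from validation against biology, which this
package does not attempt.)

In practice, legacy repository entries are rarely runnable as-is. Experiment
files point at model files that do not exist, reference deleted model
elements, define simulations no output uses, duplicate ids, format element
pointers inconsistently, or request millions of output points. Model files
carry their own scars: parameters initialized to `NaN` or infinity, invalid
visualization-package payloads, reaction-local parameters that some engines
cannot address. verikit packages the whole curation-and-verification loop:
structural validation of COMBINE/OMEX archives, a deterministic repair
catalogue with a replayable log, template-experiment generation, execution
on interchangeable engine adapters (including a built-in reference ODE
engine), and a tolerance-based replication criterion.

## The replication criterion

Two trajectories $a$ and $b$ for the same labeled output variable replicate
when every output point satisfies

$$|a_i - b_i| \le \rho \,\max(|a_i|, |b_i|) + \alpha_v,
\qquad \alpha_v = \max(\,f \cdot \mathrm{range}(a \cup b),\ \varepsilon\,)$$

with relative tolerance $\rho = 10^{-4}$ (the repository-wide replication
tolerance), range factor $f = 10^{-4}$, and absolute floor
$\varepsilon = 10^{-12}$. The two published ingredients are the relative
tolerance and an absolute tolerance scaled by the range of output values per
variable; the combining formula is this package's choice and is deliberately:

* **additive** (relative term plus absolute term), the standard
  numerical-comparison form;
* **symmetric** — normalizing by $\max(|a_i|,|b_i|)$ means no engine is
  privileged as "the reference", and swapping arguments cannot change the
  verdict;
* **range-pooled** — the range is taken over both trajectories jointly, so
  the absolute term is identical from both sides.

The range factor is not separately published; it defaults to the relative
tolerance and is configurable in `comparison_policy()`. Non-finite outputs
fail the comparison by default (`fail-on-any-nan`): a `NaN` is evidence of
failure, not of agreement. Comparison requires identical output grids and
does no interpolation — a grid mismatch means the engines interpreted the
experiment differently, which is precisely what verification must surface.

An entry is *replicated* when at least two engine runs succeed and at least
one pair of successful runs passes the criterion on every shared labeled
column (`build_verification_matrix()`).

## The reference engine and the absolute-tolerance vector

`compile_odes()` turns the SBML reaction network into
$\dot{x} = N\,v(x, t)$ plus rate-rule derivatives, with assignment rules
re-evaluated before every right-hand-side evaluation, function definitions
inlined by substitution, initial assignments evaluated in dependency order,
and amount/concentration bookkeeping per compartment size. Integration uses
variable-step stiff-capable solvers (deSolve) under two interchangeable step
controllers — `reference-lsoda` (Adams/BDF switching) and `reference-bdf`
(VODE) — registered as two engine adapters, giving an internal two-engine
verification route with no external simulator.

Tunable solver parameters (all overridable per experiment through SED-ML
KiSAO algorithm parameters):

| parameter | default | KiSAO id | meaning |
|---|---|---|---|
| relative tolerance | `1e-8` | `KISAO:0000209` | per-step relative error control |
| base absolute tolerance | `1e-12` | `KISAO:0000211` | scalar floor, the engine default shipped by mainstream ODE biosimulators |
| atol adjustment factor | unset | `KISAO:0000571` (configurable) | per-variable absolute-tolerance scaling |
| max internal steps | `20000` | `KISAO:0000415` | step-count guard |

Two of these deserve comment.

**Relative tolerance `1e-8`.** Production engines commonly default to
`1e-6`. The built-in engine, however, is the *reference* against which other
runs are judged, and its own numerical error must sit far below both the
replication tolerance (`1e-4`) and the accuracy bound it is tested against
(`1e-8` absolute versus the analytic solution of decay chains). Measured on
the chain fixtures, lsoda at `rtol = 1e-6` commits absolute errors up to
about `1e-7`; at `1e-8` the worst observed error is below `5e-9`. The
tighter default costs little on desk-scale models and is overridden by any
experiment that specifies its own tolerance.

**The adjustment factor.** When set, the effective absolute tolerance
becomes a vector, `atol_i = factor × |x_i(0)|` — each variable is integrated
as carefully as its own initial scale demands. This mirrors the mechanism
that made multi-scale repository models replicate across engines: one widely
used engine always scaled the scalar default by the initial values before
handing it to the solver, others did not, and their results diverged until
the behavior was named as an explicit algorithm parameter that every engine
could honor. For variables starting at exactly zero, the scaled value would
be zero — meaningless to a solver — so the scalar base tolerance is used as
a floor at those indices. The zero floor and the absolute-value convention
are this package's choices (the published description covers only the
scaling itself); both are isolated in `make_atol_vector()` for comparison
against real engines.

## What the synthetic fixtures emulate

All test inputs are generated in code; nothing is downloaded.

* `make_chain_model(n, k, x0)` — irreversible unimolecular mass-action
  chains $S_1 \to S_2 \to \dots \to S_n$ in a unit compartment. With
  distinct rates the Bateman closed form (`chain_closed_form()`) is the
  exact solution, so the engine is verified against an analytic oracle that
  shares none of its code. Stiffness is obtained by rate-constant spread,
  never nonlinearity, keeping the oracle valid.
* `make_multiscale_model(scales)` — species starting at $10^{s_i}$. For
  three or more species, the first three form a stiff autocatalytic
  mass-action triad (slow feed, fast bimolecular step, quench) whose
  intermediate lives several orders of magnitude below the bulk species.
  Uncoupled multi-scale decays turned out not to expose tolerance
  pathologies at all — a variable-step solver integrates smooth independent
  exponentials accurately whatever the absolute tolerance — whereas on the
  stiff triad a loose scalar absolute tolerance visibly corrupts the small
  intermediate (it can even go negative) while the initial-value-scaled
  vector keeps it correct. That is exactly the multi-scale phenotype the
  adjustment factor exists for.
* `make_defective_entry(base, defect, seed)` — injects exactly one defect
  from the catalogue (fictitious `model.xml` source, dangling target,
  unused simulation, duplicated id, malformed pointer, excessive points,
  non-finite parameter, invalid layout payload), deterministically for a
  fixed seed. One defect per entry keeps one assertion per test; compound
  cases are built by chaining.

What the fixtures do **not** emulate: models with events, delays, or
algebraic rules (outside the engine's declared subset); the full diversity
of hand-written legacy XML; annotation semantics; and repository-scale
corpora. A green suite therefore demonstrates the mechanics of validation,
repair, execution, and comparison — not that any particular real corpus
replicates at a particular rate.

## The repair catalogue

`repair_all()` applies, in order: source resolution → id deduplication →
pointer canonicalization → pruning of unreachable elements → point capping.
Sources must resolve before pointers can be checked against a model, and
pruning runs late so nothing reachable is lost mid-repair. Every action is
logged as `(code, location, before, after)`; replaying the log on the
original input reproduces the repaired output, and a clean document passes
through bit-exactly.

Design points the published account leaves open, decided here:

* **Source-resolution scoring.** With several SBML candidates for a dangling
  source, candidates score `0.5 × filename similarity + 0.5 × fraction of
  the document's targets resolvable in the candidate` (the two published
  signals, equal weights, configurable), ties broken by lexicographically
  smallest location — fully deterministic.
* **Duplicate ids.** Structurally identical duplicates collapse into the
  first occurrence. Same-id-different-content elements are renamed with a
  numeric suffix (`_2`, `_3`, ... — the same scheme used when promoting
  local parameters); existing references keep resolving to the first
  occurrence, preserving the meaning of every reference that was previously
  ambiguous-but-resolvable. Inventing a reference redistribution would be
  guessing curator intent.
* **Dangling targets are never repaired.** A pointer whose id simply does
  not exist in the model is left untouched and reported; fabricating a
  target would silently change the experiment.
* **Point cap.** Legacy files request millions of output points; the
  published account names the act, not a threshold. The cap defaults to
  100,000 output intervals and is configurable; the validator flags the
  same quantity, so capped documents validate clean.
* **Non-finite parameters.** "Unused" is defined conservatively — referenced
  by no kinetic law, rule, initial assignment, event, or constraint math —
  and only unused non-finite parameters are reset (to 0, logged, and
  flagged reviewable; the replacement value curators used is not
  published). A *used* non-finite parameter is a fatal issue, never silently
  changed, since any repair would alter results.

## Template experiments

`build_template()` encodes the repository's generic experiment for entries
with no curated one: load the model, run a deterministic ODE time course for
ten time units, and export the levels of all dynamic variables — as a report
(time plus one column per variable) and as a 2D plot (each variable against
time). Ten time units is the fixed, published part; the step count (100
intervals, 101 points) is a plot-friendly default of this package, and the
algorithm id is the KiSAO term for CVODE-style deterministic integration
(`KISAO:0000019`), since the historical template files target deterministic
ODE simulation without naming an algorithm. Templates are emitted as SED-ML
L1V4; L1V3 is read and written for legacy documents (the only serialization
difference in the supported subset is the interval attribute name).

"Dynamic variable" has a single project-wide definition
(`list_dynamic_variables()`): species not declared constant — excluding
boundary species no rule governs — plus non-species quantities under rate or
assignment rules, in document order. Whether historical templates exported
dynamic compartments and parameters in addition to species is not
documented; including them via the single dynamic-variable rule is this
package's interpretation, and it errs toward exporting more columns (extra
shared columns only strengthen a comparison).

Template generation in `cmd_verify()` is automatic *only* when an archive
contains no SED-ML; curated experiments are never overwritten.

## Numerical and degenerate-input choices

* Comparison of output grids is exact (no tolerance): grids come from the
  same declarative experiment, so any difference is an interpretation bug.
* Zero-duration time courses return a single row of initial observables.
* A zero-range (constant) output column can only be matched through the
  absolute floor `1e-12`; without it, bit-identical constant columns would
  fail on a zero-divide.
* Species values follow SBML unit conventions: amounts are the solver
  state; symbols in math and in outputs are concentrations unless
  `hasOnlySubstanceUnits` is set, converted per (possibly time-varying)
  compartment size.
* Integration failures (step-size collapse, non-finite states) never
  propagate as exceptions past an engine adapter: they are captured in the
  result status, because "this engine cannot run this entry" is a data
  point, not a crash.
* Problem sizes in the shipped tests are desk-scale by design: chains up to
  five species, 101-point grids, three-decade multi-scale models. These are
  the regimes where the analytic oracle is exact and the stiff phenotype
  already manifests.

## Known limitations

* The SBML subset excludes events, delays, and algebraic rules; the SED-ML
  subset excludes repeated tasks, steady-state and one-step simulations,
  and parameter scans (all recognized and reported as unsupported rather
  than silently dropped).
* Tabular results export as CSV plus JSON metadata per report.
* The comparator checks all output points; whether a production comparison
  service subsamples is unknown, so exact parity with any deployed service
  is not claimed.
* Replication across the two built-in configurations is necessary but not
  sufficient evidence of engine-independence: they share the model
  compilation layer. The adapter registry exists precisely so external
  engines can be wrapped without touching the comparison machinery.
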