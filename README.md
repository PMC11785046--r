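# verikit

Validation, repair, and cross-engine verification of SBML/SED-ML simulation
experiments exchanged as COMBINE/OMEX archives.

Curated model repositories hold mechanistic ODE models encoded in SBML, but
SBML alone does not say how to reproduce a published result; that is the job
of SED-ML, the declarative simulation-experiment language. Legacy entries
are riddled with small defects — experiment files pointing at a `model.xml`
that does not exist, references to deleted model elements, never-used
simulations, duplicated ids, malformed element pointers, requests for
millions of output points, parameters initialized to `NaN`, invalid
layout payloads — any one of which makes an entry unrunnable. verikit is for
curators and modelers who want to make such entries runnable again and then
*verify* them: demonstrate that independent simulation engines produce the
same trajectories for the same declared experiment.

The package provides:

* **OMEX archive I/O and validation** — `read_omex()`, `write_omex()`,
  `validate_archive()`, `find_master()`; byte-preserving, deterministic
  round trips.
* **SED-ML parsing, semantic validation, and repair** — `parse_sedml()`,
  `validate_semantics()`, and a deterministic repair catalogue
  (`repair_all()`) with a replayable `(code, location, before, after)` log.
* **SBML curation transforms** — local-parameter promotion,
  initial-assignment inlining, non-finite-parameter scrubbing, invalid
  Layout/Render stripping, annotation-URI checks; all
  semantics-preserving and idempotent.
* **Template experiments** — `build_template()` encodes the generic
  ten-time-unit time course exporting every dynamic variable, for entries
  without a curated experiment.
* **A reference ODE engine** — `compile_odes()` builds `dx/dt = N v(x, t)`
  from the reaction network; two stiff-capable integrator configurations
  (`reference-lsoda`, `reference-bdf`) are registered as interchangeable
  engine adapters, including support for initial-value-scaled
  absolute-tolerance vectors (`make_atol_vector()`).
* **The replication criterion** — trajectories `a`, `b` match when every
  point satisfies `|a_i − b_i| ≤ 1e-4·max(|a_i|,|b_i|) + atol_v`, with
  `atol_v` scaled by the range of that variable's output values
  (`compare_resultsets()`, `build_verification_matrix()`).
* **Synthetic fixtures** — mass-action chains with exact Bateman closed
  forms, a stiff multi-scale model, and single-defect archive generators,
  so the entire pipeline tests offline (`make_chain_model()`,
  `chain_closed_form()`, `make_multiscale_model()`,
  `make_defective_entry()`).

## Worked example

Break a healthy entry the way legacy archives are broken, then let the
pipeline repair and verify it:

```r
library(verikit)

model <- make_chain_model(3, c(1, 0.5), c(1, 0, 0))   # S1 -> S2 -> S3
entry <- make_entry(model,
                    write_sedml(build_template(read_sbml(model), "biomodel.xml")))
broken <- make_defective_entry(entry, "model-xml-source", seed = 1)

res <- cmd_verify(broken, run_config(output_dir = tempfile()))
res$repair_log
#>             code    location    before        after
#> 1 rewrite-source model:model model.xml biomodel.xml
res$matrix
#> <verification_matrix entry> ran=2 replicated=TRUE
#>   reference-lsoda: success
#>   reference-bdf: success
#>   reference-bdf ~ reference-lsoda : match
```

The repair log shows the fictitious `model.xml` source being rewritten to
the actual SBML file; both reference-engine configurations then run the
experiment and their trajectories match under the replication criterion
(relative tolerance `1e-4` plus a range-scaled absolute term), so the entry
is replicated and `res$exit_code` is `0`.

The trajectories themselves, and their agreement with the analytic
(Bateman) solution of the chain:

```r
rs <- execute(entry, "reference-lsoda")
rs$reports$report$values[c(1, 11, 101), ]
#>      time       S1       S2       S3
#> [1,]    0 1.000000 0.000000 0.000000
#> [2,]    1 0.367879 0.477302 0.154818
#> [3,]   10 0.000045 0.013385 0.986570
cf <- chain_closed_form(c(1, 0.5), c(1, 0, 0), rs$reports$report$time)
max(abs(rs$reports$report$values[, c("S1", "S2", "S3")] - cf))
#> [1] 9.02e-11
```

`S1` decays as `exp(-t)`, mass flows down the chain (the three columns sum
to 1 at every time point), and the engine tracks the closed form to within
`1e-10` — far below the `1e-8` accuracy bound the engine is tested against.

A command-line wrapper over the same functions ships in `inst/cli/`:

```sh
inst/cli/verikit validate entry.omex --json
inst/cli/verikit repair entry.omex -o fixed.omex --log repairs.jsonl
inst/cli/verikit template model.xml -o simulation.sedml
inst/cli/verikit verify entry.omex --engines reference-lsoda,reference-bdf -o out/
```

Exit codes: `0` replicated, `1` ran but not replicated, `2` unable to run.

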