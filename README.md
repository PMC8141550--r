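# ionbindr

Ion-binding kinetics and binding-site geometry from replica ensembles of
molecular-dynamics trajectories.

## What problem this solves

Sodium binding to SLC6-family transporters (the serotonin transporter SERT
being the motivating system) happens on the nanosecond scale and is
intrinsically stochastic: one trajectory tells you almost nothing about a
rate. The informative experiment is a *replica ensemble* — dozens of
independent simulations of identical length, each watched for its first
binding event, many of them right-censored because the event never happens
inside the window. `ionbindr` is the analysis layer for that design:

- **Event detection** — vestibule entry past the extracellular-gate salt
  bridge (a plane-plus-lateral-radius predicate), binding-site occupancy
  with entry/exit distance hysteresis and minimum dwell, explicit
  censoring, binding-order statistics, and anion-release routing.
- **Association kinetics** — the plateau-constrained mono-exponential fit
  of the cumulative first-event curve,

  y(t) = N · (1 − e^(−b·t)),  N fixed to the number of replicas,

  with t½ = ln 2 / b and k_on = b · 10⁹ / c (M⁻¹s⁻¹ at concentration c),
  a closed-form censored-MLE cross-check
  b = n_events / (Σ t_observed + n_censored · T), and a replicate-level
  bootstrap CI. Returned as a classed model object (`kinfit`) with
  `print`, `summary`, `coef`, `predict`, `residuals`, `simulate`, `plot`.
- **Spatial fields** — ion density and mean displacement-rate maps on a
  0.1 nm voxel grid in a common Kabsch-superposed frame, written as
  OpenDX.
- **Induced-fit geometry** — binding-site compactness (mean
  coordinating-atom distance to centroid, 100 ps resolution, 1 ns running
  average), pre/post-binding splits, and sorted all-vs-all RMSD matrices
  of the coordinating atoms.
- **A synthetic replica generator with exact ground truth** — an
  event-driven hybrid mode (exact exponential binding times realised by
  scripted ion paths) and a spatial overdamped-Langevin mode in a
  vestibule-shaped potential, plus an Ornstein–Uhlenbeck coordinating-atom
  process that compacts on binding. Defaults emulate a 51 × 150 ns,
  150 mM study design with a 5.7 ns vestibule half-entry time, deep-site
  rates of 4.2·10⁷ and 1.9·10⁷ M⁻¹s⁻¹, and a 0.1 nm induced-fit
  compactness shift. Every estimator in the package is tested by
  parameter recovery against this generator.

Real-mode inputs are GRO or PDB topologies with multi-frame GRO or DCD
trajectories (nm/ns internally; Å-native formats converted on read).

## Worked example

Generate a small hybrid-mode ensemble with known ground truth, detect NA1
occupancy, and fit the association kinetics:

```r
library(ionbindr)

cfg <- synthetic_config(mode = "hybrid", n_replicas = 12, duration = 100,
                        dt_frame = 0.05, seed = 42)
g   <- generate_replica_set(cfg)
top <- g$replica_set$topology

na1  <- site_definition("NA1", select_atoms(top, na1_selection_expr()))
ions <- select_ions(top)
ev   <- do.call(rbind, lapply(g$replica_set$trajectories,
                              detect_site_occupancy, site = na1,
                              ion_selection = ions))
tab  <- event_table(ev, 12, 100, sites = "NA1")
ft   <- first_binding_times(tab, "NA1")

fit <- fit_binding_kinetics(ft, concentration = 0.15, n_boot = 200,
                            seed = 1, site = "NA1")
summary(fit)
```

```
Constrained mono-exponential association fit [NA1]
  y(t) = 12 * (1 - exp(-b t)),  plateau fixed at n_replicas
  b      = 0.006928 ns^-1  (95% CI 0.002269-0.01624)
  t_half = 100 ns
  k_on   = 4.62e+07 M^-1 s^-1 at 0.15 M
  censored-MLE cross-check: b = 0.005767 ns^-1 (16.8% from LS)
  events: 5 observed, 7 censored; SSE = 491.2
```

Five of twelve replicas bound within 100 ns; the constrained fit reads
b = 0.0069 ns⁻¹, i.e. k_on ≈ 4.6·10⁷ M⁻¹s⁻¹ at 150 mM, and the generating
rate behind this dataset was 0.0063 ns⁻¹ (4.2·10⁷ M⁻¹s⁻¹) — inside the
bootstrap interval. The MLE cross-check lands at 0.0058 ns⁻¹; with only
five events the two estimators differ by ~17%, which is why the interval,
not the point estimate, is the quantity to quote at this depth of
censoring.

The full pipeline (events → kinetics → fields → geometry, with a YAML
config, a deterministic manifest, and CSV/JSON/OpenDX outputs) runs as

```r
run_pipeline(list(synthetic = list(mode = "hybrid", n_replicas = 8,
                                   duration = 50, dt_frame = 0.01),
                  output = "out", seed = 1))
```

or from a shell via `Rscript inst/cli/ionbindr.R run --config cfg.yaml`.

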