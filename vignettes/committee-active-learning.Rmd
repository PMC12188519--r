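---
title: "Methods: asynchronous query-by-committee active learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asynchronous query-by-committee active learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the workflow
model and its assumptions, the parameters that matter, what the demo stack
does and does not emulate about production deployments, and the numerical
and design choices that were genuinely open.

## The workflow model

`qbcflow` orchestrates five kernel roles. Generators explore configuration
space; a committee of M surrogate models predicts energy and forces for
each explored configuration; the controller aggregates the committee,
decides reliability, and routes work; oracles produce ground-truth labels;
trainers grow each member on the accumulating labeled set and periodically
replicate their weights to the prediction side. Two properties define the
architecture:

1. **Central uncertainty, local reaction.** Only the controller decides
   whether a prediction is reliable (committee energy spread
   $\sigma \le \sigma_\mathrm{thr}$) and whether it is labeled
   ($\sigma > \sigma_\mathrm{thr}$ by default, or a user selection hook).
   Generators receive the verdict and own only the *reaction*: propagate,
   tolerate up to `patience` consecutive unreliable steps, or restart.
2. **The fast loop never waits.** Generation–prediction exchange proceeds
   at one cycle per virtual time unit regardless of oracle latency or
   training cost. Oracle and training work is queued with configurable
   virtual costs and handled between cycles; its only influence on the
   fast loop is through explicit weight-adoption events, which are atomic
   per member and version-monotone.

The serial event-queue scheduler is the canonical backend. It is
deterministic — identical configuration and seed give byte-identical event
logs — because every random draw comes from a per-generator RNG stream
(saved and restored around each draw) and slow events are processed in
(time, sequence) order. A multi-process message-passing deployment is what
the architecture is shaped for (fixed-shape payload schemas are registered
at startup precisely because such transports want predetermined buffer
sizes); no MPI binding for R is available in this build, so `plan_ranks()`
documents the rank layout such a deployment would use and
`run_workflow(backend = "mpi")` refuses with a message.

## The committee surrogate

Each member is a single-hidden-layer tanh network
$\hat E(x) = w_2^\top \tanh(W_1 x + b_1) + b_2$ on flattened coordinates,
with forces as the exact negative input-gradient. Committee diversity comes
from independent weight initialisation (seeds derived from the run seed and
the member id); optional bootstrap resampling of ingested batches is
available but off by default. The committee spread uses the population
(divide-by-M) standard deviation: the committee *is* the whole population
of models, and the choice must be fixed once for reproducibility.
Equality with the threshold counts as reliable; forwarding requires the
spread to strictly exceed it.

Training minimises $w_E\,\mathrm{MSE}(E) + w_F\,\mathrm{MSE}(F)$ with
full-batch Adam. Both terms have closed-form parameter gradients (the force
term involves the network's second derivatives; the implementation is
finite-difference-checked in the test suite). Energy targets are
standardised by the current training set's mean and standard deviation,
with forces scaled consistently; this keeps the output bias from having to
traverse the ~150-unit absolute energies of the demo surface at practical
learning rates. The validation split is a deterministic 10% chosen by a
multiplicative hash of each sample id, so the split is stable as the
dataset grows and a new batch never lands entirely in either split. Early
stopping watches the *validation* loss (the training loss keeps falling on
interpolating models); improvement or batch ingestion resets the counter,
and ingestion also clears a halt. Weights continue across ingests by
default — re-initialising during active learning is available
(`reinitialize_on_new_data`) but discouraged.

## Parameters that matter

All quantities are in reduced units (energy, length, mass and the Boltzmann
constant equal 1 unless an oracle defines otherwise).

| parameter | default | meaning / why |
|---|---|---|
| `uncertainty_threshold` | 1.0 | the practitioner's accuracy target: committee spread above this marks a configuration worth an oracle call. ~0.7% of the demo surface's 150-unit valley range. |
| `patience` | 2 | steps a trajectory may continue on uncertain forces before restarting; small values keep exploration honest, large values chase frontiers. |
| `training_buffer_threshold` | 16 | labels per flush; the whole batch is broadcast to every trainer (members see identical data, differing by initialisation). |
| `weight_sync_period` | 5 | epochs between weight exports; the prediction side adopts each export atomically. |
| `dt`, `friction`, `temperature` | 0.005, 2, 15 | Langevin integrator; $\gamma = 0, T = 0$ reduces exactly to microcanonical velocity-Verlet. $dt$ is set by the stiffest demo-surface curvature ($\omega\,dt \approx 0.05$). |
| `oracle_cost`, `train_cost` | 5, 2 | virtual-time costs in the serial scheduler, emulating expensive labeling and training relative to inference. |
| `oracle_queue_cap` | unbounded | bound on pending + in-flight label requests. With a finite label budget this is essential: it paces requests to labeling capacity so the budget is spent across the whole run, when the committee can inform selection, instead of on the first few hundred uninformed trajectory points. |
| `label_budget` | unbounded | total oracle calls; counted at forwarding time. |

## The integrator

`md_step` consumes exactly one force evaluation per step — the force at the
current position, which is what the prediction kernel can supply — using a
splitting in which the closing half-kick of a step is applied when the next
force arrives. At zero friction this composes to standard leapfrog /
velocity-Verlet (the NVE energy-conservation test runs at
$|\Delta E / E_0| < 10^{-4}$ over $10^4$ steps at $dt = 10^{-3}$ on a
Lennard-Jones dimer); with friction the Ornstein–Uhlenbeck velocity update
is exact and sits between the two half-drifts. Synchronised velocities for
energy bookkeeping are available via `sync_velocities`. A trajectory
restarts when its state becomes non-finite, when it leaves the sampler's
domain box, or when the patience budget is exhausted; restarts draw from
the global initial sampler (a config choice; resampling around the last
reliable configuration was the alternative) and continue the generator's
private RNG stream, so runs remain reproducible across scheduling orders.

## What the demo stack emulates — and what it does not

The demo oracles are closed-form potentials with analytic gradients: the
standard four-Gaussian Müller–Brown surface (parameters shipped as
constants; its landmarks are located by grid search plus BFGS plus Newton
polish at package-test time, not hand-typed) and Lennard-Jones clusters
with pair forces clamped below $0.3\sigma$. They stand in for
quantum-chemistry labelers: deterministic, cheap, and exactly
differentiable, which is what lets the suite pin ledger, physics, and
recovery properties tightly. They do *not* emulate label noise, oracle
failures, multiple electronic states, or the wall-clock variability of real
DFT — the virtual-cost model covers latency only. Likewise the
two-dimensional surface makes coverage-by-uniform-sampling far easier than
in the high-dimensional spaces where active learning earns its keep, which
is why the budgeted comparison below is the demanding test, and passing it
here says the *machinery* (selection, pacing, buffering, retraining) works,
not that these demo hyperparameters transfer to any particular molecular
system.

## The budgeted comparison: active vs random labeling

`compare_al_vs_random()` fixes an oracle budget of 300 labels and a
committee of M = 4, runs the full workflow (20 seed labels, then
uncertainty-driven exploration at temperature 15 with uniform restarts over
the standard viewing box, queue cap 8), trains a fresh committee on the
resulting dataset, and compares against a baseline that spends the same
300 oracle calls on uniform draws over the same box — every draw charged,
no free rejections. Both arms filter training structures to true energy
$\le 100$ (the field-standard high-energy filter: wall structures carry
force components in the thousands and would dominate the loss; the active
arm still pays budget for any wall labels its exploration requests), train
the identical fresh committee with the identical protocol (up to 3000
epochs, early-stop patience 300), and are scored by RMSE of the
committee-mean energy on the same fixed 50×50 grid restricted to the
valley region ($V \le 0$). Medians over five seeds are compared. The
design intent: the *only* difference between arms is where the oracle
calls were spent.

Two protocol details were decisive during development and are worth
recording. Without the queue cap, four generators forward the entire
budget within ~70 cycles — before a single training flush completes — and
"active" selection degenerates to the start of a random walk. And without
the high-energy filter, the handful of wall structures an exploring
trajectory visits poison the force loss badly enough that the committee
cannot fit its own valley data.

## Numerical choices

- Aggregation uses the centered one-pass formula
  $\sqrt{\operatorname{mean}((E - \bar E)^2)}$, not
  $\sqrt{\operatorname{mean}(E^2) - \bar E^2}$, to avoid catastrophic
  cancellation at large absolute energies.
- Non-finite committee output marks a sample unreliable (spread $\infty$)
  instead of propagating NaNs; the generator restarts.
- Oracle dispatch ties break toward the lowest-index idle oracle; slow
  events tie-break by insertion sequence.
- A trainer with a dataset too small to populate the validation split
  validates on its training loss; one labeled point is interpolated to
  $<10^{-6}$ loss in a few hundred epochs.
- Extended-XYZ floats are written with 17 significant digits so
  write-then-read is the identity; 2-D coordinates are zero-padded to one
  3-vector "atom" and un-padded on read via a `dim=` comment key.
- Checkpoints are taken *before* the final drain of the slow queue, so a
  resumed run continues the exact event sequence of an uninterrupted one
  (verified bit-exactly in the suite).
- Fixed-dataset committee training (`train_committee`) returns each
  member's *best-validation-epoch* weights rather than its final ones:
  full-batch Adam oscillates late in training, and a last-epoch snapshot
  can be an order of magnitude off the best model passed through (observed
  as occasional committees unable to fit their own training set).
- The Lennard-Jones recovery demo disables early stopping: the combined
  energy+force loss passes through a non-monotone warm-up (validation loss
  rises for tens of epochs while the network reorganises) that would halt
  training prematurely, and the full 1500-epoch schedule on a fixed
  220-sample dataset is cheap.

## Problem sizes

The suite and the acceptance script use: 1000 random committees for the
aggregation check; twenty 500-step workflow runs (2 generators, M = 2,
1 oracle) for ledger conservation; $10^4$ NVE steps and $10^5$ thermostat
steps for the integrator checks; five seeds at budget 300 for the
active-vs-random comparison; 220 dimer geometries for well recovery. These
sizes were chosen so the full suite runs in minutes on one CPU while every
check retains a comfortable margin over its tolerance.

## Known limitations

- No multi-process backend in this build; the serial scheduler is the
  canonical surface and the rank planner documents the intended layout.
- The committee regressor is a deliberately small dense network; it is the
  test vehicle for the orchestration, not a competitive interatomic
  potential architecture.
- The labeling decision consults the energy spread only; force-spread or
  combined criteria are expressible through the selection hook but no
  default is shipped, since there is no single field-standard choice.
- Buffer-adjust and selection hooks are required to be pure functions of
  their arguments; the controller does not defend against hooks that
  mutate external state.
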