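---
title: "Methods: parallel virtual screening with a grid-map LGA engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallel virtual screening with a grid-map LGA engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockscreen)
```

`dockscreen` is a desk-scale re-creation of the multilevel architecture used
to parallelize grid-map docking codes for virtual screening: a master–worker
scheduler distributing whole dockings across workers, per-worker grid-map
caches that trade file I/O for memory, and thread-level concurrency across
the independent genetic-algorithm runs inside one docking. The docking
engine itself is deliberately simplified — the package's claims are about
the *machinery* (identical output under any degree of parallelism, counted
I/O under cache policies, complete job accounting, contiguous logs), not
about scoring realism. This vignette records the model, the tunables, the
numerical choices, and what the synthetic test system does and does not
show.

## The docking model

One *docking* is one ligand scored against one receptor represented purely
by precomputed grid maps. A pose is parameterized by a genome:

* translation $\mathbf{t} \in \mathbb{R}^3$ — position of the ligand's
  root-group centroid (Å),
* a unit quaternion $q = (w, x, y, z)$ — rigid-body orientation,
* torsion angles $\tau_1, \dots, \tau_k \in (-180^\circ, 180^\circ]$ — one
  per rotatable bond, *relative to the input conformation* (the identity
  genome reproduces the file coordinates exactly).

Torsions are applied from the root outward, each rotating its moved set
about the current bond axis (right-hand rule looking from the proximal to
the distal bond atom); then the whole body is rotated about the root
centroid and translated. Rigid groups therefore remain internally rigid to
machine precision, which the tests assert directly.

The energy of a pose is

$$E = \sum_i \Big[ M_{t(i)}(\mathbf{x}_i) + q_i\,M_e(\mathbf{x}_i) +
|q_i|\,M_d(\mathbf{x}_i) \Big] \;+\; \sum_{(i,j)} \Big[
4\varepsilon\big((\sigma/r)^{12} - (\sigma/r)^6\big) +
\frac{332.0636\, q_i q_j}{4 r^2} \Big]$$

where $M_{t(i)}$, $M_e$, $M_d$ are the atom-type affinity, electrostatic
and desolvation maps evaluated by trilinear interpolation, and the second
sum runs over *eligible* intramolecular pairs: atoms separated by at least
three bonds and lying in different rigid groups. The Coulomb term uses the
conventional distance-dependent dielectric $\varepsilon_r = 4r$. This is a
declared simplification of the full empirical free-energy models used by
production docking codes (no desolvation volumes, no torsional-entropy
term, no directional hydrogen bonding); every acceptance-level claim in
this package is policy- or structure-based and does not depend on scoring
fidelity.

Two details worth recording:

* PDBQT files carry only rotatable bonds, so the bond graph needed for the
  "three bonds apart" rule is inferred from the input geometry with a
  1.9 Å cutoff (plus the declared rotatable bonds). This covers ordinary
  covalent distances in the toy chemistry without bridging nonbonded
  contacts.
* An atom outside the grid box contributes a fixed penalty of
  $+10^5$ kcal/mol *once* (its map terms are skipped), and the standalone
  `interpolate()` returns the same constant for an outside point. A penalty
  was chosen over boundary clamping because it keeps the genetic search
  inside the box without creating artificial minima on the faces.
  Pair distances in the internal term are floored at 0.01 Å so degenerate
  geometries produced by crossover stay finite.

## The search

Each docking comprises `ga_runs` independent Lamarckian GA runs. One run:

1. initializes `ga_popsize` genomes — translation uniform in the box,
   orientation uniform on the quaternion sphere (Shoemake's method),
   torsions uniform in $(-180, 180]$;
2. each generation applies rank-proportional selection (weight equal to
   rank, best individual heaviest — the plain deterministic variant, since
   fitness scaling adds tunables without changing any claim made here),
   two-point crossover at gene boundaries (rate 0.8; genes are the three
   translation components, the orientation as one gene, and each torsion),
   per-gene Cauchy mutation (rate 0.02; scales 2.0 Å for translations,
   0.2 rad orientation perturbation composed as an axis–angle rotation and
   renormalized, 30° for torsions), and elitism of one;
3. with probability `ls_frequency` (default 0.06) each individual then
   undergoes Solis–Wets local search, and an improved genome is written
   back — the Lamarckian step;
4. the run stops when `ga_num_evals` energy evaluations or
   `ga_num_generations` generations are reached. One evaluation is defined
   as one full-pose score. A generation is always finished once begun, so
   `evals_used` may overshoot the budget by at most `ga_popsize`; the
   Solis–Wets budget is clipped to the remaining allowance.

Solis–Wets proposes $x + b + \rho \cdot s \cdot N(0, 1)$ per gene (scales
$s$: 1.0 Å translation, 0.3 rad orientation, 30° torsion), accepts strict
improvements, updates the bias $b \leftarrow 0.2 b + 0.4\,\Delta x$ on
success and $b \leftarrow 0.5 b$ on failure, doubles $\rho$ after four
consecutive successes, halves it after four consecutive failures, and stops
below $\rho_{\min} = 0.01$ or at its budget (at most 300 iterations per
invocation). The single-sided variant was chosen over the reflected
two-sided one to keep one evaluation per iteration, which makes the budget
arithmetic exact.

Defaults for the GA operator rates follow the long-standing defaults of
grid-map docking practice (population 150, 250 000 evaluations, 27 000
generations, 20 runs, crossover 0.8, mutation 0.02, elitism 1, local-search
frequency 0.06); all are exposed in `docking_parameters()` and
`search_control()`.

## Determinism and seeding

The package's central claim is that *parallelism never changes output*.
Production codes seed each concurrent run from time plus a thread
identifier, which guarantees uniqueness but ties results to the execution
schedule. Here the unit of seeding is the **run, not the thread**: run $k$
of a docking draws from an independent stream seeded `base_seed + k`
(injective in $k$), generated by xoshiro256++ seeded through splitmix64 — a
portable 64-bit generator whose streams are identical on any platform.
Consequently a `RunResult` is a pure function of (ligand, parameters, map
contents, seed), and screens are *bit-identical* for any worker count and
any threads-per-docking — the output-equivalence property that production
systems can only state statistically ("substantially similar" RMSDs
between serial and parallel runs) holds here as exact equality, and the
test suite asserts it with `expect_identical`. Log lines are buffered per
run and written en bloc after all runs finish, so the docking log of an
8-thread docking is byte-identical to the serial one.

## The map cache and the I/O law

A worker holds one `map_cache()` for its lifetime. Under `reuse`, a map
read once stays resident until the worker terminates, and a docking that
introduces a previously unseen atom type lazily loads just that map; under
`reload`, residency is dropped after every docking. The cache counts file
reads per type, giving the exact I/O law the tests verify per worker:

* reuse: reads $=$ |union of the worker's ligand type sets| $+ 2$
  (electrostatic + desolvation),
* reload: reads $= \sum_{\text{jobs}} (|\text{types}| + 2)$.

The electrostatic and desolvation maps are cached under the reserved labels
`e` and `d` exactly like affinity maps. Cache policy provably never touches
numerics (the property tests score identical poses under both policies and
compare bitwise). All maps of one docking must share grid geometry; this is
validated when a docking begins.

## The scheduler

`run_screen()` mirrors a master–worker message choreography: the
coordinator (which never docks) reads the job list, appends each job to the
submitted log at dispatch, and records each worker's completion message in
the successful or failed log — so for every completed screen
`|submitted| = |successful| + |failed|` with disjoint id sets, which is
property-tested under randomly injected failures (deleted map files). A
failing job is recorded with its reason and the screen continues; a crashed
or timed-out worker (a per-job wall-clock limit guards liveness) fails its
remaining jobs rather than hanging the screen. Two transports implement the
same dispatch contract: an in-process pool (default, testable everywhere)
and forked workers via the `parallel` package.

One deliberate divergence: instead of dynamic pull-based assignment, jobs
are assigned to workers cyclically in dispatch order. With the uniform job
costs of the toy screens, dynamic pulling degenerates to exactly this
order, and a deterministic assignment is what makes per-worker map-read
accounting and cross-worker-count output identity *exactly* testable.
Failed dockings are recorded and not redispatched. Optionally jobs are
pre-sorted by descending torsion count (a stable sort, ties keep file
order), the classic load-balancing aid for heterogeneous libraries.
Profiling, when enabled, writes one CSV line per finished docking with
per-phase durations (grid-index, map, ligand loading, compute, log
writing); the `ave`/`rms`/`med`/`max` summary is provided by
`profile_summary()` but wall-clock values are inherently
hardware-dependent and are never used as correctness claims.

## The synthetic test system

`toy_complex_spec()` builds the study system used throughout the tests: six
receptor point atoms in an octahedral cage around a chosen `well_center`,
at the Lennard-Jones minimum distance of a broad map probe
($\sigma_{\text{map}} = 5$ Å by default, wider than the 8.0 Å grid box of
20 × 0.4 Å intervals), so the whole box forms one smooth bowl. Affinity
maps are the summed 12-6 potential of the cage (clamped at $+10^3$ to keep
the text files finite and interpolation well-behaved), the electrostatic
map is the summed charge potential of alternating ±0.1 e cage charges
(vanishing at the center by symmetry, clamped at $\pm 10^3$), and the
desolvation map is a smooth Gaussian occupancy (width 2.5 Å, amplitude
0.05). By construction the single-probe lattice argmin is the well center,
which an exhaustive-scan oracle verifies. Toy ligands are zigzag chains
(1.5 Å bonds, ±0.05 e alternating charges, 0–6 torsions encoded as nested
branch records). The smallest ligand the generator emits has two atoms, so
well recovery is measured as the distance from the best pose's root
centroid to the constructed center; the cage is wide enough that the
two-atom ligand's optimum straddles the center symmetrically. At the
reduced search budget used in the tests (population 50, 25 000 evaluations)
the recovery criterion — at least 9 of 10 seeded runs within 0.5 Å — was
frozen after an oracle run of the implementation that recovered the well in
all runs with mean error below 0.1 Å.

What the toy system does *not* emulate: chemically meaningful ligands or
receptors, rugged multi-well landscapes, map files produced by real grid
generators, or realistic I/O latency. Passing tests therefore certify the
parallel machinery and the declared algorithms, not docking accuracy on
real complexes.

## Problem sizes

The test and acceptance workloads were sized for a laptop-class single
core: the output-equivalence screen uses 10 jobs × 10 runs × 10 000
evaluations (three configurations), the accounting property uses 50
screens of 2–5 jobs at toy budgets, interpolation is checked on 1000
random points, and well recovery uses 10 seeds at 25 000 evaluations.
These run in seconds to tens of seconds while exercising the same code
paths as production-sized parameters; the format layer is additionally
exercised at the production grid geometry (60 intervals at 0.375 Å,
226 981 values per map).

## Known limitations

* The scoring function is a didactic stand-in; absolute energies have no
  chemical meaning.
* RMSD is computed without symmetry correction or superposition (poses
  share the receptor frame), so symmetric ligands can show inflated
  inter-pose distances.
* The bond-graph inference by distance cutoff is sound for generated
  ligands but could mis-bond pathological hand-written geometries.
* Failed jobs are not retried, and interrupted screens do not checkpoint.
* The fork transport relies on POSIX `fork()`; on platforms without it the
  in-process transport provides the same semantics serially.
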