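# abdyn

Domain-level analysis of antibody internal dynamics from molecular-dynamics
trajectories.

## The problem

IgG antibodies are Y-shaped: an Fc stem and two antigen-binding arms (Fab1,
Fab2) joined to it by flexible hinges. In long MD simulations of a
full-length IgG1 the two arms need not move alike — one arm can be
transiently tethered to the stem by a handful of persistent hydrogen bonds
and fluctuate far less than its free partner. `abdyn` is a toolkit for
quantifying exactly that, aimed at computational structural biologists who
already have trajectories (DCD) and a structure (PDB) and want reproducible
domain-level observables rather than per-atom noise.

The pipeline:

* **Six-bead coarse-graining** — each bead is the mass-weighted center of a
  domain pair (1 Fc CH3, 2 Fc CH2, 3 Fab1 CH1+CL, 4 Fab1 VH+VL,
  5 Fab2 CH1+CL, 6 Fab2 VH+VL), mapped from a YAML chain/residue-range
  config.
* **Nine geometric observables** per frame: R<sub>23</sub>, R<sub>25</sub>
  (Fab–Fc displacements), θ<sub>123</sub>, θ<sub>125</sub> (Fab–Fc
  orientations, vertex at bead 2), Θ<sub>1234</sub>, Θ<sub>1256</sub>
  (Fc–Fab dihedrals), R<sub>34</sub>, R<sub>56</sub>, R<sub>12</sub>
  (intra-fragment extensions) — plus histogram densities, Gaussian
  summaries, peak separations and a block-bootstrap variance-asymmetry
  ratio.
* **Hydrogen-bond persistence** — Baker–Hubbard-style D–H–A candidates,
  bound iff H⋯A < 0.25 nm **and** ∠D–H–A > 120° (both strict), occupancy
  per replicate, *persistent* = occupancy > 0.80, *stable* = persistent in
  ≥ 2 replicates.
* **Essential dynamics** — Kabsch superposition of every frame onto the Fc
  Cα atoms of the first frame, PCA of the Cα covariance, per-atom
  contribution vectors and exact per-fragment partial projections.
* **Pulling assay** — per-atom constant forces ±f·r̂ (f = 0.01 kcal/mol/nm)
  on Fab2/Fc along the initial COM–COM direction, endpoint external work
  W = Σ<sub>i∈Fab2</sub> f R⃗<sub>i</sub>·r̂ − Σ<sub>j∈Fc</sub> f R⃗<sub>j</sub>·r̂,
  and rupture detection on the inter-fragment bond count.
* **Synthetic ground truth** — a generator that rebuilds frames from
  *exactly* planted observable values, programs hydrogen-bond schedules
  frame by frame, and an overdamped Langevin toy system with a breakable
  Fc–Fab2 well whose free-energy difference is computed by quadrature, so
  the Jarzynski bound ⟨W⟩ ≥ ΔF on the steered pulling work is testable.

## A worked example

Everything runs on generated data, so this works without any downloads:

```r
library(abdyn)
library(dplyr)

spec <- synthetic_antibody_spec(atoms_per_domain = 10, n_frames = 1000,
                                seed = 42, n_triads = 5)
sys <- build_synthetic_topology(spec)
asg <- assign_beads(sys$topology, sys$config)
gen <- generate_rigid_motion_trajectory(sys)

series <- compute_bead_trajectory(gen$trajectory, asg) |>
  evaluate_measures()
series |> group_by(label) |> summarise(mean = mean(value), sd = sd(value))
#> # A tibble: 9 × 3
#>   label         mean      sd
#>   <chr>        <dbl>   <dbl>
#> 1 R_12          4.00  0.0501
#> 2 R_23          5.80  0.394
#> 3 R_25          3.50  0.0515
#> 4 R_34          3.00  0.0502
#> 5 R_56          3.00  0.0505
#> 6 Theta_1234  100.   15.6
#> 7 Theta_1256 -100.    3.91
#> 8 theta_123   120.    9.90
#> 9 theta_125    60.0   3.05

variance_asymmetry(series$value[series$label == "R_23"],
                   series$value[series$label == "R_25"], seed = 1)
#> # A tibble: 1 × 6
#>   ratio ci_lower ci_upper n_frames n_boot block_length
#>   <dbl>    <dbl>    <dbl>    <int>  <int>        <int>
#> 1  7.66     7.34     8.04     1000    999           50
```

The summary table recovers the planted fluctuation model (broad Fab1:
R<sub>23</sub> = 5.8 ± 0.4 nm; tight Fab2: R<sub>25</sub> = 3.5 ± 0.05 nm),
and the variance-asymmetry ratio of 7.7 with a bootstrap CI excluding 1
says the Fab2 arm is significantly more constrained than Fab1 — the
signature the real analysis looks for.

For real data, replace the generator with

```r
st  <- read_structure("structure.pdb")
cfg <- read_config(system.file("extdata/igg1_domains.yaml", package = "abdyn"))
asg <- assign_beads(st$topology, cfg)
traj <- read_trajectory("run1.dcd", st$topology)
```

(the shipped IgG1 residue ranges are a documented reconstruction — check
them against your structure). A thin CLI over the same functions lives in
`inst/cli/abdyn.R` with subcommands `synth`, `beads`, `geometry`,
`hbonds`, `pca` and `pull-work`.

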