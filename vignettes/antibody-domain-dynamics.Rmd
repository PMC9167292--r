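---
title: "Domain-level analysis of antibody internal dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-level analysis of antibody internal dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abdyn)
library(dplyr)
```

## The model

An IgG antibody is a Y-shaped assembly of three fragments: the Fc stem and
two antigen-binding arms, Fab1 and Fab2, each arm joined to the stem by a
flexible hinge. `abdyn` analyzes molecular-dynamics trajectories of such a
molecule through a six-bead coarse-graining: each bead is the mass-weighted
center of one immunoglobulin domain pair —

1. Fc CH3, 2. Fc CH2 (together the Fc),
3. CH1+CL and 4. VH+VL of Fab1,
5. CH1+CL and 6. VH+VL of Fab2.

Bead positions are recomputed for every trajectory frame, and the internal
dynamics is summarized by nine observables: the Fab–Fc displacements
$R_{23}$ and $R_{25}$, the Fab–Fc orientations $\theta_{123}$ and
$\theta_{125}$ (angle at the middle listed bead, i.e. at Fc CH2), the
Fc–Fab dihedrals $\Theta_{1234}$ and $\Theta_{1256}$, the intra-Fab
extensions $R_{34}$ and $R_{56}$, and the intra-Fc extension $R_{12}$.
Comparing the Fab1 members of these pairs against their Fab2 counterparts
quantifies how *asymmetric* the two arms' dynamics are — the scientific
question this toolkit is built around: a Fab arm that is transiently
tethered to the Fc by persistent hydrogen bonds fluctuates far less than
its free partner.

Units are uniform throughout the package: nm, degrees, ps, amu and
kcal/mol (so forces are kcal/mol/nm). File readers convert once at the
boundary — PDB and DCD files store Angstrom.

## Conventions and numerical choices

* **Angles** are computed as the clamped arccos of the normalized dot
  product; the vertex is always the middle listed bead.
* **Dihedrals** are signed torsions in $(-180°, 180°]$ with the IUPAC
  right-hand rule about the $j \to k$ axis. No sign convention is implied
  by the observables themselves, so the convention is fixed, documented
  and pinned by tests (a mirror image flips the sign; reversing the bead
  order does not).
* **Degenerate frames** (zero-length angle arm, collinear dihedral
  planes) yield `NA`, a warning naming the frames, and are excluded from
  densities — never silently dropped, never a fabricated number.
* **Bead centers** are mass-weighted. Glycan residues (non amino-acid
  residue names) are never auto-assigned to beads; hydrogens count toward
  the center of mass when present.

## Hydrogen-bond persistence

Candidate bonds are donor–hydrogen–acceptor triples in the Baker–Hubbard
style: every N–H and O–H donor paired with every N or O acceptor outside
the donor's residue. Bond identity is the full D–H–A triple, so a donor
with two hydrogens contributes two bonds; the unique donor–acceptor *pair*
count is also reported, since published bond totals do not always say
which convention they use.

A bond is bound in a frame iff the H⋯A distance is strictly below 0.25 nm
*and* the D–H–A angle strictly above 120° — both strict, so a frame
sitting exactly at a cutoff is unbound. Occupancy is the exact bound-frame
fraction over all analyzed frames of a replicate (no smoothing window);
the trajectory stride is the user's choice and occupancies are always
fractions of analyzed frames. A bond is *persistent* in a replicate when
its occupancy exceeds 0.80 (strictly), and *stable* when persistent in at
least two replicates. Replicates with different candidate sets are aligned
by the union of bond keys, missing bonds counting as occupancy zero.

Salt bridges are not detected separately; when their geometry satisfies
the criterion they appear as hydrogen bonds. Periodic boundary conditions
are not handled (non-periodic, implicit-solvent-style trajectories are
assumed).

## Essential dynamics

Every frame is rigidly superposed (Kabsch, proper rotations only) onto the
Fc Cα atoms of the first frame, so the leading principal components
describe motion *relative to the stem*. The covariance of the aligned,
mean-centered 3M-dimensional Cα coordinate vector uses the population
normalization 1/F (the choice only scales eigenvalues). Eigenvector signs
are fixed by making the largest-magnitude entry positive, so outputs are
deterministic. Projections are computed against a single global mean
structure; fragment attribution uses *partial projections* — the sum of
per-atom displacement · eigenvector-block dot products over a fragment's
atoms — which decompose the full PC score exactly over disjoint fragments.
Covariance is computed per trajectory; pooling replicates is deliberately
not the default.

## The pulling assay and its work

The constant-force assay applies $+f\,\hat r$ to every Fab2 atom and
$-f\,\hat r$ to every Fc atom, with $\hat r$ the unit vector from COM(Fc)
to COM(Fab2) in the initial structure and $f = 0.01$ kcal/mol/nm per atom.
Per-atom magnitudes are constant, as the assay is defined, so the *net*
group forces are unbalanced when atom counts differ; no correction is
applied and the resulting slow center-of-mass drift is accepted. The
external work between a start and an end structure is the endpoint form

$$W = \sum_{i \in \mathrm{Fab2}} f\, \vec R_i \cdot \hat r
    - \sum_{j \in \mathrm{Fc}} f\, \vec R_j \cdot \hat r,$$

with raw displacements $\vec R$ — no superposition is applied first, which
makes $W$ frame-of-reference sensitive; this is recorded in the run
manifest. Rupture is the first frame at which the inter-fragment bond
count reaches zero and stays there for a configurable sustain window
(transient rebinding is ignored).

## The synthetic generator: what it emulates and what it does not

No trajectories are distributed with the structures this kind of analysis
is applied to, so the package ships a generator whose outputs have *known
ground truth* at every pipeline stage.

**Rigid-domain trajectories.** Per frame, the nine observables are drawn
from configurable normal distributions and the six bead centers are
rebuilt from the drawn values by a Z-matrix construction (bead 1 at the
origin, bead 2 on the z axis, arms placed by distance/angle/dihedral).
Domains then translate rigidly with their bead. Planted values are
therefore *exact* by construction, not approximate targets — the geometry
module must reproduce them to floating-point accuracy. The default
fluctuation model emulates asymmetric arms: Fab1 broad
($R_{23} = 5.8 \pm 0.4$ nm, $\theta_{123} = 120 \pm 10°$,
$\Theta_{1234} \pm 15°$), Fab2 tight
($R_{25} = 3.5 \pm 0.05$ nm, $\theta_{125} = 60 \pm 3°$,
$\Theta_{1256} \pm 4°$), intra-fragment distances stiff
($\pm 0.05$ nm). The means and the tight-vs-broad contrast mirror the
published fluctuation statistics of a hinge-tethered IgG1; exact widths
where no value is published are chosen once at values typical of domain
fluctuations in long implicit-solvent runs.

What the generator does **not** emulate: atomistic internal domain motion
(domains are rigid), correlated observables (each measure is drawn
independently), solvent, glycan chemistry, and the gradual binding
kinetics of real hydrogen bonds (planted schedules switch geometry
discretely between an exactly-bound pose, H⋯A = 0.20 nm at 160°, and an
exactly-unbound one at 0.40 nm). Passing tests on these trajectories
demonstrates correct *bookkeeping and statistics* — selection, reduction,
criteria, filters, decompositions — not force-field realism.

**The toy Langevin system.** A handful of beads under overdamped
Euler–Maruyama dynamics: harmonic springs, harmonic tethers and one
*breakable* Fc–Fab2 attraction — a truncated shifted harmonic well
$U(r) = \tfrac12 k (r - r_0)^2 - \varepsilon$ for $r < r_c$, zero beyond,
with $r_c = r_0 + \sqrt{2\varepsilon/k}$ so the potential is continuous at
the cutoff and the maximum restoring force $k(r_c - r_0)$ is closed-form.
The well (rather than, say, Lennard-Jones) makes rupture thresholds and
Boltzmann quadratures exact and easy. Friction enters as a single
coefficient ζ (force per velocity, kcal mol⁻¹ ps nm⁻²); in the overdamped
limit only this product matters, so bead masses never enter the dynamics.
Overdamped integration was chosen over velocity Verlet because it has
fewer parameters and the same equilibrium distribution.

Two pulling modes exist. Constant per-bead forces reproduce the assay's
force geometry and are used for deterministic rupture checks (at kT = 0 a
supra-threshold force must break the well in finite time; a sub-threshold
force must not). For the *free-energy bound*, the package uses the
standard steered protocol instead: a harmonic trap on the bead-2/bead-5
separation dragged at constant velocity, with the work ledger accumulating
the exact discrete protocol work
$U_{\mathrm{trap}}(r, c_{t+\Delta t}) - U_{\mathrm{trap}}(r, c_t)$.
The reason is thermodynamic: the Jarzynski relation
$\langle e^{-W/k_BT} \rangle = e^{-\Delta F/k_BT}$ (hence
$\langle W \rangle \ge \Delta F$) applies to the work of a controlled
switching protocol; a constant force applied for the whole run has no such
protocol, so the bound would not be well-defined for it.
`analytic_delta_f()` computes the matching reference
$\Delta F = F(c_{\mathrm{end}}) - F(c_{\mathrm{start}})$ by
one-dimensional quadrature over the pair separation with its exact $r^2$
Jacobian — exact for the two-bead system because all other degrees of
freedom separate. An interval mode (bound well vs released region) is also
provided; it tends to the well depth ε as kT → 0. Note that with the
radial measure the zero-depth limit of the interval ΔF is the (nonzero)
volume/entropy term, not zero — the energetic content vanishes, the
geometric content does not.

Integrator settings are chosen from the stiffest mode: the default
timestep keeps $\Delta t \, k_{\mathrm{tot}} / \zeta_{\mathrm{rel}}$ near
0.06, where Euler–Maruyama's stationary-variance inflation
($\approx (1 - k\Delta t / 2\zeta)^{-1}$) is below 3%; the kT = 0
energy-descent and kT/k variance tests validate this. The default pull
speed 0.05 nm/ps dissipates a clearly positive amount of work (so the
bound is informative against sampling noise at 200 repeats), while
0.005 nm/ps is quasi-static for this landscape: mean work agrees with
ΔF to well under a percent.

## Problem sizes used in validation

The validation suite runs entirely on generated data: 1000 random bead
quadruples for the geometry kernels; 10 triads × 300 frames for exact
schedule recovery; the persistence filter at realistic scale — 298 planted
Fab2–Fc bonds, 3 replicates × 250 frames, with 38 bonds planted above the
occupancy threshold in one replicate and 4 in two; 800 frames for PCA
attribution; 5000 frames for the asymmetry statistics; 200 seeded pulls
per speed for the work bound. These sizes give Monte-Carlo errors
comfortably inside the asserted tolerances while keeping the whole suite
desk-scale.

## Known limitations

* Domain boundaries come from a configuration file; the shipped IgG1
  ranges (`inst/extdata/igg1_domains.yaml`) are a documented
  reconstruction from standard EU-numbering domain boundaries, not a
  published per-bead table.
* XTC trajectories are not readable by the R toolchain; DCD is the
  supported trajectory format (read and write).
* The elbow angle of a Fab arm is not implemented — no operational
  definition is carried by the observables this package computes.
* Whether dihedral distributions should be reported signed or absolute is
  a presentation choice; the package outputs signed values and lets the
  densities reveal any symmetry.
* `W` from raw endpoint displacements is sensitive to rigid-body drift of
  the whole molecule between the two structures; interpret it with the
  manifest's "no superposition" note in mind.

## A short worked example

```{r example, eval = FALSE}
spec <- synthetic_antibody_spec(atoms_per_domain = 10, n_frames = 1000,
                                seed = 42, n_triads = 5)
sys <- build_synthetic_topology(spec)
asg <- assign_beads(sys$topology, sys$config)
gen <- generate_rigid_motion_trajectory(sys)

series <- compute_bead_trajectory(gen$trajectory, asg) |>
  evaluate_measures()
variance_asymmetry(
  series$value[series$label == "R_23"],
  series$value[series$label == "R_25"],
  seed = 1
)
```
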