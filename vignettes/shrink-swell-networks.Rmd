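---
title: "Modelling shrinkage of crosslinked semiflexible polymer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling shrinkage of crosslinked semiflexible polymer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyswell)
```

## The question the model isolates

Collagen hydrogels printed as microstructures shrink sharply when heated past
the helix-to-coil transition and recover on cooling. `polyswell` implements
the coarse-grained mechanism behind that observation: a mixture of
semiflexible bead-spring chains is allowed to self-assemble, permanently
crosslinked, and then switched from *stiff* (bending potential on, emulating
folded triple helices) to fully *flexible* (bending potential zero, emulating
denatured coils) while the crosslinks are retained. The only thing that
changes between the two stages is the chains' bending rigidity; everything
else — topology, sterics, thermostat, barostat — is identical. The volume
response of the network to that single switch is the object of study.

## Model

Each chain is a linear series of beads (one per monomer) with three
interaction terms:

* **Bonds** between consecutive beads, and crosslinks between beads of
  different chains: harmonic springs
  $V_\mathrm{bond}(d) = \tfrac{1}{2} K_\mathrm{bond}(d - 2r)^2$ with
  equilibrium at the bead diameter $2r$.
* **Sterics**: the repulsive $r^{-12}$ term of a Lennard-Jones potential,
  $V_\mathrm{rep}(d) = 4\varepsilon\,(\sigma/d)^{12}$, truncated at
  $d_\mathrm{cutoff}$ and excluded for directly bonded neighbors. The bead
  radius is tied to the repulsion length by $r = \sigma\,2^{1/6}/2$, so the
  bond equilibrium sits at the minimum of the corresponding full
  Lennard-Jones potential.
* **Bending** at every triad of consecutive beads:
  $V_\mathrm{angle}(\theta) = \tfrac{1}{2} K_\theta(\cos\theta -
  \cos\theta_0)^2$ with $\theta_0 = 180^\circ$. Note this potential is
  *quartic*, not harmonic, in $\theta$ near $\theta_0$ — the harmonic
  worm-like-chain relation between $K_\theta$ and persistence length does not
  apply, which is why calibration goes through a quadrature of the exact
  Boltzmann weight (below). Setting the `flexible` flag makes this term
  identically zero.

Dynamics are Langevin at temperature $k_BT$ with friction $m\gamma$,
integrated with the BAOAB splitting: free-particle diffusion matches the
Einstein relation $D = k_BT/(m\gamma)$ up to $O((\gamma\Delta t)^2/12)$ and
kinetic energy equipartitions to $k_BT/2$ per degree of freedom (both are
enforced by tests). Constant pressure uses the Berendsen weak-coupling
rescale: each step the box edge and all coordinates are multiplied by
$\mu = \left[1 - \kappa\,\tfrac{\Delta t}{\tau_p}(P_0 - P)\right]^{1/3}$,
clamped to $[0.95, 1.05]$ against pathological excursions. Pairwise
interactions go through a two-level Verlet-buffer neighbor list: an outer
super-list with a wide buffer absorbs the cost of the full pair scan, and the
force-loop list (buffer = skin, $0.3\sigma$) is refreshed from it whenever
the two largest bead drifts since its build could bridge the skin. All
distances use the minimum-image convention in a cubic periodic box.

### Reduced units and defaults

Lengths are in $\sigma$, energies in $k_BT$, masses in the bead mass, and
times in the bead diffusion time $\tau = (2r)^2/D$. Defaults (all
configurable through `sim_params()`):

| parameter | default | why |
|---|---|---|
| $K_\mathrm{bond}$ | $200\,k_BT/\sigma^2$ | bond-length fluctuations $\ll \sigma$ at the default $\Delta t$ |
| $\varepsilon$ | $1\,k_BT$ | soft steric repulsion of order the thermal energy |
| $d_\mathrm{cutoff}$ | $2.5\sigma$ | conventional Lennard-Jones truncation |
| $K_\theta$ | calibrated | solves $e^{-2r/l_p} = -\langle\cos\theta\rangle$ for $l_p = 50r$ (≈ 414 $k_BT$) |
| $\gamma$ | $1$ | velocity relaxation on the reduced time unit; $\tau = 2^{1/3}$ |
| $\Delta t$ | $1.587\times10^{-3}\,\tau$ | back-derived from the full-scale protocol's step-to-$\tau$ conversion (`audit_time_units()`); ≈ 150 steps per bond vibration period |
| $\tau_p$ | $0.07937\,\tau$ | the stated barostat coupling time (≈ 50 $\Delta t$) |
| $P_0$ (`p_target`) | $1.0\,k_BT/\sigma^3$ | see below |
| $\kappa$ | $1\,\sigma^3/k_BT$ | volume relaxation on the $\tau_p$ scale |

The experimental pressure is known only in native units ("1 bar"), with no
usable mapping to reduced units. The default was therefore calibrated
against the full-scale protocol's assembly behavior: at $P_0 = 1.0\,k_BT/\sigma^3$ the scaled-down mixture densifies
slowly during self-assembly (measured $V/V_\mathrm{CP}$: $2.7 \to 2.5$ over
the demo assembly, approaching the full-scale protocol's equilibrated assembly volume near
$2.4\,V_\mathrm{CP}$), whereas at $0.5$ it expands instead ($2.7 \to 3.1$). The
phase-behavior checks are run across
$P_0 \in \{0.2, 0.5, 1.0\}\,k_BT/\sigma^3$ rather than at one privileged
value. The potential is shifted so $V_\mathrm{rep}(d_\mathrm{cutoff}) = 0$;
energies therefore differ from the unshifted form by a constant while forces
(and hence all dynamics) are untouched.

## Protocol

`run_full_protocol()` executes, per replica:

1. **Initialization** — straight chains at random positions/orientations
   without overlap (`generate_initial_chains()`), thermal velocities.
2. **Compression** — the box edge is interpolated linearly to each target
   over the configured steps, coordinates rescaled affinely each step, while
   Langevin dynamics runs. (Whether the original work compressed affinely or
   let the barostat act is not stated; affine interpolation is deterministic
   and reproducible, and the subsequent NPT stage erases the difference.)
3. **Self-assembly** — NPT dynamics; the volume trace, normalized by the
   close-packing volume $V_\mathrm{CP} = 4\sqrt{2}\,r^3 N$ (equal to
   $N\sigma^3$ exactly for the tied bead radius), densifies toward the
   barostat's equation of state.
4. **Conformation selection** — `select_conformations()` picks $k$ stored
   snapshots whose volumes sit at evenly spaced quantiles of the observed
   volume range: a deterministic rule that guarantees the selected states
   span the densification trajectory from its largest to its smallest
   volume.
   Snapshots carry no velocities — stages restarted from them draw fresh
   Maxwell-Boltzmann velocities from their own seed, which Langevin dynamics
   rethermalizes within a tiny fraction of a stage.
5. **Crosslinking** — every inter-chain bead pair closer than $2r$
   (instantaneous snapshot geometry, minimum image) is independently linked
   with probability $P_{CL}$; springs are identical to bonds. A bead may
   carry several crosslinks (the literal Bernoulli rule); crosslinked pairs
   keep their steric repulsion, which merely shifts the spring's effective
   minimum marginally outward.
6. **Stiff stage, then flexible stage** — NPT dynamics with the bending term
   on, then off, crosslinks unchanged. For the $P_{CL}=0$ control the
   trailing `stage_steps` window of the self-assembly serves as the stiff
   stage and a bending-free continuation as the flexible stage.

The swelling factor $S_V = \langle V_\mathrm{flexible}\rangle /
\langle V_\mathrm{stiff}\rangle$ averages the trailing half of each stage
trace, pooling replicas by concatenation before averaging (so replicas of
unequal length contribute proportionally). `phase_map()` tabulates $S_V$
over $(\langle V_\mathrm{stiff}\rangle/V_\mathrm{CP},\ P_{CL})$ and flags
shrink ($S_V<1$) versus swell ($S_V>1$).

## Calibrating the bending constant

Because the angular potential is Gaussian in $\cos\theta$ (not in $\theta$),
$\langle\cos\theta\rangle$ is computed by adaptive quadrature of the exact
single-angle Boltzmann weight (`predicted_cos_theta()`), with the integration
window clipped to where the weight is numerically non-zero so the rule cannot
miss a narrow peak at large $K_\theta$. Under the interior-angle convention
(straight chain $\theta = 180^\circ$) the correlation of consecutive bond
tangents equals $-\langle\cos\theta\rangle$, so
`calibrate_bending_constant()` root-solves
$e^{-b/l_p} = -\langle\cos\theta\rangle(K_\theta)$:

```{r}
p <- sim_params()
calibrate_bending_constant(50 * p$r, 2 * p$r)
```

The quadrature ignores excluded volume (single-angle factorization). That is
an excellent approximation for the stiff chain — at $\theta \approx 180^\circ$
next-nearest beads sit near $2b \approx 2.24\sigma$, where the repulsion is
$\sim 10^{-4}\,k_BT$ — but not for the flexible chain, whose $\approx 2r$
persistence length arises *from* excluded volume (an ideal freely jointed
chain would have none). The flexible value is therefore checked only by
simulation.

## Measuring persistence length

`persistence_length()` fits $\langle \hat t_i\cdot\hat t_{i+s}\rangle =
e^{-s b/l_p}$ by through-origin log-linear least squares, weighted by the
inverse variance of $\log C(s)$ estimated from the snapshot ensemble with
block-based standard errors. The weighting matters: correlations at large
separations decorrelate only through the chain's slowest bending mode, and
with equal weights they dominate the slope and inflate the seed-to-seed
scatter of the stiff-chain estimate several-fold. Two further numerical
choices matter:

* **Fit range.** The fit starts at $s = 1$ and extends over separations with
  mean correlation above 0.05, but only while the observed decay remains
  consistent with the exponential extrapolated from $s = 1$ (cumulative rate
  within 15%). Worm-like decorrelation is exponential, so stiff chains and
  ideal worm-like-chain ensembles keep the full range; a flexible
  self-avoiding chain develops a slower, power-law-like tail
  (measured $C(s) = 0.34, 0.21, 0.14, \dots$ against $0.34, 0.12, 0.04$ for
  a pure exponential) that would otherwise bias $l_p$ upward by a factor
  of two, so there the fit correctly collapses to the short-range regime.
  The 15% tolerance is uncritical: the deviation at $s = 2$ is below 1% for
  calibrated worm-like ensembles and about 80% for the flexible chain.
* **Uncertainty.** Successive snapshots of a stiff chain are correlated
  through its slowest bending mode (relaxation $\sim 10^6$ steps for a
  50-bead chain at $l_p = 50r$), so the confidence interval uses a
  moving-block bootstrap over snapshots (default block length
  $n/30$); a plain bootstrap would understate the interval severely.

A perfectly straight ensemble is reported as above the configurable cap
(effectively infinite); an ideal freely jointed chain, whose correlation
vanishes beyond $s = 0$, raises an estimation error rather than returning a
number.

## The synthetic generator and the presets

All inputs are generated in code; nothing is downloaded. `preset()` bundles
three scales:

* **full** is the complete study layout — 200 chains × 50 beads in
  a $(399.6\sigma)^3$ box, compression over $10^7$ steps to $48\sigma$ and
  $10^6$ steps to $30\sigma$, $6\times10^8$ assembly steps, $2\times10^8$
  steps per stage, $P_{CL}\in\{0,5,15,25\}\%$, four conformations, three
  replicas. It is *not* desk-reproducible (months of CPU); it exists so the
  full-scale configuration is explicit and auditable.
* **demo** keeps the number density of every stage (box scaled by
  $(500/10^4)^{1/3}$) with 20 chains × 25 beads, $10^4{+}10^3$ compression
  steps, $2\times10^5$ assembly steps, $10^5$ steps per stage, three
  replicas — minutes on one CPU. This is the scale at which the package's
  tests probe the shrink/swell phase behavior.
* **ci** is a seconds-scale smoke test (8 chains × 12 beads) for the
  end-to-end pipeline and the command-line interface.

Single-chain persistence-length measurements use one 50-bead chain in a box
of 2.5 contour lengths, pooling three independent runs with fresh seeds
($3\times10^7$ total steps stiff, $6\times10^6$ flexible in the
reproduction script; a third of that in the test suite), snapshots every
1000/200 steps with the first fifth of each run discarded as equilibration —
sizes chosen so the slowest bending mode is sampled dozens of times while
the whole measurement stays within minutes.

What the demo scale does and does not show: it preserves the stage densities,
the crosslinking rule, and the stiff/flexible persistence-length contrast of
the full layout, and it shows shrinkage at $P_{CL} = 25\%$ with $S_V$
non-increasing in $P_{CL}$ across the pressure grid. It does **not**
reproduce the swelling of the uncrosslinked control: that behavior compares
the flexible equation of state against an *equilibrated* stiff melt, and the
stiff phase of rod-like 25-bead chains cannot orientationally equilibrate
within $3\times10^2\,\tau$ of assembly (the full layout allows
$10^6\,\tau$). Measured across $P_0 = 0.2$–$3\,k_BT/\sigma^3$, chain
stiffnesses from $12.5r$ to $50r$, and assemblies up to $10^6$ steps, the
demo-scale control stays at $S_V \approx 0.95$–$0.99$. The corresponding
acceptance check is left failing rather than weakened. Absolute $S_V$ values
at this scale likewise need not match the $10^4$-bead layout's; no test
asserts that they do.

## Known limitations

* Purely repulsive sterics: no attractive interactions, electrostatics or
  solvent; assembly is driven entirely by the barostat.
* Crosslinks are permanent harmonic springs; no bond breaking or exchange.
* The stiff→flexible switch is instantaneous — no temperature axis, and no
  mapping of $S_V$ onto the experimental temperature response.
* One helix is one chain throughout: the topology change when a triple helix
  denatures into three strands is deliberately ignored.
* The Berendsen barostat relaxes pressure but does not sample the true NPT
  ensemble; for the volume *averages* used here that distinction is
  immaterial at the reported tolerances.
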