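---
title: "Methods: thermodynamic decomposition of protein condensate formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic decomposition of protein condensate formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensotherm)
```

## The problem and the model

Liquid–liquid phase separation (LLPS) of an intrinsically disordered
protein concentrates the protein from a dilute solution (\(\rho_{dil}\sim 1\)
mg/mL, essentially bulk water) into a dense condensate
(\(\rho_{cond}\sim 350\) mg/mL). Because free energy is a state function,
the thermodynamics of this process can be reconstructed from a *series of
homogeneous solutions* at intermediate concentrations \(\rho\): each
ledger row answers "what would the free-energy change be if a homogeneous
solution at \(\rho\) demixed into the condensate plus bulk water".

The total change is split as

\[
\Delta G = \Delta G_P + \Delta G_{solv},\qquad
\Delta G_P = \Delta E_{PP} - T\Delta S_P ,
\]

with the solvation part built from the *released* waters (expelled into
the bulk-like dilute phase) and the *retained* waters (kept inside the
condensate):

\[
\Delta N_W^{rele}(\rho) = N_W(\rho) - N_W(\rho_{cond}), \qquad
\Delta N_W^{reta} = N_W(\rho_{cond}),
\]
\[
\Delta S^{rele}(\rho) = \bigl(S(\rho_{dil})-S(\rho)\bigr)\,\Delta N_W^{rele}(\rho),
\qquad
\Delta S^{reta}(\rho) = \bigl(S(\rho_{cond})-S(\rho)\bigr)\,\Delta N_W^{reta}.
\]

Here \(S(\rho)\) is the molar entropy of water *per molecule* in the
system at concentration \(\rho\), and \(N_W(\rho)\) is the water count
per protein chain. The released waters gain entropy (water entropy falls
with crowding), the retained ones lose it: the solvation entropy is a
tug-of-war between the two populations.

Water–water enthalpy and entropy changes cancel identically
(\(\Delta E_{WW} - T\Delta S_{WW} = 0\), the Ben-Naim compensation), so the
package enforces \(T\Delta S_{WW} := \Delta E_{WW}\) and

\[
T\Delta S_{PW} = T\Delta S_{solv} - \Delta E_{WW},\qquad
\Delta G_{solv} = \Delta E_{PW} - T\Delta S_{PW}
= \Delta H_{solv} - T\Delta S_{solv},
\]

which holds as an exact arithmetic identity in every assembled ledger
(`assemble_ledger()` is tested for it to 1e-9 on randomized inputs).

Two analytic side terms are computed and reported but excluded from
\(\Delta G\) by default, mirroring their deliberate neglect at reference
conditions: the mixing penalty \(RT\ln(\rho_{cond}/\rho_{dil})\)
(≈ 14.6 kJ/mol at 300 K) and the droplet interface penalty
\(3\gamma M/(c\,r\,N_A)\) (≈ 4 kJ/mol at its most pessimistic,
r = 20 nm and γ = 0.5 mN/m). Both are an order of magnitude below the
leading terms.

### Conventions that matter

* Units package-wide: nm, ps, amu, kJ/mol, K; entropies in
  J mol⁻¹ K⁻¹. In these units 1 amu nm² ps⁻² = 1 kJ/mol exactly.
* All extensive Δ quantities are **per protein chain**; a negative
  \(\Delta G\) favors condensation.
* Input normalization: `S_*`, `E_PW`, `E_WW` per water molecule; `E_PP`
  per protein. The budget converts per-water quantities to per-protein
  totals via the released/retained counts.
* The dilute-phase reference is the bulk-water rows of the series
  (configurable by editing which rows carry `is_bulk`).
* A scalar conformational entropy change \(\Delta S_P\) is interpreted as
  the dilute-limit value and faded linearly to zero at \(\rho_{cond}\);
  the reference state must be exactly null in every column, including
  this one. Pass a per-row vector for any other interpolation.

## Water entropy: the 2PT engine

The molar entropy of (rigid) water is computed with the
two-phase-thermodynamics method. The translational and rotational
velocity autocorrelation functions

\[
C_{tr}(t)=m_W\langle \mathbf v(\tau)\mathbf v(\tau+t)\rangle_\tau,\qquad
C_{rot}(t)=\sum_{k=1}^{3} I_k \langle \omega_k(\tau)\omega_k(\tau+t)\rangle_\tau
\]

are transformed into the density of states
\(I(\nu) = \tfrac{2}{k_BT}\int e^{i2\pi\nu t}C(t)\,dt\)
(one-sided: \(\int_0^\infty I\,d\nu = 3N\)), which is split into a
solid-like and a diffusive gas-like part,
\(I = I^s + I^g\). The gas part is the hard-sphere/rigid-rotor Lorentzian
\(I^g(\nu)=s_0/[1+(\pi s_0\nu/6fN)^2]\) carrying \(3Nf\) degrees of
freedom, where the fluidicity \(f\) solves the universal equation
\(2y^3-6y^2+(6-f)y+2f-2=0\), \(y=f^{5/2}\Delta^{-3/2}\), with the
normalized diffusivity \(\Delta\) built from \(s_0=I(0)\), \(T\), the
molecular mass and the number density. Entropy weights: quantum harmonic
oscillator for the solid part, Carnahan–Starling hard-sphere entropy at
packing fraction \(y\) (translation) or the rigid-rotor entropy with
symmetry number σ = 2 and the rotational temperatures of the water
geometry (rotation) for the gas part. These closed forms are frozen in
the `R/dos2pt.R` header and each is pinned by an oracle test
(brute-force VACF, naive DFT, 10⁶-point root scan, Sackur–Tetrode and
quantum-HO closed forms).

### Numerical choices

* **Spectral estimator.** `compute_dos()` tapers the correlogram with a
  Bartlett window by default. The unbiased \(1/(n-\text{lag})\) VACF
  estimator with a rectangular window scatters negative sidelobe weight
  across the spectrum; any nonnegativity enforcement downstream then
  *rectifies* that noise into a large positive entropy bias (we measured
  +100% on a pure-cosine fixture). The Bartlett taper is precisely the
  classical biased-autocorrelation (Fejér) spectral estimate, whose
  kernel is nonnegative; the HO recovery error on harmonic fixtures drops
  to ~0.2%. The window never touches the lag-0 value, so the
  \(\int I = 3N\) bookkeeping is window-independent. `window = "none"`
  remains available and both choices are recorded in results.
* **Signed solid remainder.** \(I^s = I - I^g\) is kept signed (clipping
  it at zero biases the HO integral by the full rectified weight); the
  integrated negative excursion is logged as a QC metric. Final entropy
  components are floored at zero — they are entropies — which also guards
  the degenerate \(f\to 0\) branch where \(y \to 1\) makes the
  Carnahan–Starling excess blow up.
* **Gas quota in closed form.** \(\int I^g\) is evaluated analytically
  (\(s_0 w \arctan(\nu_{max}/w)\)); for free-flight fixtures the
  Lorentzian is about one frequency bin wide and trapezoid quadrature is
  a few percent off, which would leak directly into the entropy.
* **VACF length** defaults to half the trajectory (10 ps for the 20 ps
  reference protocol), frequency grid two-fold zero-padded.
* **Degenerate input guards:** trajectories whose consecutive frames
  repeat (a halved stride) are refused; a series in which *every* frame
  repeats is legitimate free flight and is allowed.

## The bulk-water fixture engine

`simulate_water_box()` generates the velocity data for the bulk-water
validation point: `n` rigid four-site dispersion-corrected waters
(TIP4P-D-like geometry: OH 0.09572 nm, HOH 104.52°, M-site 0.01546 nm,
qH = +0.58 e; oxygen LJ σ = 0.3165 nm, ε = 0.937 kJ/mol) in a cubic box
at 0.997 g/cm³, NVT at 300 K. Integration is velocity Verlet for the
centers of mass plus the exact NO_SQUISH free-rotor splitting for the
rigid rotation, a CSVR thermostat, reaction-field electrostatics
(\(\varepsilon_{rf}=\infty\)) with a molecule-based 0.9 nm cutoff, and a
quintic switching function over the outer 0.1 nm — without the switch the
cutoff discontinuities pump ~1.7 kJ/mol/ps per water into the system;
with it the NVE drift is below 4·10⁻⁴ kJ/mol/ps per water. Protocol:
2 ps at 0.5 fs with clamped forces from a lattice start, 18 ps
equilibration and 20 ps production at 2 fs, velocities written every
4 fs.

At 500 waters and seed 1 the full pipeline gives
\(S_{tot} \approx 56.6\) J mol⁻¹ K⁻¹ (\(S_{tr} \approx 47.6\),
\(S_{rot} \approx 9.0\)); the bulk reference value for this water model
is 54.7 = 43.8 + 10.9. The ~3% offset is consistent with the scaled-down
box, the reaction-field (vs. Ewald) electrostatics, NVT at fixed
experimental density (vs. NpT), and single-window sampling. This is what
a green acceptance run establishes — agreement of the *method* at the
scaled-down operating point — not a force-field-faithful replication of
the reference simulations.

## Hydration structure

* `tetrahedral_q()`: each water oxygen's four nearest water oxygens
  (minimum image, no cutoff — the standard Errington–Debenedetti
  convention) give \(q = 1-\tfrac38\sum_{j<k}(\cos\psi_{jk}+\tfrac13)^2\);
  q = 1 for a perfect tetrahedron, mean 0 for random directions, 0.5 for
  square-planar coordination.
* `count_hbonds()`: geometric criterion, donor–acceptor O···O ≤ 0.35 nm
  and H–D–A angle ≤ 30°. There is no single canonical criterion in the
  field; this default is the common GROMACS-style choice, it is
  configurable, and every report logs it. Per-water means use the
  symmetric convention 2·bonds/N.
* `count_phl_waters()`: a water is in the protein hydration layer if any
  of its atoms is within 0.3 nm of any protein atom (hydrogens included
  on both sides — "surface" is otherwise undefined; the inclusive choice
  is stated and the cutoff configurable). Normalization divides by a
  dilute single-chain reference count.
* `fit_crossover()`: continuous two-segment least squares
  \(y = b_0+b_1x+b_2(x-x^*)_+\); the knot is scanned over every interior
  data interval and refined continuously, so a noiseless planted
  breakpoint (e.g. 150 mg/mL, which lies between grid points) is
  recovered exactly. A fit is flagged unreliable when a single line
  explains the data essentially as well — the breakpoint of a straight
  line is meaningless.

## Conformational entropy

Backbone torsions are extracted per chain and pooled over identical
chains; marginal entropies use the Kozachenko–Leonenko kNN estimator with
wrap-around distance (k = 1 default), pairwise mutual information uses
the plug-in 2-torus estimate, and the total is the first-order
maximum-information-spanning-tree sum
\(S=\sum_iH_i-\sum_{tree}I_{ij}\), with MI edges restricted to torsion
pairs whose central bonds lie within the 0.8 nm extraction cutoff.
Numerical guards: exact duplicates are jittered deterministically by
~1e-10 rad (warned); MI is clipped to \([0,\min(H_i,H_j)]\) when the
marginals are informative, which makes the noiseless-coupling limit
collapse onto a single marginal instead of diverging. The resulting
\(\Delta S_P\) is labelled a rough estimate in reports — torsion-based
estimators inherit all sampling limitations of their input trajectories —
and enters the ledger as the (small) \(-T\Delta S_P\) term.

## What the synthetic generators emulate

Every pipeline stage has a generator whose output carries analytic
ground truth:

* harmonic ensembles (exact quantum-HO entropy; canonical-mean
  amplitudes by default so the attached truth is exact rather than
  realized — Boltzmann-drawn amplitudes are available and add
  \(O(1/\sqrt{dof})\) scatter),
* ideal gases (Sackur–Tetrode; free flight needs a long observation
  window, ~500 ps, for the fluidicity to reach 1),
* a Langevin soft-sphere fluid (disordered q distribution, kinetic
  thermometer),
* toy condensates (bead-string chains, point waters; box edge solved
  from \(\rho = nM/N_AV\) — geometry only, no physics),
* planted concentration tables (below),
* circular torsion samples (uniform / von Mises, optional couplings with
  closed-form joint entropies).

The planted concentration tables deserve a note. Their defaults are
anchored at the Table-1 bulk entropies with a crossover at 150 mg/mL and
the rotational slope 2.4× smaller above it. The remaining slopes were set
once, from the following constraint: with a piecewise-linear
\(S(\rho)\) whose second segment is steeper by a factor \(k\), the
released waters win the entropy tug-of-war at low \(\rho\) only if
\(k \lesssim 1.55\) (plug the budget counts into \(\Delta S^{rele} +
\Delta S^{reta}\) and solve); the defaults use \(k \approx 1.43\), so
\(-T\Delta S_{solv}\) is slightly favorable, \(\Delta G_{solv}<0\), and
\(|\Delta G_{solv}|\sim|\Delta E_{PP}|\) — the qualitative driving-force
pattern the analysis is designed to resolve. What the generators do
**not** emulate: real force-field magnitudes of \(S(\rho)\) and
\(E(\rho)\), protein flexibility, ions, or interfacial physics. A green
end-to-end test therefore establishes the correctness of the
*bookkeeping and estimators*, not of any molecular model.

## Known limitations

* The water engine is a validation fixture, not a production MD code:
  O(N²) pair loop, reaction-field electrostatics, NVT only.
* 2PT inherits its usual assumptions (harmonic solid, Enskog/rigid-rotor
  gas, rigid molecules); flexible waters are rejected rather than
  mishandled.
* Binary trajectory formats are supported only through the reader
  registry seam; the package itself parses text formats (GRO, PDB,
  xvg-like tables).
* The conformational-entropy module is a rough estimator by design and
  is labelled as such everywhere it reports.
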