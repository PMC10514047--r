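# condensotherm

Thermodynamic decomposition of protein condensate formation from
molecular-dynamics-style inputs.

## What problem this solves, and for whom

When an intrinsically disordered protein undergoes liquid–liquid phase
separation (LLPS), a dilute solution (ρ_dil ≈ 1 mg/mL, essentially bulk
water) demixes into a dense condensate (ρ_cond ≈ 350 mg/mL). Because free
energy is a state function, the driving forces of this process can be
reconstructed from simulations of *homogeneous* solutions at a series of
concentrations — no phase-separation trajectory needed. `condensotherm`
is for computational biophysicists who have (or want to emulate) such a
concentration series and need the complete free-energy ledger:

```
ΔG(ρ) = ΔG_solv(ρ) + ΔE_PP(ρ) − TΔS_P(ρ)
```

with the solvation part resolved into the *released* waters (expelled to
the bulk-like dilute phase, entropy gain) and the *retained* waters (kept
in the crowded condensate, entropy loss):

```
ΔN_rele(ρ) = N_W(ρ) − N_W(ρ_cond)          ΔN_reta = N_W(ρ_cond)
ΔS_rele(ρ) = (S(ρ_dil) − S(ρ)) · ΔN_rele   ΔS_reta(ρ) = (S(ρ_cond) − S(ρ)) · ΔN_reta
```

Water–water enthalpy and entropy cancel identically
(ΔE_WW − TΔS_WW = 0, Ben-Naim compensation), so
ΔG_solv = ΔE_PW − TΔS_PW with TΔS_PW = TΔS_solv − ΔE_WW — an identity the
package enforces and tests exactly.

The package provides, as first-class tested modules:

* **2PT water entropy**: velocity autocorrelation → vibrational density
  of states I(ν) = (2/k_BT)·FT[C(t)] → universal fluidicity f → solid
  (quantum harmonic oscillator) / gas (Enskog hard sphere, rigid rotor)
  partition → molar S_tr, S_rot, S_tot;
* **hydration structure**: tetrahedral order parameter
  q = 1 − (3/8)Σ(cos ψ_jk + 1/3)², hydrogen-bond counts, 0.3 nm
  hydration-layer populations, radius of gyration, and continuous
  two-segment crossover fits of S(ρ);
* **the thermodynamic ledger** above, plus the analytic mixing
  (RT ln(ρ_cond/ρ_dil)) and droplet-interface (3γM/(c·r·N_A)) estimators;
* **conformational entropy** from torsion angles via circular
  Kozachenko–Leonenko kNN estimation and a maximum-information spanning
  tree (MIST);
* **synthetic generators with analytic ground truth** for every stage,
  including a lightweight rigid four-site water simulator (Rcpp) that
  produces bulk-water velocity trajectories for validating the 2PT
  engine end to end;
* a manifest-driven pipeline (`run_pipeline()`) and a CLI
  (`inst/cli/condensotherm`).

## Worked example

Generate a synthetic concentration series with planted trends (bulk
anchors S_tr = 43.8, S_rot = 10.9 J mol⁻¹ K⁻¹; slope crossover at
150 mg/mL), then assemble the ledger against the 350 mg/mL condensate
reference with a conformational entropy change of −291 J mol⁻¹ K⁻¹:

```r
library(condensotherm)
ser <- gen_concentration_tables(noise_sd = 0.02, seed = 1)
ser <- concentration_series(ser[ser$rho <= 350 | ser$is_bulk, ])
led <- assemble_ledger(ser, rho_cond = 350, dS_P = -291, T = 300)
print(led)
#> <ct_ledger> rho_cond = 350 mg/mL, T = 300 K
#>  rho TdS_solv TdS_PW dE_PW dH_solv dG_solv  dE_PP  TdS_P dG_total
#>   25    71.71 1526.6 852.1  -602.8  -674.5 -390.3 -87.30   -977.5
#>   60  -104.12 1079.6 830.4  -353.3  -249.1 -348.3 -77.90   -519.5
#>  100   -50.14 1007.8 709.2  -348.8  -298.6 -300.3 -67.15   -531.7
#>  145  -127.35  736.7 566.6  -297.4  -170.0 -246.2 -55.07   -361.2
#>  205    37.79  651.7 407.2  -206.7  -244.5 -174.1 -38.95   -379.6
#>  260    69.61  452.0 243.5  -138.8  -208.4 -108.1 -24.18   -292.3
#>  350     0.00    0.0   0.0     0.0     0.0    0.0   0.00      0.0
```

Reading the table (all kJ/mol per protein, negative favors
condensation): starting from a dilute 25 mg/mL solution, the noncanceling
protein–water entropy term TΔS_PW ≈ +1527 (favorable through −TΔS) and
the protein–protein interaction energy ΔE_PP ≈ −390 are the two large
driving forces; the conformational entropy penalty −TΔS_P ≈ +87 is an
order of magnitude smaller; the total ΔG ≈ −978 favors condensation, and
every Δ vanishes at the ρ_cond reference row. The analytic side terms
(excluded from ΔG by default):

```r
mixing_free_energy(350, 1, 300)        # 14.61 kJ/mol
interface_penalty(20, 0.5, 350, 17.2)  # 3.69 kJ/mol
```

And the 2PT engine on a freshly simulated 500-water box (the bulk
reference for this water model is S_tot = 54.7 = 43.8 + 10.9
J mol⁻¹ K⁻¹):

```r
sim <- simulate_water_box(n_waters = 500, T = 300, seed = 1)  # ~2 min
entropy_pipeline(sim$series)
#> <ct_entropy> per-molecule molar entropies (J mol^-1 K^-1)
#>   S_tot   56.613 = S_tr   47.628 (HO 30.139 + HS 17.490, f = 0.212)
#>               + S_rot   8.985 (HO 7.062 + RR 1.923, f = 0.046)
```

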