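# membranekit

Analysis toolkit for studies of how lipid bilayer thickness and composition
modulate the function of membrane-embedded enzymes — the workflow used when
an intramembrane protease (such as the *E. coli* rhomboid GlpG) is
reconstituted into phosphatidylcholine/cholesterol vesicles, the membrane is
characterised by solid-state NMR and molecular-dynamics trajectories, and
enzyme activity is followed by FRET cleavage kinetics. It is written for
membrane biophysicists who need the numerical chain between raw
measurements and physical membrane parameters to be reusable, seeded, and
tested.

The package covers four linked analyses:

1. **²H NMR → chain order.** Fluid-phase perdeuterated lipids give powder
   spectra that are superpositions of Pake doublets, one per labelled
   carbon, with 90°-edge splitting
   Δν₉₀ = (3/4) χ_Q c |S_CD| (χ_Q = 167 kHz, c = 1/3 for the rotating
   methyl). `simulate_quadrupolar_powder()` is the exact forward model;
   `depake()` inverts a powder spectrum to its 0°-oriented sub-spectrum by
   regularised non-negative least squares; and
   `extract_smoothed_order_profile()` converts the oriented spectrum into a
   smoothed per-carbon order profile by equal-area-per-deuteron
   integration.
2. **Order → thickness.** The first-order mean-torque model maps each
   segment's S_CD onto its projection on the bilayer normal,
   ⟨cos β⟩ = ½(1 + √((−8S_CD − 1)/3)), and the projected acyl chain length
   is l_c = Σ 1.27 Å · ⟨cos β_i⟩ (`cos_beta_first_order()`,
   `projected_chain_length()`). `fit_thickness_model()` regresses l_c on
   cholesterol content so assay samples can be placed on a thickness axis.
3. **³¹P lineshapes.** `fit_multicomponent()` decomposes a phosphorus
   spectrum into one or two axially symmetric CSA powder patterns
   (ν(θ) = σ_iso + (Δσ/3)(3cos²θ − 1)) plus an isotropic line, with
   fractions constrained to the simplex — the decomposition that exposes a
   second, motionally averaged headgroup population around a membrane
   protein.
4. **Kinetics and trajectories.** `fit_single_exponential()` fits
   I(t) = I_max − I₀ e^(−t/τ) to cleavage progress curves, with τ/τ₀
   normalisation (`normalize_tau()`) and linear/exponential thickness
   trends (`trend_fits()`). Trajectory observables implement
   S_CD = ½⟨3cos²θ_z − 1⟩ (`acyl_order_parameters()`), annular-lipid
   classification and composition (`classify_annular()`,
   `annulus_composition()`), P–N headgroup and helix-tilt angles, pair
   distribution functions, and the Helfrich–Canham bending modulus from
   the height-fluctuation spectrum S_u(q) = k_BT/(k_c q⁴ + γ q²)
   (`undulation_spectrum()`, `fit_bending_modulus()`).

Seeded generators (`gen_order_profile()`, `gen_2h_spectrum()`,
`gen_progress_curve()`, `gen_helfrich_surfaces()`, `gen_bilayer_frames()`,
`gen_ideal_helix()`) emulate every input class with known ground truth, so
the full pipeline runs and validates without any external data. The
methods vignette (`vignettes/membranekit-methods.Rmd`) documents the
models, parameter choices and limitations.

## Worked example

Simulate a DLPC-like ²H spectrum at signal-to-noise 50, dePake it, extract
the order profile, and project it to a chain length:

```r
library(membranekit)
prof <- gen_order_profile(n_carbons = 12, plateau_s = 0.21, methyl_s = 0.05, seed = 1)
spec <- gen_2h_spectrum(prof, chi_q = 167, broadening = 0.5, snr = 50, seed = 2)
rec  <- extract_smoothed_order_profile(depake(spec), n_carbons = 12)
rec
#> <order_profile> chain mean, carbons C2..C12
#>  carbon_index        s_cd is_methyl
#>             2 -0.21552436     FALSE
#>             3 -0.21145210     FALSE
#>             ...
#>            11 -0.09256751     FALSE
#>            12 -0.05251225      TRUE
projected_chain_length(rec)
#> <chain_length_result> l_c = 9.770 A over 11 segments (first-order mean torque)
```

The recovered profile matches the generating one within ±0.01 per carbon,
and the chain length lands at the ~9.8 Å leaflet thickness typical of
cholesterol-free DLPC. A thickness calibration and its use:

```r
m <- fit_thickness_model(c(0, 10, 20, 30), c(9.70, 10.33, 10.96, 11.60))
m
#> <thickness_model> l_c = 9.6980 + 0.0633 * chol (A vs mol %), r^2 = 1.0000, n = 4
predict(m, 15)
#> [1] 10.6475
```

Bending rigidity from thermally sampled membrane surfaces:

```r
surf <- gen_helfrich_surfaces(box_l = 25, grid_n = 64, kc = 20, n_frames = 500, seed = 3)
fit_bending_modulus(undulation_spectrum(surf), temperature = 310)
#> <bending_fit> kc = 20.1 kBT (8.62e-20 J at 310 K), gamma = 0 kBT/nm^2 [tension_free]
#>   q in [0.251, 0.562] nm^-1 over 4 bins, r^2 = 0.9991
```

The generator drew surfaces at k_c = 20 k_BT; the spectrum fit recovers it
within 1%, confirming the estimator's normalisation against its sampler.
An entire three-arm study (NMR → thickness, kinetics → τ/τ₀ vs thickness,
trajectory observables) runs from one YAML configuration with
`run_study("study.yaml")`; a thin command-line wrapper lives at
`inst/cli/membranekit`.

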