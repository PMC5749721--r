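# flimpair

Tools for choosing donor–acceptor fluorescent protein pairs for
**FLIM-FRET** experiments — FRET read out through the donor's fluorescence
*lifetime* rather than its intensity.

Picking a pair involves two very different kinds of evidence. Photophysics
predicts what a pair *could* do: the spectral overlap integral
*J* = ∫ f_D(λ) ε_A(λ) λ⁴ dλ sets the Förster radius
r₀ = 0.02108 (K φ_D n⁻⁴ J)^(1/6), and efficiency falls with separation as
E = r₀⁶ / (r₀⁶ + r⁶). Per-cell measurements show what a pair actually
*does* on a given instrument, and the screening statistic

    Z′ = 1 − 3(σ_max + σ_min) / |μ_max − μ_min|

— donor-alone lifetimes as the maximum signal, pair lifetimes as the
minimum — scores whether the lifetime shift is large and reproducible
enough to build an assay on (Z′ > 0.5 is conventionally "good"). The
package implements both sides and the measurement models in between:

* spectral predictions: `overlap_integral()`, `forster_radius()`,
  `efficiency_at_distance()`, `predict_pair()`;
* frequency-domain FLIM (40 MHz homodyne): `fd_response()`,
  `calibrate_reference()`, `lifetime_from_phase()`,
  `phasor_coordinates()`;
* time-domain FLIM (TCSPC, 80 ps bins): `simulate_decay()`,
  `fit_monoexp()`, `fit_biexp()`, `select_decay_model()`;
* assay scoring: `efficiency_from_lifetimes()`, `z_factor()`,
  `evaluate_assay()` (static and time-course modes), `concordance()`,
  `sensitivity_ps_per_percent()`, `stimulation_response()`;
* time-course stability: `normalize_traces()`, `drift_slope()`,
  `endpoint_change_summary()`, `variability_correlation()`,
  `predicted_vs_measured_fit()`;
* a deterministic synthetic-study generator that routes observations
  through the real measurement code paths: `synthetic_study_config()`,
  `generate_study()`, `generate_timecourse()`.

A benchmark of ten pairs (Clover, EGFP, mTFP1 and mTurquoise2 donors with
mCherry, mRuby2, YPet, Venus and the dark acceptor sREACh) ships with the
package: `flim_pair_table()`, `flim_measured_assays()`,
`read_fluorophore_table()`.

## Worked example

Predict the Clover–mCherry pair from its photophysics, then run a
synthetic 3-day study through the frequency-domain measurement path and
score it:

```r
library(flimpair)

pairs <- flim_pair_table()
clv <- pairs[pairs$pair == "Clv-mCh", ]
forster_radius(clv$qy_donor, clv$J)
#> 5.18 nm
round(100 * efficiency_at_distance(clv$r0_ref, c(5, 6, 7)))
#> 55 / 29 / 14   (% efficiency at 5, 6, 7 nm separation)

cfg <- synthetic_study_config(pair_name = "Clv-mCh", platform = "FD",
                              measurement = "full", rng_seed = 42)
study <- generate_study(cfg)
evaluate_assay(study[study$construct == "donor_alone", ],
               study[study$construct == "Clv-mCh", ], mode = "static")
#> Assay evaluation (static, 3 day repeats)
#>   FRET efficiency: 24.2% +/- 0.3%
#>   Z'-factor:       0.526 +/- 0.069

sensitivity_ps_per_percent(4.0)
#> 40   (ps lifetime change per %E for a 4.0 ns donor)
```

Reading it: a 5.18 nm Förster radius puts the expected efficiency at 29%
if the fluorophores sit ~6 nm apart (about as close as two β-barrels get);
the synthetic study — generated with a true efficiency of 24.1% and
measured through simulated homodyne detection, instrument offsets and
fluorescein calibration — recovers 24.2 ± 0.3% and a Z′ around 0.53,
i.e. a usable assay. The last line is why long-lifetime donors matter: at
4.0 ns, every percentage point of efficiency moves the readout by 40 ps,
twice the leverage of a conventional 2 ns green donor.

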