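# sipraman

Single-cell Raman spectroscopy combined with ¹³C stable-isotope probing
(SIP-Raman) identifies metabolically active cells in environmental
communities without cultivation: cells that assimilate a ¹³C-labeled
substrate build the heavier isotope into their biomass, and the Raman
bands of carbon-containing bonds shift to lower wavenumbers. **sipraman**
implements the computational side of this workflow for chemoautotrophs,
whose resonance-enhanced cytochrome c bands (pyrrole breathing ~747 cm⁻¹,
ν(C–N) ~1125 cm⁻¹, δ(C–H) ~1312 cm⁻¹, ν(C–C) ~1584 cm⁻¹) and
phenylalanine ring-breathing band (~1002 cm⁻¹) redshift on ¹³C
incorporation. It is intended for microbial ecologists and spectroscopists
running Raman-activated sorting or activity-screening experiments.

The package provides:

- **I/O** for single-cell spectra in long-format CSV/TSV with a JSON
  manifest, plus three packaged band tables of empirical ¹²C/¹³C
  endmember positions (`reference_strains`, `sediment_enrichment`,
  `strain_TX1`) and user-defined tables in JSON/TSV.
- **Preprocessing**: grid resampling, 500–1800 cm⁻¹ fingerprint cropping,
  asymmetric-least-squares baseline subtraction, Savitzky–Golay
  smoothing, ℓ2/area/max normalization, and cohort averaging with SD
  envelopes.
- **Band-shift analysis**: pseudo-Voigt fitting of each biomarker band in
  its search window; per-band redshift Δ = c₁₂ − ĉ; labeling fraction by
  band position, f = (c₁₂ − ĉ)/(c₁₂ − c₁₃), or by non-negative
  least-squares decomposition onto endmember spectra, f = a₁₃/(a₁₂ + a₁₃);
  and the sorting criterion — a cell is an active carbon fixer when all
  four cytochrome c bands **and** the phenylalanine band shift by at least
  `delta_min` (default 5 cm⁻¹: above the ~3 cm⁻¹ instrument resolution,
  below the smallest genuine biomarker shift).
- **A synthetic-spectrum simulator** (`simulate_cohort()`) with the band
  structure, isotope shifts, instrument broadening, autofluorescence
  baseline and noise of the emulated experiments — the validation
  substrate for everything above.
- **Command-line entry points** (`sipraman simulate | classify | report`,
  installed under `inst/scripts/`) wrapping the same functions.

## Worked example

Simulate a sorted group of 10 fully labeled cells at SNR 30 and classify
it with the default rule:

```r
library(sipraman)
cfg <- sim_config(n_cells = 10, active_fraction = 1, label_fraction = 1,
                  snr = 30, seed = 42)
cohort <- simulate_cohort(cfg)
fit <- sip_raman(cohort$set)
summary(fit)
#> <cohort_report> 10 cells: 10 active, 0 inactive
#>   rule: all_cytc_and_phe, delta_min = 5 cm-1, band table 'reference_strains'
#>               band n_success mean_center sd_center mean_delta sd_delta mean_f  sd_f
#>  pyrrole_breathing        10     724.903     0.588     22.097    0.588  0.992 0.013
#>              nu_CN        10    1114.792     0.557     10.208    0.557  0.986 0.027
#>           delta_CH        10    1300.167     0.582     11.833    0.582  0.974 0.037
#>              nu_CC        10    1536.085     0.626     47.915    0.626  0.994 0.007
#>           phe_ring        10     965.013     0.678     36.987    0.678  0.993 0.011
```

Every cell shows all five bands at the fully labeled ¹³C positions
(725/1115/1300/1536/965 cm⁻¹), redshifts of ~22/10/12/48/37 cm⁻¹ — far
above the 5 cm⁻¹ threshold — and labeling fractions near 1, so all 10
cells are called active carbon fixers. `coef(fit, "delta")` gives the
per-cell shift matrix, `as.data.frame(fit)` a per-cell results table, and
`plot(fit)` the group mean spectra with SD envelopes and band markers.
An unlabeled control cohort (`active_fraction = 0`) classifies 0/10
active.

## Documentation

The methods vignette (`vignettes/sip-raman-band-shifts.Rmd`) describes
the model, the preprocessing chain, the numerical choices in the band
fitter, what the simulator does and does not emulate, and known
limitations.
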