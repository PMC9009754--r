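# thzshrink

Reflection-mode terahertz time-domain spectroscopy (THz-TDS) can identify
molecular crystals by their low-frequency vibrational resonances, but on
rough-surfaced samples the specular reflectivity is distorted by
rough-surface scattering: a Gaussian frequency roll-off, a collapsing usable
bandwidth, atmospheric water-vapour lines and noise artifacts that bury the
characteristic absorption fingerprints — especially off the specular
direction. `thzshrink` implements a wavelet-shrinkage retrieval technique
that recovers the resonant frequencies from the negative derivative of the
scattered power reflectivity, together with the Kirchhoff scattering model
used to characterise the surfaces and a seeded synthetic-spectrum generator
for validation. It is aimed at spectroscopists working on stand-off or
non-destructive chemical identification with broadband THz systems.

## The method

For a measured power reflectivity |ρ(f)|² the pipeline computes
V₀(f) = −d|ρ(f)|²/df and pushes it through the maximal overlap discrete
wavelet transform (MODWT) pyramid with the least-asymmetric LA(8) ("sym4")
filters h̃, g̃:

W̃ⱼ(f) = Σₖ h̃(k) Ṽⱼ₋₁(f − 2ʲ⁻¹k mod N),  Ṽⱼ(f) = Σₖ g̃(k) Ṽⱼ₋₁(f − 2ʲ⁻¹k mod N)

for j = 1…J (default J = 6). The level-j wavelet coefficients are circularly
advanced by 2ʲ⁻¹(L−1) − ν (ν = −3 for LA(8)) to align wavelet-domain
features with the spectrum. Levels whose second-order total variation
TV₂,ⱼ = Σ|W̃ⱼ(f+2δf) − 2W̃ⱼ(f+δf) + W̃ⱼ(f)| accounts for more than 25% (sharp
noise, scattering and water-vapour transitions) or less than 0.2% (baseline)
of the total are excluded. For each remaining level a threshold τⱼ is the
largest coefficient magnitude inside two noise-and-scattering intervals — a
200 GHz window at 0.3 THz and a 200 GHz window at 1.7 THz — and the
coefficients are hard-thresholded: kept verbatim when |W̃ⱼ(f)| ≥ τⱼ, zeroed
otherwise. After reversing the circular advances, the inverse pyramid

Ṽⱼ₋₁(f) = Σₖ h̃(k) W̃ⱼ(f + 2ʲ⁻¹k mod N) + Σₖ g̃(k) Ṽⱼ(f + 2ʲ⁻¹k mod N)

reconstructs a derivative spectrum in which the surviving local maxima mark
the resonant frequencies.

The scattering side implements the Kirchhoff (tangent-plane) approximation
|ρ(f)|² = |r|² exp(−4k²σ²cos²θᵢ): fitting ln|ρ|² against k² recovers the RMS
surface height σ, and the Fraunhofer criterion σ ≥ λ/(32 cos θᵢ) gives the
frequency above which scattering distorts the spectrum.

## Worked example

Simulate a 4-aminobenzoic-acid (PABA) pellet pressed against grit-220
sandpaper (RMS height 15 µm), measured at 35° in the specular direction, and
run the identification pipeline:

```r
library(thzshrink)

res <- thz_identify(thz_preset("paba", 220, seed = 7))
res
#> Wavelet-shrinkage identification
#>   kept levels : 3, 4, 5
#>   thresholds  : 3.17, 0.703, 0.311
#>   peaks (4)  : 0.599, 0.800, 1.292, 1.541 THz

tidy(res)
#> # A tibble: 4 × 5
#>   frequency amplitude prominence line_center deviation
#>       <dbl>     <dbl>      <dbl>       <dbl>     <dbl>
#> 1     0.599     3.43        3.42        0.6  -0.00125
#> 2     0.800     3.95        6.82        0.8  -0.000450
#> 3     1.29      1.64        2.80        1.29  0.00235
#> 4     1.54      0.678       1.13        1.54  0.00125
```

All four PABA resonances (0.6, 0.8, 1.29, 1.54 THz) emerge as local maxima
of the reconstructed derivative, within 0.5–2.4 GHz of the generated line
centres, even though the 1.29 and 1.54 THz modes are invisible in the
raw derivative. The wavelet decomposition kept levels 3–5: levels 1–2 carry
the sharp water-vapour and noise transitions (> 25% of total variation each)
and level 6 only baseline (< 0.2%). `autoplot(res)` overlays the raw and
reconstructed derivative with the called peaks.

Surface characterisation from the same spectrum:

```r
thz_roughness(thz_simulate(thz_preset("paba", 220, seed = 7)))
#> Kirchhoff roll-off fit
#>   sigma_um     : 15.88 (se 0.316)
#>   r2 baseline  : 0.2817
#>   ...
```

The fitted 15.9 µm RMS height recovers the generating 15 µm surface despite
the absorption lines and noise riding on the roll-off.

A thin command-line wrapper with `simulate`, `identify`, `roughness` and
`decompose` subcommands is installed under `cli/thzshrink.R` in the package
directory.

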