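Package: thzshrink
Title: Wavelet Shrinkage Retrieval of Terahertz Resonant Fingerprints from
    Rough-Surface Scattered Reflectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieves obscured resonant absorption fingerprints of molecular
    crystals (such as alpha-lactose monohydrate and 4-aminobenzoic acid) from
    rough-surface scattered terahertz reflectivity spectra measured in specular
    and off-specular geometries.  Implements the maximal overlap discrete
    wavelet transform (MODWT) pyramid algorithm with least-asymmetric (symlet)
    filters, zero-phase circular advancement of wavelet coefficients,
    decomposition-level selection by second-order total variation, and
    interval-based hard-threshold wavelet shrinkage of the negative derivative
    of power reflectivity.  Also provides the Kirchhoff-approximation specular
    scattering model (Rayleigh-factor roll-off), RMS surface roughness
    estimation by log-domain fitting, the Fraunhofer roughness criterion, and a
    seeded synthetic-spectrum generator emulating rough-surface scattered
    terahertz time-domain spectroscopy measurements for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
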