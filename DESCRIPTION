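Package: megstream
Title: Real-Time MEG Streaming, Source Imaging and Neurofeedback Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for real-time magnetoencephalography (MEG)
    signal streaming and source-level neurofeedback. Provides a FieldTrip-style
    real-time sample buffer with its TCP wire protocol and an append-only
    recording format; a synthetic 306-channel Elekta-like acquisition simulator
    (102 magnetometer + 204 planar-gradiometer channels plus trigger channels)
    driven by simulated parieto-occipital and prefrontal alpha-band sources;
    an overlapping-sphere analytic forward model (Sarvas solution); signal-space
    projection (SSP) denoising and a depth-weighted, cortically constrained
    minimum-norm (WMNE) imaging kernel; a 500-ms real-time loop that applies the
    kernel to FFT coefficients to track region-of-interest alpha power and emit
    an inverse-power visual-gauge feedback value; a discrete-event loopback
    harness characterizing chunked data-access delays; and an online-versus-
    offline comparison with simulated head-movement sensitivity sweeps.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
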