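Package: mrduet
Title: Simulation Toolkit for Interleaved Dual-Nuclear (23Na/1H) Radial MRI
    with Parallel Transmission
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation and processing toolkit for interleaved
    sodium/proton (23Na/1H) MRI with parallel-transmit (pTx) proton
    excitation. Provides density-adapted 3D radial k-space trajectories with
    golden-means projection ordering, interleave scheduling of the two
    nuclei, digital torso/cardiac phantoms with synthetic birdcage and
    array coil field maps, a spoiled steady-state forward signal simulator,
    gridding (Kaiser-Bessel) nonuniform Fourier reconstruction with Hamming
    filtering, flip-angle and B1 field mapping (double-angle method, actual
    flip angle imaging, receive-profile and transmit-efficiency maps), pTx
    pulse design (individual and universal phase shims, kT-points pulses,
    reference-voltage calibration), and quantitative evaluation metrics
    (Rayleigh-corrected SNR, coefficient of variation, relative difference
    maps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
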