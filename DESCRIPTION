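Package: hzesim
Title: Heavy-Ion Transport, Fragmentation, and Mixed-Field Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale transport physics for heavy charged particles (HZE
    ions) in shielding and therapy contexts: Bethe stopping power and
    range-energy integration, geometric (Bradt-Peters / Wilson-Townsend)
    charge-changing cross sections with a chi-squared grid fit of the nucleon
    radius and nuclear transparency, Goldhaber fragmentation kinematics, a
    one-dimensional Monte Carlo slab transport producing Bragg curves, and
    ICRP-60 quality-factor dosimetry of mixed fields behind shielding,
    including a parametric galactic-cosmic-ray source spectrum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
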