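Package: sonodrop
Title: Droplet and Dried-Particle Size Prediction for Ultrasonic Atomization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unit-aware calculations for ultrasonic atomization of polymer
    (drug-carrier) solutions used in microencapsulation. Implements the
    ultrasonic-modified Weber, Ohnesorge and Intensity dimensionless numbers,
    the critical and maximum flow-rate operating window of a vibrating-surface
    atomizer, power-law (shear-thinning) rheology with concentration fits for
    sodium alginate, four literature droplet-size correlations (Lang,
    Rajan-Pandit, Ramisetty, Avvaru, Barba) with validity-envelope checking,
    and droplet-to-dried-microparticle volumetric shrinkage. Ships a built-in
    worked case for a 1.5% w/w alginate / alpha-tocopherol shell-core system
    atomized at 25 kHz, plus a YAML configuration loader, JSON/text reporting
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, yaml, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
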