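Package: ectfield
Title: Mesoscale Electric Field and Thermal Modeling for Liver Electroporation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element modeling of electrochemotherapy (ECT) and
    irreversible electroporation (IRE) in liver tissue on 2-D cross-section
    geometries. Solves the nonlinear steady-state potential problem with
    field-dependent (smoothed-step) tissue conductivity for sequentially
    activated electrode pairs, superposes per-pair fields, runs a duty-cycle
    Pennes bioheat solver with Arrhenius thermal-damage integration, and fits
    electric-field thresholds to segmented damage-zone masks with the
    Sorensen-Dice coefficient. Includes a hepatic-lobule microstructure
    generator (hexagonal lobule lattice with interlobular septa and
    centrilobular veins), a heterogeneity study comparing heterogeneous,
    semi-homogeneous and homogeneous tissue models, and a synthetic-case
    generator producing damage-zone masks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
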