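Package: diallelQTL
Title: Multi-Parent Half-Diallel QTL Mapping for Tomato Flavor Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for flavor quantitative trait
    locus (QTL) mapping in a four-parent half diallel. Provides a meiosis
    simulator (Haldane map function, single-seed descent to recombinant
    inbred lines), parental-origin dosage encoding, the three marker-trait
    association models used for such designs (diversity-panel regression,
    an F2 half-diallel mixed model with REML variance components and a
    Wald test on founder-allelic effects with a ripening-mutation
    correction, and per-cross F6 scans), Kruskal-Wallis marker
    association, QTL-map binning, founder-haplotype representation scoring
    in germplasm panels, random-forest sensory-metabolite modelling with
    signed permutation importance, and substitution fine mapping of QTL
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    ape,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
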