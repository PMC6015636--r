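Package: stereophantom
Title: Design-Based Stereology Pipeline Validated on Synthetic Tissue Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the two classical design-based stereological
    estimators for serial histological sections - Cavalieri point-counting
    volumetry with a systematic uniform random section sample, and
    physical-dissector estimation of neuron numerical density with the
    unbiased counting frame (acceptance and forbidden lines) - together
    with the downstream one-way ANOVA and Fisher LSD group comparison used
    in developmental neurotoxicology studies. A synthetic layered-organ
    phantom generator with exactly known compartment volumes and cell
    positions provides ground truth, so the unbiasedness of every
    estimator and the full four-group analysis can be verified end to end
    without real histology data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, tiff, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
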