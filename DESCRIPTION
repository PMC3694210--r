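Package: artimap
Title: Motor-Based Speaker Normalization for Phone Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Speaker normalization for phone classification through an
    acoustic-to-articulatory mapping: a deep neural network (pretrained as a
    stack of restricted Boltzmann machines, fine-tuned by back-propagation)
    maps any speaker's Mel-filtered spectral coefficients into the
    articulatory feature space of a reference listener, and the reconstructed
    articulatory features augment a phone classifier. Includes a synthetic
    paired audio/electromagnetic-articulography corpus generator (shared
    articulatory latent, speaker-specific source-filter acoustics),
    phone-synchronous acoustic and articulatory feature extraction, acoustic
    baseline normalization strategies, scenario machinery for within-speaker
    and cross-speaker evaluation, exact McNemar comparison of classifiers,
    and articulatory-reconstruction correlation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
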