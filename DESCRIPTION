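Package: dsfuse
Title: Time-Domain Fusion of Classification Evidence with Weighted
    Dempster-Shafer Combination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for smoothing and fusing noisy per-frame classification
    evidence under Dempster-Shafer theory. Provides mass-function algebra
    (belief, plausibility, conflict, Dempster's rule), belief entropies
    (Shannon, Deng, and a bound-based entropy that discriminates evidence
    sharing states across focal elements), the Jousselme distance, an
    8-step weighted time-domain fusion algorithm with credibility
    partitioning and entropy-based reward/penalty weighting, sliding-window
    streaming fusion, discounting of classifier scores into basic
    probability assignments via confusion-matrix precision and recall, a
    seeded synthetic classification-stream generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
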