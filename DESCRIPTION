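Package: dartpulse
Title: Quantification of Love-Dart Mucus Effects on Snail Reproductive Organs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for in vitro organ-bath cross-reactivity
    experiments on helicid land snails, in which accessory-gland mucus carried
    by the love-dart is applied to preparations of the female reproductive
    tract.  Provides marker tracking from video frame stacks, displacement
    traces on a 5-second grid, a rule-based contraction detector and per-trial
    scorer, daily positive-control normalization, the diverticulum-shortening
    metric, and the study's inference layer: a Steel many-one rank test
    (nonparametric Dunnett-type comparison with control), split-plot mixed
    ANOVA with Fisher LSD simple effects, paired Wilcoxon and Kruskal-Wallis
    tests, log-link GLMs compared by AICc, and Blomberg's K with randomization
    p-values on a supplied phylogeny.  A synthetic-data module generates every
    input with known ground truth, from marker trajectories with planted
    contraction events to Brownian-motion traits on a tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
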