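Package: cliffopt
Title: Activity-Cliff-Guided Single-Atom Ligand Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Jointly predicts ligand bioactivity and proposes single-atom
    element substitutions that move a ligand across an activity cliff. A
    graph-attention molecular encoder feeds a bioactivity predictor; an
    adversarial perturbation of the molecular embedding, decoded through an
    attentive graph reconstruction network, yields a maximum-posterior choice
    of which atom to change and which element to put there. Includes matched
    molecular pair cliff mining, activity-cliff train/test splits, evaluation
    metrics, and a synthetic scaffold-library generator with a planted
    element-at-site activity rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    pROC
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
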