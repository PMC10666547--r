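Package: toxprio
Title: Chemical Prioritization by Direct Classification of Acute Fish Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing chemicals by acute fish toxicity (96 h LC50)
    directly from molecular descriptors. Implements descriptor-table curation
    (replicate-stability, max-scaling, variance and cross-set ratio filters,
    PCA chemical-space projection), toxicity category schemas (bootstrapped
    k-means on log LC50 and monoisotopic mass, and fixed GHS acute aquatic
    hazard thresholds), random-forest QSAR regression with two-step
    categorization versus direct random-forest classification (grid search,
    3-fold cross-validation, out-of-bag importance, relative-importance
    variable selection), leverage-based applicability-domain assessment over
    alternative descriptor subspaces, evaluation reports, a synthetic-data
    generator emulating the structure of real descriptor sets, and an
    end-to-end pipeline runner with reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    MASS,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
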