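Package: nestspacing
Title: Territoriality Analysis of Raptor Nest Spacing in Patchy Forest Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess habitat quality from the territorial spacing of
    forest raptors (goshawk, sparrowhawk, buzzard). Computes nearest-neighbour
    distances between con-specific nests at annual and multi-annual scales,
    tests them against a habitat-constrained Monte-Carlo null model (forest-type
    proportions, minimum patch size, maximum elevation), quantifies spatial
    regularity with the G index, habitat preference with Ivlev's electivity
    index, breeding density, and ranks populations against literature
    nearest-neighbour distances. Includes a synthetic landscape and hard-core
    nest-pattern generator with known ground truth for validating every stage,
    and gamma mixed-model (AICc) comparison of observed versus simulated
    distances.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    glmmTMB,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
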