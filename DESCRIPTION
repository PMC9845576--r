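Package: n2osource
Title: Source Partitioning of N2O Emissions from Isotopocule and 15N Tracer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for attributing nitrous oxide (N2O) emissions to microbial
    source processes in closed-chamber experiments. Implements closed-chamber
    flux estimation with robust linear regression, two-endmember correction of
    isotopocule values for atmospheric N2O admixture with Gaussian error
    propagation, dual-isotope (site preference vs. d18O) endmember mapping
    with Rayleigh fractionation to estimate the bacterial-denitrification
    fraction and the N2O/(N2O+N2) product ratio, 15N-tracer two-pool source
    partitioning from N2O isotopologue distributions, and a whole-system
    excess-15N mass balance with tracer recovery. A forward simulator of the
    full labeling experiment with known ground truth supports parameter
    recovery testing of every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
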