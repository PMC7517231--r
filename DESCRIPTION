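Package: sampenprof
Title: Sample Entropy Profiles and Relative-Consistency Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Sample Entropy (SampEn) profiles of univariate time
    series across an entire grid of tolerance radii in a single pass over
    template pairs, using a look-up-table (NCM-style) correlation-sum engine
    with an exact brute-force reference implementation. Provides seeded
    generators for the MIX(p) process (a sinusoid whose samples are replaced
    by uniform noise with probability p) and the MIXTURE(lambda) process (a
    sinusoid plus bounded uniform noise), tools for averaging entropy
    profiles over replicate realizations, detecting and localizing crossings
    between profiles by sign-change bracketing, and mapping the region of
    (r, tuning-parameter) space in which the relative ordering of profiles
    is preserved.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
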