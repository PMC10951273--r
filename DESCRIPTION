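Package: breedgain
Title: Quantifying Historical Genetic Gain in Clonal Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for documenting genetic gain in long-running clonally
    propagated breeding programs such as strawberry. Builds pedigree (A),
    genomic (G), and unified single-step (H) additive relationship matrices
    with SNP quality control; estimates breeding values for genotyped and
    ungenotyped individuals by single-step BLUP with REML variance
    components, prediction error variances, and accuracies; locates the
    onset of directional selection by continuous piecewise (change-point)
    regression of breeding values on birth year, including a
    transformed-residual analysis of additive-variance trends; analyses
    replicated clonal trials by linear mixed models with estimated marginal
    means, clone-mean heritability, genetic-gain contrasts, and AUDPS
    disease scoring; predicts progeny means and additive genetic variances
    of prospective crosses by simulating meiosis from phased parents with
    ridge-regression marker effects; and supplies a fully synthetic
    breeding-program generator (pedigree, haplotypes, trait architectures,
    trial phenotypes) so the whole chain can be exercised and tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    emmeans,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    vcfR,
    withr
Config/testthat/edition: 3
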