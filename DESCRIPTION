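Package: pedrecomb
Title: Crossover Detection and Maternal-Age Effects in Genotyped Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Localizes meiotic crossover events in nuclear families from
    dense SNP genotypes by sibling-comparison phasing, with marker-level
    pre-treatment of spurious tight double recombinants, removal of
    crossovers shared between siblings, and reduced-family counting that
    removes the family-size bias in event totals. Quantifies the effect of
    parental age at birth on recombination with family-adjusted linear
    regression, random-intercept mixed models, penalized linear splines
    fitted by REML, rank statistics and permutation tests, evaluates
    chromosome-specific shifts between maternal age groups with
    redistribution simulations, maps events to centromere-relative
    coordinates and measures congruence with recombination hotspots, and
    implements a model of age-dependent loss of the protection against
    chromosome non-disjunction conferred by recombination. Reads and writes
    PLINK bed/bim/fam pedigree genotypes and includes a pedigree genotype
    simulator with fully known crossover truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    nlme,
    lme4,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
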