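Package: stocksel
Title: Selection for Farm-Introgressed Genotypes Under Hatchery Supplementation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how hatchery supplementation of wild Atlantic salmon
    populations selects for farm-introgressed genotypes. Provides a supervised
    maximum-likelihood estimator of individual proportion farmed ancestry from
    diagnostic SNP panels, parentage assignment of recaptured adults to
    broodstock pairs by Mendelian exclusion with mitochondrial maternity
    verification, scale-based back-calculation of smolt length and volumetric
    egg measurements, and the accompanying mixed-model suite: log-count and
    log-phenotype linear mixed models with AIC model selection, a
    multinomial-logit mixed model for sea age fitted by Laplace approximation,
    and an overdispersed logit model contrasting introgression in wild-born and
    hatchery-reared spawners. A seeded synthetic-data generator reproduces the
    statistical structure of a stocked-river study for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: lme4, stats, utils, yaml
Suggests: testthat (>= 3.0.0), nnet, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
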