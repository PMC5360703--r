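Package: goalcat
Title: Goal-Directed Bayesian Categorization Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying why categorization systems should represent
    latent causes, hierarchies, context and action. Provides discrete
    generative models (directed acyclic graphs of categorical variables with
    block-structured conditional probability tables), constructors for four
    canonical model structures, a characteristic-parameter complexity
    calculus with threshold inequalities, exact planning-as-inference for
    action and category posteriors, Bayesian model evidence with an
    accuracy-minus-complexity decomposition (closed-form Dirichlet
    multinomial scores, exact latent sums, and an EM plus BIC
    approximation), and a seeded synthetic-environment simulator with
    structure-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
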