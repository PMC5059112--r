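Package: pathscreen
Title: Simulation and Deconvolution of Pathway-Centric Pooled Resistance Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pathway-centric pooled gain-of-function screens that
    map signaling pathways to drug-resistance phenotypes. Ships a barcoded
    library manifest of 36 pathway-activating constructs spanning 17
    oncogenic signaling pathways plus control constructs, a synthetic screen
    generator (Poisson infection at low multiplicity, dose arms spanning
    GI20-GI80, passage bottlenecks, multinomial sequencing with substitution
    errors, 27-nt barcode reads), a streaming FASTQ demultiplexer and barcode
    counter, fractional-representation enrichment normalized to vehicle arms,
    and pathway-level hit calling against negative-control baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
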