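Package: codonadapt
Title: Virus-Host Codon Usage Co-Adaptation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for analysing codon usage bias in coding sequences and
    the co-adaptation of a virus's codon usage to its host. Computes relative
    synonymous codon usage (RSCU), the effective number of codons (ENc, Wright's
    estimator and Novembre's composition-corrected variant), synonymous codon
    usage orderliness (SCUO), the codon adaptation index (CAI) with a
    host-ENc-derived reference set, the relative codon deoptimization index
    (RCDI), a virus-host codon usage similarity index (SiD), positional GC
    composition, parity-rule-2 (PR2) third-position biases, and dinucleotide
    over/under-representation z-scores under base, codon and synonymous-codon
    shuffling null models. Includes a seedable synthetic CDS generator with
    controllable codon preference and GC3, ENc-GC3 and PR2 diagnostic plots,
    and a single pipeline entry point that writes tidy TSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
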