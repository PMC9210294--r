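Package: bsaseqr
Title: BSA-Seq Trait Association via the Significant-SNP Ratio, Allele
    Frequency, and G-Statistic Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects trait-associated genomic regions from bulked segregant
    analysis sequencing (BSA-Seq) data, with or without parental genome
    sequences. Implements the significant-SNP (sSNP/totalSNP ratio) method
    based on per-SNP Fisher's exact tests of bulk allele depths, alongside
    the allele-frequency difference and G-statistic methods, including SNP
    filtering, REF/ALT allele-depth swapping against a reference parent,
    Savitzky-Golay smoothing of per-chromosome statistic tracks,
    Monte-Carlo significance thresholds, sliding-window genome scans with
    peak verification, and an F2 population simulator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
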