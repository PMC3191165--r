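Package: chromoband
Title: Band and Interband Demarcation on Physical Maps of Interphase Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demarcates polytene-chromosome band and interband borders on a
    physical genome map by consensus over open-chromatin evidence tracks
    (interband-associated proteins, DNase I hypersensitive sites, histone H1
    dips, ORC binding), and provides the downstream computations for such
    maps: band/interband lengths and DNA fractions, DNA compaction ratios
    from electron-microscopy axial lengths, classification of bands into
    late-replicating intercalary-heterochromatin and early-replicating faint
    types, genomic context of interbands against gene models, ORC spacing
    statistics, chromatin-state composition, and banding-map comparison.
    Includes a synthetic-track generator with planted ground truth so the
    whole pipeline can be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
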