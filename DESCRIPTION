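Package: condel
Title: Consistency-Based Detection of Tumor-Specific Deletions from
    Matched Paired-End Mappings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate tumor-specific deletions from paired-end
    mappings of matched normal and tumor samples. Deletion-indicating
    discordant mappings are grouped into maximal valid clusters, checked
    for haploid and diploid consistency (minimal conflicting sets as
    hyperedges of a two-colorable conflict hypergraph), and mappings from
    the contaminated tumor sample are assigned to four chromosome copies
    (two normal, two tumor) by a branch-and-bound search that minimizes
    the number of discarded mappings. Includes a simulator of matched
    normal/tumor mapping data with planted heterozygous deletions and
    ground truth, readers for SAM/BAM and a simple tab-separated
    paired-end format, and a pipeline entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
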