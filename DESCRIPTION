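Package: chromcode
Title: Combinatorial Chromatin Codes by Sparse Non-Negative Matrix
    Factorization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovers sparse combinatorial patterns ("codes") of histone
    modifications from ChIP-seq data by non-negative matrix factorization
    of locus-by-mark signal matrices. Provides three modes of analysis:
    absolute (codes of co-occurring mark levels at one set of loci),
    discriminatory (class-specific codes recombined by non-negative least
    squares over all loci), and differential (codes of coordinated
    per-mark gain and loss between two conditions, from depth-corrected
    windowed coverage differences). Includes deterministic NNDSVD
    initialization, Hoyer sparsity diagnostics, rank scanning, hard code
    assignment, Hungarian-algorithm matching of basis patterns across
    factorizations, Spearman multicollinearity reports, random-set
    gene-set enrichment with Benjamini-Hochberg correction, a synthetic
    benchmark generator with planted ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    IRanges,
    Rsamtools,
    DESeq2,
    fgsea,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
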