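Package: dinuprof
Title: Gapped Dinucleotide Frequency Profiles for Alignment-Free DNA
    Sequence Comparison
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes DNA sequences by the frequencies of ordered
    nucleotide pairs XY at separation distances d = 1..d0, where d0 is
    bounded by one quarter of the sequence length so that at least half of
    all positions contribute to every pair layer.  Each sequence maps to a
    d0 x 16 frequency matrix (or its flattened 16*d0 vector), and sequence
    sets are compared through city-block distances between matrices and
    cosine distances between vectors, without alignment.  Includes pairwise
    distance matrices with TSV/CSV/PHYLIP export, relative-similarity
    tables, covariance PCA projections of the profile vectors, the classic
    11-species beta-globin exon-1 benchmark as a built-in dataset, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
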