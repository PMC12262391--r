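Package: chromsaliency
Title: Information-Theoretic Saliency Scoring of Multi-Biosample Chromatin State Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the saliency (surprisal, in bits) of chromatin-state
    configurations observed across many biosamples at each genomic bin,
    using Kullback-Leibler divergence against genome-wide background models
    of increasing complexity (state frequencies, state-pair co-occurrence,
    and state-pair by biosample-pair co-occurrence). Builds consensus
    epigenomes, performs pairwise differential analysis between biosample
    groups with a signed squared Euclidean distance statistic and a
    permutation null fitted by a generalized normal distribution, recommends
    high-saliency regions with a greedy non-overlapping window algorithm,
    and searches the genome for regions with similar chromatin-state
    architecture via a scale-normalized 25-block max-pooled representation.
    Includes a seed-deterministic simulator of categorical annotation
    matrices with planted patterns for testing, readers and writers for
    BED-like segmentations, bedGraph and TSV score tracks, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
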