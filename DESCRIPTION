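Package: panrescue
Title: Pan-Genome Anchor Realignment for Structural Variant Rescue from Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Augments a linear reference genome with anchor sequences built
    from a panel of known structural variants (deletions, insertions and
    duplications), re-aligns SV-signature short read pairs against those
    anchors with a seed-chain-extend aligner over a de Bruijn graph k-mer
    index, and infers genotyped SV calls from clustered, assembled and
    consensus-aligned reads. Includes a deterministic simulator of genomes,
    implanted SVs, divergent known-SV panels and paired-end reads so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
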