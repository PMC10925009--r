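Package: oligocodec
Title: Error-Corrected Binary-to-DNA Transcoding for Oligo Pool Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes arbitrary binary files into pools of synthetic-DNA
    oligonucleotides and recovers them bit-exactly after sequencing errors.
    Payload bits are protected block-wise by systematic Levenshtein
    (Varshamov-Tenengolts) codes that correct a single substitution, deletion,
    or insertion per block, then transcoded three bits to two bases under a
    codebook that forces 50% local GC content, caps homopolymers at two
    bases, and excludes the GAATTC and GGC motifs. Includes a seeded
    substitution/indel channel simulator, a pluggable lossless compression
    front-end, pool metrics (net information density, constraint audits,
    SSIM for images), and an end-to-end encode/corrupt/decode pipeline with
    FASTA input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
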