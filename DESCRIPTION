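Package: transannot
Title: Membrane Transporter Annotation with Negative-Rule Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Annotates membrane transport proteins in prokaryotic proteomes
    by aggregating homology, profile-HMM, COG and transmembrane-topology
    evidence, removing false-positive ATPase look-alikes with a declarative
    negative decision tree, transferring transporter family, Transporter
    Classification (TC) numbers and tiered substrate predictions from a
    curated reference table (abstaining when evidence is weak), and scoring
    predictions against a gold standard with false-positive and
    false-negative rates. Includes a built-in Kyte-Doolittle hydropathy
    predictor of transmembrane segments, readers and writers for the
    standard evidence formats (BLAST tabular, HMMER3 domtblout, TMHMM short
    output), and a deterministic synthetic-fixture generator with planted
    transporters and decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
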