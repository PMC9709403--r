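Package: polyatac
Title: ATAC-Seq Open-Chromatin Analysis for Large Plant Genomes
Version: 0.1.0
Authors@R: person("polyatac", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained toolkit for ATAC-seq analysis in large
    (polyploid) plant genomes, from aligned Tn5 tags or fragments to
    reproducible open-chromatin regions.  Implements post-alignment
    filtering and duplicate removal with ENCODE-style library-complexity
    metrics, cut-site pileup tracks with shift/extension smoothing and
    per-million normalization, a native Poisson local-background peak
    caller, irreproducible-discovery-rate (IDR) consistent-peak selection
    with pseudo-replicates, a quality-control battery (TSS enrichment,
    FRiP, SPOT, fragment-length periodicity, binned track correlation,
    organelle-contamination accounting), sequencing-saturation analysis by
    subsampling and Michaelis-Menten extrapolation, peak-to-gene promoter
    annotation, and a ground-truth synthetic-library simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
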