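Package: CoFrag
Title: Identification of Co-Fragmented Peptides by Full Isolation-Window
    Search of DDA and Wide-Window Acquisition Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A spectrum-centric database search engine for chimeric tandem
    mass spectra. Every MS2 spectrum is scored with the hyperscore against
    all database peptides whose precursor m/z falls anywhere inside the
    full isolation window, rather than within a narrow tolerance of the
    instrument-reported precursor. Search results are then refined by
    targeted extraction of precursor isotope chromatograms from MS1,
    scored against averagine isotope envelopes with the Kullback-Leibler
    divergence, and rescored by greedy removal of fragment peaks shared
    between co-fragmented peptides. Includes in-silico digestion with
    decoy and shuffled-entrapment database generation, target-decoy
    q-value estimation, entrapment-based false-discovery-proportion
    bounds, and a ground-truthed synthetic LC-MS run generator covering
    conventional narrow-window DDA and wide-window acquisition
    geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    mzR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
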