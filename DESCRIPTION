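Package: isceimap
Title: Mapping I-SceI-Mediated Transgene Integration Sites from Whole-Genome
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates meganuclease (I-SceI) mediated transgene integration
    sites at base-pair resolution from paired-end whole-genome sequencing,
    estimates transgene copy number from GC-corrected coverage ratios, and
    annotates junction microhomology consistent with microhomology-mediated
    end joining (MMEJ). Reads are aligned to a combined reference (host genome
    plus the transgene construct as an extra chromosome) in end-to-end and
    local modes; discordant "junction pairs" and soft-clipped "split reads"
    are clustered into left/right integration boundaries, paired into sites,
    and classified as blunt joins, target-site deletions, or target-site
    duplications. A seeded simulator emulates a hemizygous transgenic genome
    (multi-copy concatemer insertions, target-site lesions, junction
    microhomology) so the whole analysis runs and is tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
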