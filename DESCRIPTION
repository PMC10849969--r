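Package: revmet
Title: Reverse Metabolomics with Virtual Combinatorial Libraries and
    Desk-Scale Spectral Repository Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the reverse-metabolomics discovery strategy:
    enumerate virtual combinatorial condensation libraries (N-acyl amides,
    acyl esters, amino-acid-conjugated bile acids) with exact monoisotopic
    mass and adduct m/z calculus, select reference MS/MS spectra from
    acquisition runs, search spectral corpora with repository-style match
    criteria (precursor tolerance, minimum matched ions, cosine score),
    match LC-IMS features against library records (ppm, retention time,
    drift time, isotope dot product), aggregate criteria-passing matches
    against sample metadata into presence/absence summaries, phenotype
    proportions, binary-Jaccard ordination and Wilcoxon/Benjamini-Hochberg
    association statistics, and quantify analytes via internal-standard
    normalized linear calibration.  Includes a synthetic spectra/repository
    simulator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    optparse
Config/testthat/edition: 3
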