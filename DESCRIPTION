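Package: nucspacing
Title: Nucleosome Positioning and Internucleosome Spacing from MNase-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing nucleosome organisation from MNase-Seq
    fragment data: strand-separated read-start tracks, fragment-length
    inference by Watson/Crick cross-correlation, normalized occupancy
    tracks and +1-aligned metaprofiles, template-filter nucleosome
    calling, promoter NDR and +1/-1 annotation, internucleosome spacing
    and repeat-length estimation, and paired strain-versus-strain shift
    statistics. Includes a synthetic MNase-Seq generator with ground-truth
    nucleosome architectures and strain-swap perturbation presets for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
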