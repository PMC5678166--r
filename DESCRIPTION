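Package: urbanforay
Title: Collar-Based Analysis of Urban-Edge Raiding in Wild Primates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing GPS/tri-axial accelerometer collar data from
    animals exploiting a risky, resource-rich urban edge. Implements static
    versus dynamic acceleration decomposition and VeDBA (vectorial dynamic
    body acceleration), GPS track cleaning (daylight and distance-jump
    filters, UTM projection), gridded energy and deterrence-risk landscapes
    built from quadrat surveys and ranger score maps, detection of brief
    urban forays with their duration and activity contrast, and the
    accompanying statistics (ties-corrected Kruskal-Wallis, permutation
    partial Mantel test with spatial control, and a spatial mixed model of
    log-VeDBA on deterrence risk). A fully parameterised synthetic collar
    data generator with ground-truth labels makes every stage testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    geosphere,
    optparse
Config/testthat/edition: 3
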