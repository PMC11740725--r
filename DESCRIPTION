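Package: heatshift
Title: Occupational Heat Exposure and Work-Capacity Analysis Under Surface-Albedo Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for estimating outdoor-worker heat exposure and
    productivity under surface-albedo modification scenarios. Generates (or
    ingests) hourly micrometeorology for a monthly campaign, computes wet bulb
    globe temperature (WBGT) from the Stull wet-bulb approximation and an
    iterative Liljegren-style globe-temperature energy balance, converts hourly
    WBGT to physical-work-capacity loss via a logistic exposure-response, and
    aggregates losses to worker shifts to report hours of productivity gained
    under cooling scenarios. Includes narrow-to-broadband satellite albedo
    conversion and scenario remapping of surface-type albedos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff,
    ggplot2
Config/testthat/edition: 3
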