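Package: dndea
Title: Dynamic Network Slacks-Based Measure DEA with Undesirable Outputs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-oriented slacks-based-measure (SBM) data envelopment analysis
    for panels of decision-making units observed over several periods and
    internal divisions. Supports undesirable (bad) outputs, intermediate link
    variables passed between divisions within a period, and good carry-overs
    connecting consecutive periods under variable returns to scale. The
    fractional efficiency program is linearized by the Charnes-Cooper
    transformation and solved per unit; overall scores decompose into period,
    division, and division-period efficiencies, and per-variable total-factor
    efficiency indices are computed from optimal slacks. Includes a packaged
    two-stage production/health-treatment model configuration, a synthetic
    panel generator with planted efficient frontiers for testing, CSV/JSON
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
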