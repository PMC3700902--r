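Package: eutrosim
Title: Coupled Water-Column and Sediment Diagenesis Eutrophication Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A generic box-model simulator of lake eutrophication with
    comprehensive benthic-pelagic coupling. Couples fully mixed water
    compartments to multi-layer sediment columns and dynamically simulates
    phytoplankton competition (linear-programming biomass allocation over
    phenotypes), multi-G decomposition of detrital organic matter, the
    electron-acceptor cascade (oxygen, nitrate, sulphate, methanogenesis),
    nitrification, phosphate adsorption on redox-corrected reactive iron,
    vivianite-like and apatite-like mineral kinetics, opal silicate
    dissolution, sulphide and methane chemistry, surface gas exchange, and
    vertical sediment transport (settling, burial, seepage, bioturbation and
    bio-irrigation as depth-decaying dispersion). Every mass flux is recorded
    in a ledger so elemental mass balances (C, N, P, S, Si, Cl) close to
    numerical precision, enabling audited sediment-water nutrient return
    fluxes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
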