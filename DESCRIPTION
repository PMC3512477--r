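Package: inpa
Title: Impedance Network Protein Analogue for Simulating Protein Charge Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Maps a protein's C-alpha tertiary structure onto an impedance
    network: amino acids become nodes, residue pairs closer than an
    interaction radius become elemental RC links, and the network is solved
    within a linear Kirchhoff scheme for the global impedance spectrum Z(w)
    and its Nyquist plot. Nonlinear current-voltage characteristics are
    obtained from a stochastic sequential-tunneling mechanism in which links
    switch to a low-resistivity state with a voltage-dependent barrier
    penetration probability (direct and Fowler-Nordheim regimes). Native and
    activated conformers can be compared electrically and single-protein
    currents scaled to macroscopic measurements, so that a conformational
    change is monitored as a change in electrical response. Includes PDB
    C-alpha readers, synthetic structure generators for desk-scale studies,
    CSV/JSON exports and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
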