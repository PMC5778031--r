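Package: anisoIR
Title: Direction-Resolved Infrared Spectra of Confined Protonated Water Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes direction-resolved infrared absorption spectra from
    molecular-dynamics dipole time series via the dipole-derivative
    autocorrelation (Wiener-Khinchin) route, tracks excess-proton (hydronium)
    defects and Zundel complexes in water-cluster trajectories, assembles
    dipoles from nuclei with effective charges or from nuclei plus Wannier
    centers, and resolves polarized ATR-FTIR absorbance pairs into in-plane
    and membrane-normal components with the two-phase thick-film
    effective-field formalism.  A classical flexible-water cluster simulator
    (harmonically confined chains, discs and droplets, with or without an
    excess proton) and a stochastic proton-hop dipole emulator provide
    desk-scale synthetic data for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
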