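Package: aqpflux
Title: Transition-State-Theory Analysis of Single-Channel Osmotic Water Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes single-channel osmotic water permeabilities of membrane
    channels (aquaporins and aquaglyceroporins) from equilibrium molecular
    dynamics trajectories using transition state theory with an explicit
    recrossing correction. Detects dividing-plane crossing events in
    channel-frame water tracks and follows each to resolution (bulk arrival or
    recrossing), estimates the transmission coefficient kappa, bins linear
    water density along the pore axis to obtain n(z0), and combines them into
    the TST rate constant k0, the permeability p_f, osmotic rate equations and
    the Arrhenius activation energy. Includes geometric hydrogen-bond analysis
    of single-file waters and an inertial Langevin trajectory generator with a
    configurable axial potential of mean force, so that every stage of the
    pipeline is testable without external simulation data. Reads PDB/PSF
    topologies and DCD trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
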