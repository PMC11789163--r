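Package: evccp
Title: Extended-Variable Coupled Crystal Polymorph Monte Carlo Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Enhanced sampling of molecular-crystal polymorph energy
    landscapes for rigid molecules. Crystal packings are generated
    pseudo-randomly under space-group symmetry and locally minimized on a
    site-site Lennard-Jones plus Coulomb lattice-energy surface.  A set of
    extended variables (molecular centers and Euler angles in an orthogonal
    reference box) is harmonically tethered to the packing coordinates and
    propagated by Metropolis Monte Carlo over mini-batches of minimized
    structures, optionally with replica exchange of the extended variables
    across a temperature ladder, history-dependent Gaussian bias, and
    forced-relaxation restarts.  Includes free-energy perturbation between
    polymorph ensembles (e.g. different numbers of molecules in the
    asymmetric unit) by exponential averaging, harmonic vibrational free
    energies, landscape summaries, and CIF/JSONL input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
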