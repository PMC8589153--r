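Package: rbcmem
Title: Structure and Bending Rigidity of Stacked Red Blood Cell Membranes
    from X-Ray Scattering and Coarse-Grained Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for solid-supported membrane stacks studied by
    X-ray diffraction and diffuse scattering, aimed at red blood cell
    cytoplasmic membranes and how blood-bank storage changes them. Extracts
    specular reflectivity and lamellar d-spacings, reconstructs relative
    electron density profiles by Fourier synthesis with phase enumeration,
    quantifies stack orientation via the Hermans parameter, decomposes
    in-plane wide-angle patterns into lipid-domain and protein peaks with
    Scherrer domain sizing, fits Caille smectic theory to diffuse-scattering
    line cuts for the bending modulus kappa and compression modulus B, and
    analyses coarse-grained bead trajectories (Helfrich-Canham fluctuation
    spectra, component density maps, mass density profiles). Includes
    forward models that generate every input with known ground truth,
    together with a brute-force Monte Carlo smectic scattering oracle, and a
    lipidomics-to-coarse-grained composition mapper with leaflet-asymmetry
    assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
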