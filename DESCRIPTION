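Package: memperm
Title: Membrane Permeability from Umbrella Sampling via WHAM and the
    Inhomogeneous Solubility-Diffusion Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate small-molecule membrane permeability from
    umbrella-sampling window time series. Implements the Weighted Histogram
    Analysis Method (WHAM) for potential-of-mean-force estimation with
    bulk referencing, moving-average smoothing and leaflet assembly
    (mirror duplication for symmetric bilayers, independent-leaflet
    joining for asymmetric ones); position-dependent diffusion
    coefficients from restrained-window position autocorrelation
    (Hummer's variance/autocorrelation estimator); and permeability
    coefficients through the inhomogeneous solubility-diffusion model.
    Includes a seeded overdamped Langevin generator of umbrella windows
    on analytic free-energy/diffusivity landscapes for end-to-end
    validation, plus toy-bilayer structural metrics (mass density
    profiles, Voronoi area per lipid, deuterium order parameters).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
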