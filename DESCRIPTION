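Package: oculotamp
Title: Silicone-Oil Tamponade Statics and Saccadic Wall Shear in the Vitrectomized Eye
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-order models of intraocular silicone-oil (SiO) tamponade.
    Builds a triangulated vitreous-chamber surface (24 mm sphere with an
    anterior lens indentation), segments it into anatomical regions (macula,
    post-equatorial and pre-equatorial retina, ora serrata, lens) split into
    superior and inferior hemispheres, and solves the static oil-aqueous
    equilibrium for a given posture and fill fraction either as a flat
    gravity-normal interface or as an energy-minimizing spherical-cap
    interface honouring interfacial tension and contact angle. Per-region
    retina-tamponade contact fractions are reported. A quintic saccade
    waveform (50 degrees in 0.137 s) drives a per-vertex unsteady Stokes-layer
    wall-shear model, from which five wall-shear summary statistics (IMSS,
    PMSS, VASS, ARSS, IMSR) are computed for 1000 and 5000 mPa.s oils.
    Includes seeded synthetic fixtures carrying their own analytic oracles,
    a 30-configuration sweep driver, and VTK/PLY/CSV writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
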