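Package: rostrabeam
Title: Beam-Theory Section Properties of Archosaur Rostra
Version: 1.0.0
Authors@R: person("Rostrabeam", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes cross-sectional geometric properties (second moments
    of area Ix and Iy, polar moment of inertia J) along transverse image
    stacks of skulls, treating the rostrum as a cantilever beam. Provides
    synthetic hollow-ellipse rostrum phantoms with closed-form ground
    truth, mask preparation operators (thresholding, hole filling, mirror
    completion of hemirostra), isometric size correction to a common skull
    length, and a normality-gated paired test battery (Wilcoxon signed-rank
    normal approximation or paired t) with Sidak family-wise correction,
    plus a configuration-driven pipeline and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
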