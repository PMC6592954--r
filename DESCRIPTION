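Package: darkfield3d
Title: Three-Dimensional X-ray Dark-Field Forward Projection Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward projection model for grating-based X-ray dark-field
    imaging in full 3-D. Models the anisotropic ultra-small-angle scatter of a
    micrometer-scale fiber as an oblate Gaussian spheroid and projects it along
    arbitrary (parallel or cone-beam) rays onto arbitrary interferometer
    sensitivity directions. Includes circular and helical acquisition
    trajectory generators, a chord-length factor for finite fiber cylinders,
    Beer-Lambert dark-field line integrals over voxel and analytic cylinder
    phantoms, sinogram synthesis, and closed-form prior 2-D projection models
    together with numerical consistency checks that the 3-D model reduces to
    each of them under the corresponding geometric constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
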