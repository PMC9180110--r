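Package: opticpath
Title: Along-Tract Diffusion MRI Analysis of the Anterior Optic Pathway
Version: 0.1.0
Authors@R:
    person("Neuroimaging", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-tractography analysis of the anterior optic pathway
    (optic nerve, chiasm, optic tract) from multishell diffusion MRI.
    Normalizes three-tissue spherical-deconvolution output into
    four-compartment signal fractions including a background component,
    fits diffusion tensors and derives fractional anisotropy and mean
    diffusivity with validity filtering, converts streamline bundles into
    fibre-density maps and thresholded tract masks with a
    continuity-driven background-exclusion loop, bins slices into
    anatomy-scaled segments (ten postchiasmatic, seven prechiasmatic),
    computes per-slice and per-segment statistics, compares groups with
    Welch's t-test under Hochberg step-up familywise error control, and
    correlates tract measures with eye-mapped clinical covariates.
    Includes a synthetic optic-pathway phantom (geometry, streamlines,
    compartment volumes, tensor-derived scalar maps, diffusion-weighted
    volumes, clinical covariates) so the full pipeline is testable
    without patient data. Reads and writes NIfTI-1 volumes and MRtrix
    TCK streamline files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
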