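Package: vasobold
Title: Biophysical Simulation of Macrovascular Resting-State BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of the macrovascular contribution to
    resting-state BOLD fMRI at 3 Tesla. Implements a Fourier dipole-kernel
    susceptibility-to-field forward model, analytic infinite-cylinder field
    offsets, single-voxel 2D and 3D cylinder simulators with complex-mean
    static-dephasing signal formation, a whole-volume vascular-network
    simulator driven by sinusoidal blood-volume and oxygenation
    fluctuations, vascular geometry processing (centreline merging, local
    orientation, tube voxelization, blood-volume-fraction maps,
    perivascular shells), resting-state metrics (RSFA, extremum
    cross-correlation functional connectivity, sigma-weighting), and
    binned-regression evaluation of predicted against measured
    connectivity, including a synthetic vascular-network generator for
    end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
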