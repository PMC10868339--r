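Package: biofilmOCT
Title: Structural Characterization of Biofilms from 3D Optical Coherence
    Tomography Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments greyscale voxel volumes from optical coherence
    tomography (OCT) scans of biofilms into bottom (support), biofilm and
    top (bulk liquid) regions, and quantifies biofilm structure. The
    pipeline detects the support interface from the brightest reflector
    per column with iterated running-median smoothing along both the
    horizontal and depth axes, binarizes voxels against a
    percentile-derived void intensity threshold, grows the attached
    biofilm structure from the support under 26-connectivity, grows the
    top region under either a deep or a shallow continuity model, and
    computes mean thickness, roughness, roughness coefficient, compaction
    and porosity, globally or on regions of interest. Includes a chunked
    processing mode that reproduces serial results exactly, a synthetic
    phantom generator with analytic ground truth for validation, and
    rendering of binary masks, interface overlays, thickness heatmaps and
    top-surface topography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    parallel,
    png,
    stats,
    grDevices,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
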