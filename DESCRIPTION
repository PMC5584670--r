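Package: patchrig
Title: Virtual Rig for Automated Two-Photon Targeted Patch-Clamp
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and control algorithms for robotic two-photon targeted
    whole-cell patch-clamp recording, exercised entirely against a built-in
    virtual rig. Provides a synthetic two-photon scene generator (fluorescent
    somata, dye-filled pipette cone, viscoelastic tissue deformation,
    breathing and heartbeat motion, shot and read noise), on-line image
    quantification (background-corrected Otsu segmentation, particle analysis
    and a contrast-focus score), contrast-based autofocus with Gaussian peak
    fitting, step-synchronized target tracking, a closed-loop visual-servo
    pipette approach, PID pneumatic pressure control, seal-test resistance
    estimation, and the adaptive-suction seal and break-in state machine,
    wired together into seeded end-to-end virtual patching experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
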