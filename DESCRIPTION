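Package: sitlight
Title: Smart-Chair Heart-Rate-Variability Sensing, Posture Classification,
    and Ambient Light Biofeedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline computational core of a sensor-augmented office chair
    for workplace health promotion. Processes seat-measured
    ballistocardiogram (BCG) signals into inter-beat intervals via Haar
    wavelet detail denoising, a moving mean-absolute-deviation envelope and
    moving-maximum beat detection; maintains a recursive 40-beat
    heart-rate-variability estimate with per-user calibration; classifies
    sitting posture from six force-sensing-resistor channels with a
    three-layer feedforward network trained by Levenberg-Marquardt; and maps
    sedentary time, posture and HRV onto a 28-LED ambient light strip in
    intervention, stretch-guidance and breathing-biofeedback modes. Includes
    synthetic-signal generators with ground truth so the full closed loop is
    testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
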