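Package: sfcwbreath
Title: Breath Detection for SFCW Ultra-Wideband Radar via Operational
    Bandwidth Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and signal-processing toolkit for detecting human
    respiration with stepped-frequency continuous-wave (SFCW) ultra-wideband
    radar. Provides a seeded echo simulator for a sinusoidally breathing
    point target plus frequency-random static clutter, an operational
    bandwidth segmentation operator that splits the echo matrix into
    overlapping sub-bands, a breath-enhancement pipeline (range synthesis by
    IFFT, slow-time motion filtering, power normalization, low-pass breath
    filtering, slow-time FFT) with configurable averaging along the
    operational frequency, power-range diagnostics with a
    signal-to-noise-and-clutter ratio estimator, and a k-means based target
    presence decision built on per-sub-band power peaks. Includes a plain
    text matrix container, a YAML run configuration, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
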