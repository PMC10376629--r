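Package: wavehrv
Title: Heart Rate Variability from Photoplethysmographic Traces via
    Wavelet Scattering and Adaptive Band-Pass Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts contact or remote photoplethysmography (rPPG) pulse
    traces into refined inter-beat intervals and heart-rate-variability
    metrics. The pipeline projects mean-RGB traces to a pulse candidate
    (plane-orthogonal-to-skin), resamples to a power-of-two rate, computes
    first-order Morlet wavelet scattering coefficients, selects a narrow
    heart-rate band per sliding window by K-means clustering of scattering
    energies, reconstructs the cleaned pulse by overlap-add with edge
    amplification, detects beats with automatic multiscale-based peak
    detection (AMPD), applies rule-based inter-beat-interval refinement,
    and reports SDNN, RMSSD, the Baevsky stress index and the LF/HF ratio.
    Also included: ground-truth cleaning criteria for noisy contact PPG
    reference recordings, paired agreement statistics (MAE, RMS difference,
    Pearson r, paired t-test, Bland-Altman limits), and a synthetic PPG
    generator with known beat times for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
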