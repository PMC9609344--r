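Package: emgpipe
Title: Surface EMG Gesture Classification Pipeline for Myoelectric Prosthesis Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for a low-cost myoelectric
    hand-prosthesis controller. Provides a seeded synthetic surface-EMG
    generator for five hand gestures, a digital emulation of the analog
    conditioning chain (instrumentation pre-amplifier, third-order
    Butterworth low-pass and high-pass filters, non-inverting gain, DC
    offset and a 10-bit 1 kHz ADC), extraction of a 20-element hybrid
    time/frequency/time-frequency feature vector (MAV, zero crossings,
    slope sign changes, waveform length, Burg AR coefficients, FFT and
    short-time Fourier energies, and Daubechies db5 wavelet
    approximation variances), a from-scratch 20-15-5 multilayer
    perceptron trained with Levenberg-Marquardt and four comparison
    optimizers with validation-based early stopping, and evaluation
    utilities including confusion matrices, a randomized assertiveness
    protocol and gesture-to-servo command decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
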