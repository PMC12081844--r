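# Detector geometry constants shared across modules.
QPID_GRID <- 256L               # pixels per side
QPID_PITCH_UM <- 55             # pixel pitch, micrometres
QPID_TIME_QUANTUM_NS <- 1.5625  # least-bit time sampling, ns

GAUSS_FWHM <- 2 * sqrt(2 * log(2))   # FWHM of a unit-sigma Gaussian
GAUSS_FWTM <- 2 * sqrt(2 * log(10))  # FWTM of a unit-sigma Gaussian
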