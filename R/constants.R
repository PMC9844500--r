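#' Proton gyromagnetic ratio
#'
#' `gamma_bar()` returns the proton gyromagnetic ratio divided by 2*pi, in
#' kHz/mT (equivalently Hz/uT or MHz/T). All gradient-to-frequency
#' conversions in the package go through this single constant.
#'
#' @return Numeric scalar, 42.577 kHz/mT.
#' @export
gamma_bar <- function() 42.577

# Internal unit conventions, used consistently throughout:
#   time        ms
#   RF nutation Hz   (complex sample; Mod = amplitude, Arg = RF phase, rad)
#   gradient    mT/m
#   position    mm   (along the gradient axis)
#   velocity    cm/s (1 cm/s = 0.01 mm/ms)
#   off-resonance Hz
# A gradient G mT/m at position x mm shifts the local frequency by
# gamma_bar() * G * x Hz.

CM_S_TO_MM_MS <- 0.01
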