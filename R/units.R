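# Unit conversions between SI internals and conventional reporting units.
# 1 mL/min = 1e-6/60 m^3/s; 1 mm = 1e-3 m; 1 mm^2 = 1e-6 m^2.

mlMinToM3s <- function(q) q * (1e-6 / 60)
m3sToMlMin <- function(q) q * 6e7
mmToM <- function(x) x * 1e-3
mToMm <- function(x) x * 1e3
mm2ToM2 <- function(x) x * 1e-6
m2ToMm2 <- function(x) x * 1e6

# dQ/dA in (mL/min)/mm^2 for a slope c in m/s: Q[m3/s] = c * A[m2]
# => Q[mL/min] = c * 6e7 * 1e-6 * A[mm^2] = 60 c A.
pwvToFieldSlope <- function(c_ms) 60 * c_ms
fieldSlopeToPwv <- function(slope) slope / 60
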