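# Shared fixture builders. Everything is generated in code; the small
# profile keeps module tests fast while preserving the window arithmetic
# (at 512 points over 5 um, a 50-nm RoV window still spans >= 5 samples).

smallProfile <- function(...) {
  args <- list(...)
  defaults <- list(nPoints = 512L, noiseSd = 0.5)
  do.call(sampleProfile, utils::modifyList(defaults, args))
}

# simple analytic curve: flat baseline then Sneddon contact, no solver
sneddonCurve <- function(E = 10, n = 256L, ramp = 2500, cpfrac = 0.5,
                         k = 0.03, theta = 35, nu = 0.5, noise = 0,
                         seed = 1) {
  set.seed(seed)
  Z <- seq(0, ramp, length.out = n)
  Zcp <- cpfrac * ramp
  d <- numeric(n)
  inC <- Z > Zcp
  # small-deflection regime: treat travel as indentation (valid because
  # forces here stay << k * travel)
  d[inC] <- sneddonForce(Z[inC] - Zcp, E, theta, nu) / k
  d <- d + rnorm(n, 0, noise)
  list(curve = forceCurve(Z, d, k = k, theta = theta, nu = nu,
                          Zglass = Zcp + 1e6, label = "sneddon-toy"),
       cpIndex = max(which(!inC)), Zcp = Zcp)
}

# iid-noise curve with no contact anywhere
noiseCurve <- function(n = 512L, sd = 1, seed = 1, k = 0.03) {
  set.seed(seed)
  forceCurve(seq(0, 5000, length.out = n), rnorm(n, 0, sd), k = k,
             label = "noise-only")
}
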