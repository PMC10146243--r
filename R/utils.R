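# Internal geometry / numerics helpers shared across modules.

DEG2RAD <- pi / 180

deg2rad <- function(x) x * DEG2RAD
rad2deg <- function(x) x / DEG2RAD

# Unit vector for a direction given as (azimuth, elevation) in degrees.
# Convention (documented package-wide): x = East, y = North, z = up;
# azimuth measured clockwise from North; elevation from the horizontal.
dir_vector <- function(azimuth, elevation) {
  az <- deg2rad(azimuth)
  el <- deg2rad(elevation)
  c(sin(az) * cos(el), cos(az) * cos(el), sin(el))
}

# Rodrigues rotation of vector v about unit axis k by angle theta (radians)
rotate_about <- function(v, k, theta) {
  k <- k / sqrt(sum(k^2))
  v * cos(theta) + cross3(k, v) * sin(theta) + k * sum(k * v) * (1 - cos(theta))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Round half away from zero (base round() uses banker's rounding; leaf counts
# must not depend on IEEE rounding parity).
round_half_up <- function(x) floor(x + 0.5)

# Derive a reproducible substream seed from a master seed and a stream tag.
# Keeps results < 2^31 so they remain valid R integers.
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate expr with a temporary RNG state seeded by `seed`; restores the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Barometric pressure (kPa) at altitude z (m); scale height 8434 m.
pressure_at_altitude <- function(altitude_m) 101.325 * exp(-altitude_m / 8434)

# Saturation vapour pressure (kPa) over water, Tetens form, T in degC.
svp_kpa <- function(temp_c) 0.61078 * exp(17.27 * temp_c / (temp_c + 237.3))

# Shoelace area of a planar polygon given 2D vertices (n x 2 matrix).
polygon_area_2d <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}
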