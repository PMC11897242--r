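deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi

# Angle of the start->sample chord relative to the start->target ray
# (target straight ahead on +y), counterclockwise positive.
chord_angle_deg <- function(x, y) unname(rad2deg(atan2(-x, y)))

# Position on the play field at a given chord angle and radius.
angle_to_xy <- function(theta_deg, r) {
  th <- deg2rad(theta_deg)
  cbind(x = -r * sin(th), y = r * cos(th))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic per-participant seed stream, order-independent and < 2^31.
derive_seed <- function(seed, index, stream = 0L) {
  (abs(seed) %% 1000003L) * 2099L + index * 7919L + stream * 104729L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
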