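# Independent oracles used across the suite.

# Literal iterative thinning: repeatedly delete the first (chronological)
# fix whose gap from its predecessor is below the threshold, recomputing
# gaps after every deletion.
thin_oracle <- function(times, min_period) {
  repeat {
    if (length(times) < 2) return(times)
    bad <- which(diff(times) < min_period)
    if (length(bad) == 0) return(times)
    times <- times[-(bad[1] + 1)]
  }
}

# Noise-free forward model: arrival times of a transmission at t0 from
# (x, y) at each receiver of `array`.
forward_arrivals <- function(x, y, array, c_ms = 1447, t0 = 0) {
  t0 + plane_distance(x, y, array$x_m, array$y_m) / c_ms
}

# Random non-collinear 3-receiver subset indices of a 7-receiver array.
random_triple <- function(array, min_area = 50) {
  repeat {
    s <- sample(nrow(array), 3)
    a <- array[s, ]
    area <- abs((a$x_m[2] - a$x_m[1]) * (a$y_m[3] - a$y_m[1]) -
                  (a$x_m[3] - a$x_m[1]) * (a$y_m[2] - a$y_m[1])) / 2
    if (area > min_area) return(s)
  }
}
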