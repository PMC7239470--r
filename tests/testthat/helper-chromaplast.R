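# shared fixtures, built in code

grid301 <- 300:700

# single-spectrum set from a reflectance vector on the 300-700 grid
one_spec <- function(r, id = "x01", treatment = "cold", replicate = "r1",
                     sex = "M", temp = NA_real_, wl = grid301) {
  spectrum_set(wl, r, data.frame(
    individual_id = id, sex = sex, treatment = treatment,
    body_temperature = temp, replicate = replicate,
    stringsAsFactors = FALSE))
}

flat_spec <- function(value = 40, ...) one_spec(rep(value, 401), ...)

gaussian_refl <- function(center, sd, amp, bg = 0, wl = grid301) {
  bg + amp * exp(-(wl - center)^2 / (2 * sd^2))
}

# fine-grid trapezoid quadrature oracle for band integrals of an analytic
# reflectance function, independent of the package's integration path
fine_grid_integral <- function(f, lo, hi, step = 0.01) {
  x <- seq(lo, hi, by = step)
  y <- f(x)
  sum((y[-1] + y[-length(y)]) * diff(x)) / 2
}

# random smooth synthetic spectrum: one or two Gaussian bumps over a flat
# or sloping background, always strictly positive somewhere
random_spectrum <- function() {
  n_bump <- sample(1:2, 1)
  r <- rep(stats::runif(1, 0, 3), 401)
  r <- r + stats::runif(1, 0, 0.02) * (grid301 - 300)
  for (b in seq_len(n_bump)) {
    r <- r + gaussian_refl(stats::runif(1, 320, 690),
                           stats::runif(1, 15, 80),
                           stats::runif(1, 5, 60))
  }
  r
}

# random relative quantum-catch vector (Dirichlet-ish via gamma draws)
random_catch <- function() {
  q <- stats::rgamma(4, shape = stats::runif(1, 0.3, 3))
  q / sum(q)
}

# brute-force oracle for r_max: bisection on "t * xyz still inside all four
# face half-spaces", using only the face inequalities
oracle_r_max <- function(xyz) {
  faces <- chromaplast:::tetra_faces()
  inside <- function(p) all(vapply(faces, function(f)
    sum(f$n * p) <= f$c + 1e-12, logical(1)))
  dir <- xyz / sqrt(sum(xyz^2))
  lo <- 0
  hi <- 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (inside(mid * dir)) lo <- mid else hi <- mid
  }
  lo
}

# minimal long_measurements table for the variance-component routines
make_long <- function(ids, treatment, values, metric = "sim",
                      sex = "M", temperature = 23) {
  data.frame(individual_id = ids, sex = sex, treatment = treatment,
             body_temperature = temperature, replicate = NA,
             metric = metric, value = exp(values),
             band_lo = NA_real_, band_hi = NA_real_,
             temperature = temperature,
             temperature_centered = 0,
             value_transformed = values, stringsAsFactors = FALSE)
}
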