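#' A1 visual-pigment spectral sensitivity template
#'
#' Builds a cone spectral sensitivity curve from the standard A1
#' (rhodopsin) alpha + beta band template of Govardovskii et al. (2000).
#' With `x = lambda_max / lambda`, the alpha band is
#' `1 / (exp(A(a - x)) + exp(B(b - x)) + exp(C(c - x)) + D)` with
#' `A = 69.7`, `B = 28`, `C = -14.9`, `D = 0.674`, `b = 0.922`,
#' `c = 1.104` and
#' `a = 0.8795 + 0.0459 exp(-(lambda_max - 300)^2 / 11940)`;
#' the beta band is `0.26 exp(-((lambda - lmb)/bb)^2)` with
#' `lmb = 189 + 0.315 lambda_max` and `bb = -40.5 + 0.195 lambda_max`.
#' The summed curve is normalized to unit area (trapezoid rule) on the grid,
#' so a spectrally flat stimulus excites every cone equally.
#'
#' @param lambda_max Peak sensitivity in nm (may be fractional), within the
#'   grid range.
#' @param grid Integer wavelength grid in nm (default 300:700).
#' @param label Cone label (e.g. `"U"`, `"S"`, `"M"`, `"L"`).
#' @return A `cone_sensitivity` object: list with `label`, `lambda_max`,
#'   `wl`, `raw` (pre-normalization template, peak near 1) and `sens`
#'   (unit-area curve).
#' @export
pigment_template <- function(lambda_max, grid = 300:700, label = NA) {
  if (lambda_max < min(grid) || lambda_max > max(grid)) {
    stop("lambda_max must lie within the wavelength grid")
  }
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((grid - lmb) / bb)^2)
  raw <- alpha + beta
  sens <- raw / trapz(grid, raw)
  structure(list(label = label, lambda_max = lambda_max, wl = grid,
                 raw = raw, sens = sens),
            class = "cone_sensitivity")
}

#' Tetrachromatic visual system
#'
#' Four cone classes (U, S, M, L) built from A1 pigment templates, plus a
#' cone-ratio vector and an illuminant. The default peaks are those of the
#' iguanid lizard *Crotaphytus dickersonae* (359, 459, 481, 558 nm), cone
#' ratios are even, and the illuminant is flat. The noiseless relative
#' quantum-catch computation does not use the ratios; they are carried in
#' the data model to make the evenness assumption explicit.
#'
#' @param peaks Numeric vector of four increasing peak wavelengths in nm.
#' @param ratios Positive cone-ratio vector of length four.
#' @param illuminant Numeric vector on `grid` (default flat = 1).
#' @param grid Integer wavelength grid in nm.
#' @return A `visual_system` object.
#' @export
visual_system <- function(peaks = c(359, 459, 481, 558),
                          ratios = c(1, 1, 1, 1),
                          illuminant = NULL, grid = 300:700) {
  if (length(peaks) != 4L || is.unsorted(peaks, strictly = TRUE)) {
    stop("peaks must be four strictly increasing wavelengths")
  }
  if (length(ratios) != 4L || any(ratios <= 0)) {
    stop("ratios must be four positive numbers")
  }
  if (is.null(illuminant)) illuminant <- rep(1, length(grid))
  if (length(illuminant) != length(grid) || any(illuminant < 0)) {
    stop("illuminant must be non-negative and match the grid")
  }
  labels <- c("U", "S", "M", "L")
  cones <- lapply(seq_len(4L), function(i)
    pigment_template(peaks[i], grid, labels[i]))
  names(cones) <- labels
  structure(list(cones = cones, ratios = ratios, illuminant = illuminant,
                 wl = grid),
            class = "visual_system")
}

#' Load a visual system from a YAML file
#'
#' Recognized keys: `peaks` (four numbers), `ratios` (four numbers,
#' optional), `illuminant` (path to a two-column CSV `wl,intensity`,
#' optional).
#'
#' @param path YAML file path.
#' @return A [visual_system].
#' @export
read_visual_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  grid <- 300:700
  ill <- NULL
  if (!is.null(cfg$illuminant)) {
    tab <- utils::read.csv(cfg$illuminant)
    ill <- stats::approx(tab$wl, tab$intensity, xout = grid)$y
  }
  visual_system(
    peaks = if (is.null(cfg$peaks)) c(359, 459, 481, 558)
            else as.numeric(cfg$peaks),
    ratios = if (is.null(cfg$ratios)) c(1, 1, 1, 1)
             else as.numeric(cfg$ratios),
    illuminant = ill, grid = grid)
}

#' Relative quantum catches of the four cone classes
#'
#' `Q_i = integral R(lambda) S_i(lambda) I(lambda) dlambda` by the trapezoid
#' rule, normalized so the four catches sum to one.
#'
#' @param s A single spectrum on the visual system's grid.
#' @param vs A [visual_system].
#' @return Named numeric vector `c(u, s, m, l)` summing to one.
#' @export
quantum_catch <- function(s, vs) {
  x <- as_single(s)
  if (length(x$wl) != length(vs$wl) || any(abs(x$wl - vs$wl) > 1e-9)) {
    stop("spectrum and visual system must share a wavelength grid")
  }
  if (all(x$r == 0)) stop("no reflectance signal: spectrum is all zero")
  if (any(x$r < 0)) {
    stop("reflectance must be non-negative for the visual model; ",
         "clip negatives first (handle_negatives, mode = 'zero')")
  }
  q <- vapply(vs$cones, function(cone)
    trapz(x$wl, x$r * cone$sens * vs$illuminant), 0)
  q <- q / sum(q)
  names(q) <- c("u", "s", "m", "l")
  q
}

# vertices of the regular tetrahedron in the packaged coordinate convention
# (rows: U, S, M, L pure-catch points; all at distance 0.75 from the origin)
tetra_vertices <- function() {
  verts <- rbind(
    U = tetra_xyz(c(1, 0, 0, 0)),
    S = tetra_xyz(c(0, 1, 0, 0)),
    M = tetra_xyz(c(0, 0, 1, 0)),
    L = tetra_xyz(c(0, 0, 0, 1)))
  colnames(verts) <- c("x", "y", "z")
  verts
}

tetra_xyz <- function(q) {
  u <- q[1]; s <- q[2]; m <- q[3]
  c(x = sqrt(3 / 2) * (1 - 2 * s - m - u) / 2,
    y = (-1 + 3 * m + u) / (2 * sqrt(2)),
    z = u - 1 / 4)
}

# outward face normals and offsets: each face satisfies n . x <= c inside
tetra_faces <- function() {
  v <- tetra_vertices()
  centroid <- colMeans(v)  # the origin
  faces <- vector("list", 4L)
  for (i in seq_len(4L)) {
    tri <- v[-i, , drop = FALSE]
    n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    cc <- sum(n * tri[1, ])
    if (cc < sum(n * centroid)) {  # orient outward
      n <- -n
      cc <- -cc
    }
    faces[[i]] <- list(n = n, c = cc)
  }
  faces
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project relative quantum catches into tetrahedral colour space
#'
#' Uses the convention with the UV vertex on the vertical axis:
#' `x = sqrt(3/2) (1 - 2s - m - u) / 2`, `y = (-1 + 3m + u) / (2 sqrt(2))`,
#' `z = u - 1/4`. All four vertices lie at distance `r = 0.75` from the
#' achromatic origin (equal catches).
#'
#' @param q Named relative-catch vector from [quantum_catch()] (or any
#'   non-negative length-4 vector summing to one).
#' @return A `tetra_point`: list with `x`, `y`, `z`, `r`.
#' @export
tetra_coordinates <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L || any(q < -1e-12) || abs(sum(q) - 1) > 1e-9) {
    stop("q must be four non-negative relative catches summing to one")
  }
  p <- tetra_xyz(q)
  structure(list(x = unname(p[1]), y = unname(p[2]), z = unname(p[3]),
                 r = sqrt(sum(p^2))),
            class = "tetra_point")
}

#' Hue-corrected saturation r.achieved
#'
#' The distance `r` of a colour point from the achromatic origin depends on
#' hue direction, because the tetrahedron is not a sphere: the maximum
#' attainable `r` ranges from 0.25 (face centres) to 0.75 (vertices).
#' `r_achieved` casts a ray from the origin through the point, finds the
#' distance `r_max` to the first tetrahedron face it crosses, and returns
#' `r / r_max`, a hue-independent saturation in `[0, 1]`. The origin itself
#' is defined to have `r_achieved = 0`.
#'
#' @param p A `tetra_point` from [tetra_coordinates()].
#' @return List with `r`, `r_max` and `r_achieved`.
#' @export
r_achieved <- function(p) {
  xyz <- c(p$x, p$y, p$z)
  faces <- tetra_faces()
  inside <- vapply(faces, function(f) sum(f$n * xyz) <= f$c + 1e-9,
                   logical(1))
  if (!all(inside)) stop("point lies outside the tetrahedron")
  r <- sqrt(sum(xyz^2))
  if (r == 0) {
    return(list(r = 0, r_max = NA_real_, r_achieved = 0))
  }
  dir <- xyz / r
  tmax <- Inf
  for (f in faces) {
    denom <- sum(f$n * dir)
    if (denom > 1e-12) tmax <- min(tmax, f$c / denom)
  }
  list(r = r, r_max = tmax, r_achieved = r / tmax)
}

#' Visual-model saturation panel
#'
#' Applies the visual system to every spectrum of a processed set:
#' relative catches, tetrahedral coordinates, `r` and the hue-corrected
#' saturation `r_achieved` (the value fed to the reaction-norm analysis).
#'
#' @param set A [spectrum_set] on the 300-700 nm grid.
#' @param vs A [visual_system] (default: even-ratio iguanid system).
#' @return Data frame with the metadata columns plus `u`, `s`, `m`, `l`,
#'   `x`, `y`, `z`, `r`, `r_achieved`.
#' @export
visual_saturation_panel <- function(set, vs = visual_system()) {
  check_grid(set, 300, 700)
  rows <- lapply(seq_len(ncol(set$refl)), function(j) {
    q <- quantum_catch(list(wl = set$wl, r = set$refl[, j]), vs)
    p <- tetra_coordinates(q)
    ra <- r_achieved(p)
    data.frame(set$meta[j, , drop = FALSE],
               u = q[["u"]], s = q[["s"]], m = q[["m"]], l = q[["l"]],
               x = p$x, y = p$y, z = p$z, r = ra$r,
               r_achieved = ra$r_achieved,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
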