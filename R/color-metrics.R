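#' Band definitions for spectral saturation metrics
#'
#' A band definition names a spectral integration rule. Three modes exist:
#' `fixed` (a constant wavelength window), `peak_tracking` (a window of
#' `half_width` nm either side of the reflectance peak, optionally with the
#' centre capped at `cap` nm), and `minmax_contrast` (the max-minus-min
#' contrast rule, which uses no window).
#'
#' @param name Label for the band.
#' @param mode `"fixed"`, `"peak_tracking"` or `"minmax_contrast"`.
#' @param lo,hi Window limits in nm (fixed mode).
#' @param half_width Half-window in nm (peak-tracking mode; default 50).
#' @param cap Maximum allowed window centre in nm, or `NULL` for no cap.
#' @return A `band_definition` object.
#' @export
band_definition <- function(name,
                            mode = c("fixed", "peak_tracking",
                                     "minmax_contrast"),
                            lo = NULL, hi = NULL,
                            half_width = 50, cap = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(lo) || is.null(hi)) stop("fixed band needs lo and hi")
    if (!(lo >= 300 && lo < hi && hi <= 700)) {
      stop("fixed band requires 300 <= lo < hi <= 700")
    }
  }
  if (mode == "peak_tracking") {
    if (half_width <= 0) stop("half_width must be positive")
    if (!is.null(cap) && !(cap > 300 && cap <= 700)) {
      stop("cap must lie in (300, 700]")
    }
  }
  structure(list(name = name, mode = mode, lo = lo, hi = hi,
                 half_width = half_width, cap = cap),
            class = "band_definition")
}

#' Built-in band presets
#'
#' The packaged saturation metrics and their spectral integration rules:
#' `S1B` (blue, 400-510 nm), `S1Sc` (turquoise, 450-550 nm), `S1ScFull`
#' (blue-to-green, 400-600 nm), `S3` (peak +/- 50 nm), `S3Sc` (peak
#' +/- 50 nm with the centre capped at 600 nm, so long-wavelength background
#' peaks in weakly ornamented animals do not masquerade as ornament
#' saturation), and `S8` (max-min contrast).
#'
#' @return Named list of [band_definition] objects.
#' @export
band_presets <- function() {
  list(
    S1B      = band_definition("S1B", "fixed", lo = 400, hi = 510),
    S1Sc     = band_definition("S1Sc", "fixed", lo = 450, hi = 550),
    S1ScFull = band_definition("S1ScFull", "fixed", lo = 400, hi = 600),
    S3       = band_definition("S3", "peak_tracking"),
    S3Sc     = band_definition("S3Sc", "peak_tracking", cap = 600),
    S8       = band_definition("S8", "minmax_contrast")
  )
}

#' Load band definitions from a YAML file
#'
#' Each top-level YAML key names a band; its fields mirror the
#' [band_definition] arguments (`mode`, `lo`, `hi`, `half_width`, `cap`).
#' Entries override or extend the built-in presets, realizing user-defined
#' spectral ranges for saturation.
#'
#' @param path YAML file path.
#' @return Named list of [band_definition] objects (presets plus overrides).
#' @export
read_band_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bands <- band_presets()
  for (nm in names(cfg)) {
    e <- cfg[[nm]]
    bands[[nm]] <- band_definition(
      nm,
      mode = if (is.null(e$mode)) "fixed" else e$mode,
      lo = e$lo, hi = e$hi,
      half_width = if (is.null(e$half_width)) 50 else e$half_width,
      cap = e$cap)
  }
  bands
}

# single-spectrum accessor used by the scalar metric functions
as_single <- function(s) {
  if (inherits(s, "spectrum_set")) {
    if (ncol(s$refl) != 1L) {
      stop("expected a single spectrum; got ", ncol(s$refl))
    }
    list(wl = s$wl, r = s$refl[, 1L])
  } else {
    list(wl = s$wl, r = s$r)
  }
}

#' Trapezoidal band integral of a spectrum
#'
#' Area under the reflectance curve over `[lo, hi]` (percent reflectance
#' times nm), by the trapezoid rule on the 1 nm grid.
#'
#' @param s A single-spectrum [spectrum_set] (or a list with `wl`, `r`).
#' @param lo,hi Integration limits in nm, `300 <= lo < hi <= 700`.
#' @return Numeric scalar, in units of percent x nm.
#' @export
integrate_band <- function(s, lo, hi) {
  x <- as_single(s)
  if (lo >= hi) stop("integration bounds must satisfy lo < hi")
  if (lo < min(x$wl) - 1e-9 || hi > max(x$wl) + 1e-9) {
    stop("band outside the spectrum's wavelength range")
  }
  keep <- x$wl >= lo - 1e-9 & x$wl <= hi + 1e-9
  trapz(x$wl[keep], x$r[keep])
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Hue as the wavelength of maximal reflectance (H1)
#'
#' Ties are broken deterministically in favour of the lowest wavelength.
#'
#' @param s A single spectrum.
#' @return Wavelength in nm of the global reflectance maximum.
#' @export
hue_H1 <- function(s) {
  x <- as_single(s)
  if (all(x$r == 0)) stop("no reflectance signal: spectrum is all zero")
  x$wl[which.max(x$r)]
}

#' Mean brightness (B2)
#'
#' Arithmetic mean of percent reflectance over all grid points.
#'
#' @param s A single spectrum.
#' @return Mean reflectance in percent.
#' @export
brightness_B2 <- function(s) {
  mean(as_single(s)$r)
}

#' Total brightness over 300-700 nm
#'
#' Total spectral reflectance: the trapezoidal integral of reflectance over
#' the full 300-700 nm range. This is the denominator of every packaged
#' saturation metric.
#'
#' @param s A single spectrum on the 300-700 nm grid.
#' @return Numeric scalar in percent x nm.
#' @export
total_brightness <- function(s) {
  integrate_band(s, 300, 700)
}

total_or_stop <- function(s) {
  tot <- total_brightness(s)
  if (tot <= 0) stop("zero total reflectance over 300-700 nm")
  tot
}

#' Fixed-band spectral saturation
#'
#' Reflectance within a fixed wavelength band relative to total 300-700 nm
#' reflectance. With the packaged presets this yields S1B (400-510 nm),
#' S1Sc (450-550 nm) and S1ScFull (400-600 nm).
#'
#' @param s A single spectrum on the 300-700 nm grid.
#' @param band A fixed-mode [band_definition].
#' @return Dimensionless saturation in `[0, 1]`, with the effective band as
#'   attributes `band_lo`/`band_hi`.
#' @export
saturation_fixed <- function(s, band) {
  if (!inherits(band, "band_definition") || band$mode != "fixed") {
    stop("band must be a fixed-mode band_definition")
  }
  tot <- total_or_stop(s)
  val <- integrate_band(s, band$lo, band$hi) / tot
  structure(val, band_lo = band$lo, band_hi = band$hi)
}

#' Peak-tracking spectral saturation (S3 and S3Sc)
#'
#' Reflectance within `half_width` nm (default 50) either side of the
#' reflectance peak, relative to total 300-700 nm reflectance. With
#' `cap = 600` the window centre is not allowed beyond 600 nm (the S3Sc
#' rule), so that a dominant long-wavelength background in weakly
#' ornamented individuals cannot generate spurious ornament saturation.
#' The window is truncated at the 300/700 nm grid edges; the centre itself
#' is never shifted by edge truncation.
#'
#' @param s A single spectrum on the 300-700 nm grid.
#' @param cap Window-centre cap in nm, or `NULL` for plain S3.
#' @param half_width Half-window in nm.
#' @return Dimensionless saturation in `[0, 1]` with attributes `band_lo`,
#'   `band_hi` and `center` describing the effective window.
#' @export
saturation_S3 <- function(s, cap = NULL, half_width = 50) {
  tot <- total_or_stop(s)
  center <- hue_H1(s)
  if (!is.null(cap)) center <- min(center, cap)
  lo <- max(300, center - half_width)
  hi <- min(700, center + half_width)
  val <- integrate_band(s, lo, hi) / tot
  structure(val, band_lo = lo, band_hi = hi, center = center)
}

#' Max-min contrast saturation (S8)
#'
#' The difference between maximal and minimal reflectance divided by the
#' total 300-700 nm reflectance, implemented exactly as the contrast rule
#' is conventionally printed. Note the dimensional asymmetry: the numerator
#' is in percent while the denominator is in percent x nm, so the value is
#' dimensionless only per-nm; since both numerator and denominator scale
#' linearly with reflectance the metric is still scale-invariant. A variant
#' normalized by mean brightness is available as
#' [saturation_contrast_mean()] and is never silently substituted.
#'
#' @param s A single spectrum on the 300-700 nm grid.
#' @return Numeric scalar (per nm).
#' @export
saturation_S8 <- function(s) {
  tot <- total_or_stop(s)
  x <- as_single(s)
  (max(x$r) - min(x$r)) / tot
}

#' Max-min contrast normalized by mean brightness
#'
#' `(max(R) - min(R)) / mean(R)`: a dimensionless alternative to
#' [saturation_S8()].
#'
#' @param s A single spectrum on the 300-700 nm grid.
#' @return Dimensionless scalar.
#' @export
saturation_contrast_mean <- function(s) {
  x <- as_single(s)
  m <- mean(x$r)
  if (m <= 0) stop("zero mean reflectance")
  (max(x$r) - min(x$r)) / m
}

metric_names <- function() {
  c("H1", "B2", "total_brightness",
    "S1B", "S1Sc", "S1ScFull", "S3", "S3Sc", "S8")
}

compute_one_metric <- function(sub, metric, bands) {
  switch(metric,
    H1 = list(value = hue_H1(sub), lo = NA_real_, hi = NA_real_),
    B2 = list(value = brightness_B2(sub), lo = 300, hi = 700),
    total_brightness = list(value = total_brightness(sub), lo = 300,
                            hi = 700),
    S3 = {
      v <- saturation_S3(sub, cap = bands$S3$cap,
                         half_width = bands$S3$half_width)
      list(value = as.numeric(v), lo = attr(v, "band_lo"),
           hi = attr(v, "band_hi"))
    },
    S3Sc = {
      v <- saturation_S3(sub, cap = bands$S3Sc$cap,
                         half_width = bands$S3Sc$half_width)
      list(value = as.numeric(v), lo = attr(v, "band_lo"),
           hi = attr(v, "band_hi"))
    },
    S8 = list(value = saturation_S8(sub), lo = 300, hi = 700),
    {
      b <- bands[[metric]]
      if (is.null(b) || b$mode != "fixed") {
        stop("unknown metric '", metric, "'; valid names: ",
             paste(union(metric_names(), names(bands)), collapse = ", "))
      }
      v <- saturation_fixed(sub, b)
      list(value = as.numeric(v), lo = b$lo, hi = b$hi)
    })
}

#' Compute a tidy panel of colour metrics
#'
#' Evaluates the requested metrics on every spectrum of a processed set, all
#' from the identical spectra (one processing path feeds every metric).
#' Replicate-level values are preserved; nothing is averaged silently.
#'
#' @param set A [spectrum_set] on the 300-700 nm grid.
#' @param metrics Character vector of metric names (see [band_presets];
#'   plus `"H1"`, `"B2"`, `"total_brightness"`). Custom fixed bands from
#'   [read_band_config] are accepted by name.
#' @param bands Band definitions (default [band_presets()]).
#' @return Data frame with columns `individual_id`, `sex`, `treatment`,
#'   `body_temperature`, `replicate`, `metric`, `value`, `band_lo`,
#'   `band_hi`, ordered by spectrum then metric.
#' @export
compute_metric_panel <- function(set,
                                 metrics = c("H1", "B2", "S1B", "S1Sc",
                                             "S1ScFull", "S3", "S3Sc", "S8"),
                                 bands = band_presets()) {
  check_grid(set, 300, 700)
  known <- union(metric_names(), names(bands))
  bad <- setdiff(metrics, known)
  if (length(bad)) {
    stop("unknown metric name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(known, collapse = ", "))
  }
  rows <- vector("list", length(set) * length(metrics))
  k <- 0L
  for (j in seq_len(ncol(set$refl))) {
    sub <- list(wl = set$wl, r = set$refl[, j])
    for (m in metrics) {
      res <- compute_one_metric(sub, m, bands)
      k <- k + 1L
      rows[[k]] <- data.frame(set$meta[j, , drop = FALSE],
                              metric = m, value = res$value,
                              band_lo = res$lo, band_hi = res$hi,
                              stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    return(data.frame(individual_id = character(), sex = character(),
                      treatment = character(), body_temperature = numeric(),
                      replicate = character(), metric = character(),
                      value = numeric(), band_lo = numeric(),
                      band_hi = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}
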