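#' Construct a set of reflectance spectra
#'
#' A `spectrum_set` holds one or more reflectance spectra measured on a
#' common (or, before regridding, per-set raw) wavelength axis, together with
#' per-spectrum metadata and an append-only processing log. Reflectance is
#' expressed in percent relative to a diffuse white standard.
#'
#' @param wl Numeric vector of wavelengths in nm, strictly increasing.
#' @param refl Numeric matrix of reflectance values, one column per spectrum,
#'   `length(wl)` rows. A vector is accepted for a single spectrum.
#' @param meta Data frame with one row per spectrum and columns
#'   `individual_id`, `sex` (`"M"`/`"F"` or `NA`), `treatment`,
#'   `body_temperature` (degrees C, may be `NA`) and `replicate`.
#' @param log Character vector of processing-log entries (normally empty at
#'   construction; steps append to it).
#'
#' @return An object of class `spectrum_set`: a list with elements `wl`,
#'   `refl`, `meta` and `log`.
#' @export
spectrum_set <- function(wl, refl, meta, log = character()) {
  wl <- as.numeric(wl)
  if (is.null(dim(refl))) refl <- matrix(as.numeric(refl), ncol = 1L)
  refl <- as.matrix(refl)
  if (anyNA(wl) || is.unsorted(wl, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing with no duplicates")
  }
  if (nrow(refl) != length(wl)) {
    stop("refl must have one row per wavelength")
  }
  if (!all(is.finite(refl))) stop("reflectance values must be finite")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  needed <- c("individual_id", "sex", "treatment", "body_temperature",
              "replicate")
  for (col in setdiff(needed, names(meta))) meta[[col]] <- NA
  meta <- meta[needed]
  if (nrow(meta) != ncol(refl)) {
    stop("meta must have one row per spectrum column")
  }
  key <- spectrum_keys(meta)
  if (anyDuplicated(key)) {
    stop("duplicate (individual_id, treatment, replicate) key: ",
         key[duplicated(key)][1L])
  }
  colnames(refl) <- key
  structure(list(wl = wl, refl = refl, meta = meta, log = log),
            class = "spectrum_set")
}

spectrum_keys <- function(meta) {
  paste(meta$individual_id, meta$treatment, meta$replicate, sep = "_")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set: %d spectra, %d wavelengths (%g-%g nm)>\n",
              ncol(x$refl), length(x$wl), min(x$wl), max(x$wl)))
  if (length(x$log)) {
    cat("processing log:\n")
    cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
length.spectrum_set <- function(x) ncol(x$refl)

append_log <- function(set, entry) {
  set$log <- c(set$log, entry)
  set
}

#' Read reflectance spectra from delimited text
#'
#' Two dialects are supported. The *wide* dialect mirrors common spectrometer
#' exports: a first column named `wl` followed by one column per spectrum,
#' with column names of the form `id_treatment_replicate` (for example
#' `m01_cold_r1`). The *long* dialect is tidy: columns `id`, `treatment`,
#' `replicate`, `wl` and `reflectance`, with optional `sex` and
#' `body_temperature` columns.
#'
#' @param path Path to a CSV (or TSV, detected by extension `.tsv`) file.
#' @param dialect `"wide"` or `"long"`.
#' @return A [spectrum_set] with raw wavelengths preserved.
#' @export
read_spectra <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "wide") {
    if (!identical(names(dat)[1L], "wl")) {
      stop("wide dialect requires the first column to be named 'wl'")
    }
    refl <- as.matrix(dat[-1L])
    if (!is.numeric(refl)) stop("non-numeric reflectance values in ", path)
    meta <- parse_wide_names(names(dat)[-1L])
    out <- spectrum_set(dat$wl, refl, meta)
  } else {
    needed <- c("id", "treatment", "replicate", "wl", "reflectance")
    missing_cols <- setdiff(needed, names(dat))
    if (length(missing_cols)) {
      stop("long dialect is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    if (!is.numeric(dat$reflectance)) {
      stop("non-numeric reflectance values in ", path)
    }
    key <- paste(dat$id, dat$treatment, dat$replicate, sep = "_")
    keys <- unique(key)
    wl <- sort(unique(dat$wl))
    refl <- matrix(NA_real_, nrow = length(wl), ncol = length(keys))
    meta_rows <- vector("list", length(keys))
    for (j in seq_along(keys)) {
      rows <- dat[key == keys[j], ]
      if (anyDuplicated(rows$wl)) {
        stop("duplicate wavelength within spectrum ", keys[j])
      }
      idx <- match(rows$wl, wl)
      refl[idx, j] <- rows$reflectance
      meta_rows[[j]] <- data.frame(
        individual_id = rows$id[1L],
        sex = if ("sex" %in% names(rows)) rows$sex[1L] else NA,
        treatment = rows$treatment[1L],
        body_temperature = if ("body_temperature" %in% names(rows))
          rows$body_temperature[1L] else NA_real_,
        replicate = rows$replicate[1L],
        stringsAsFactors = FALSE)
    }
    if (anyNA(refl)) {
      stop("long input: spectra do not share a complete wavelength grid")
    }
    out <- spectrum_set(wl, refl, do.call(rbind, meta_rows))
  }
  append_log(out, sprintf("read %d spectra from %s (%s dialect)",
                          length(out), basename(path), dialect))
}

# wide column names are id_treatment_replicate; extra underscores join into id
parse_wide_names <- function(nm) {
  parts <- strsplit(nm, "_")
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) {
    stop("cannot parse spectrum column name(s): ",
         paste(nm[bad], collapse = ", "),
         " (expected id_treatment_replicate)")
  }
  data.frame(
    individual_id = vapply(parts, function(p)
      paste(p[seq_len(length(p) - 2L)], collapse = "_"), ""),
    sex = NA_character_,
    treatment = vapply(parts, function(p) p[length(p) - 1L], ""),
    body_temperature = NA_real_,
    replicate = vapply(parts, function(p) p[length(p)], ""),
    stringsAsFactors = FALSE)
}

#' Write a spectrum set to delimited text
#'
#' @param set A [spectrum_set].
#' @param path Output file path (CSV, or TSV if the extension is `.tsv`).
#' @param dialect `"wide"` or `"long"` (see [read_spectra]).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  if (dialect == "wide") {
    out <- data.frame(wl = set$wl, set$refl, check.names = FALSE)
  } else {
    n <- length(set$wl)
    out <- data.frame(
      id = rep(set$meta$individual_id, each = n),
      sex = rep(set$meta$sex, each = n),
      treatment = rep(set$meta$treatment, each = n),
      body_temperature = rep(set$meta$body_temperature, each = n),
      replicate = rep(set$meta$replicate, each = n),
      wl = rep(set$wl, times = ncol(set$refl)),
      reflectance = as.vector(set$refl),
      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the processing log to JSON
#'
#' @param set A [spectrum_set].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_processing_log <- function(set, path) {
  jsonlite::write_json(list(n_spectra = length(set), steps = set$log),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Interpolate spectra onto the integer 1 nm grid
#'
#' Linear interpolation onto the inclusive integer grid `lo..hi`
#' (default 300-700 nm, 401 points). Extrapolation is refused: the input
#' must cover the requested range.
#'
#' @param set A [spectrum_set].
#' @param lo,hi Grid limits in nm.
#' @return A [spectrum_set] on the integer grid.
#' @export
regrid_1nm <- function(set, lo = 300, hi = 700) {
  if (lo >= hi) stop("lo must be less than hi")
  if (min(set$wl) > lo || max(set$wl) < hi) {
    stop(sprintf(
      "input covers %g-%g nm; cannot regrid to %g-%g without extrapolation",
      min(set$wl), max(set$wl), lo, hi))
  }
  grid <- seq(lo, hi, by = 1)
  refl <- apply(set$refl, 2L, function(y)
    stats::approx(set$wl, y, xout = grid)$y)
  out <- spectrum_set(grid, refl, set$meta, set$log)
  append_log(out, sprintf("regridded to 1 nm over [%g, %g]", lo, hi))
}

#' Smooth spectra by locally weighted quadratic regression
#'
#' Classic loess smoothing: degree-2 local polynomials with tricube weights
#' and a window covering `span` of the points, evaluated at every grid
#' point. The default span of 2/3 is the conventional choice for reflectance
#' spectra.
#'
#' @param set A [spectrum_set] on the 1 nm grid.
#' @param span Fraction of points in the local window, in (0, 1].
#' @return A smoothed [spectrum_set] on the same grid.
#' @export
smooth_spectra <- function(set, span = 2 / 3) {
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    stop("span must be a single number in (0, 1]")
  }
  check_grid(set)
  wl <- set$wl
  refl <- apply(set$refl, 2L, function(y) {
    fit <- stats::loess(y ~ wl, span = span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    stats::predict(fit, newdata = data.frame(wl = wl))
  })
  out <- spectrum_set(wl, refl, set$meta, set$log)
  append_log(out, sprintf("loess smoothed (degree 2, span %.4g)", span))
}

#' Handle negative reflectance values
#'
#' Smoothing and instrument noise can push reflectance slightly below zero.
#' `mode = "zero"` clips negatives to zero; `mode = "none"` leaves the data
#' untouched (the default: no silent alteration) but still records how many
#' negative points were retained.
#'
#' @param set A [spectrum_set].
#' @param mode `"none"` or `"zero"`.
#' @return A [spectrum_set].
#' @export
handle_negatives <- function(set, mode = c("none", "zero")) {
  mode <- match.arg(mode)
  n_neg <- sum(set$refl < 0)
  if (mode == "zero") {
    set$refl[set$refl < 0] <- 0
    append_log(set, sprintf("negatives clipped to zero: %d point(s)", n_neg))
  } else {
    append_log(set, sprintf("negatives retained: %d point(s)", n_neg))
  }
}

#' Average replicate spectra within (individual, treatment)
#'
#' Pointwise mean of replicate measurements per individual and treatment.
#' The replicate index of each output spectrum is set to `"mean"`. The
#' mixed-model workflow normally consumes replicates directly; averaging is
#' an explicit, optional step.
#'
#' @param set A [spectrum_set] whose members share a grid.
#' @return A [spectrum_set] with one spectrum per (individual, treatment).
#' @export
average_replicates <- function(set) {
  grp <- paste(set$meta$individual_id, set$meta$treatment, sep = "_")
  groups <- unique(grp)
  refl <- vapply(groups, function(g)
    rowMeans(set$refl[, grp == g, drop = FALSE]), numeric(length(set$wl)))
  meta <- set$meta[match(groups, grp), ]
  meta$replicate <- "mean"
  sizes <- table(grp)[groups]
  out <- spectrum_set(set$wl, refl, meta, set$log)
  append_log(out, sprintf(
    "averaged replicates: %d group(s), sizes %s", length(groups),
    paste(as.integer(sizes), collapse = ",")))
}

#' Subset a spectrum set
#'
#' @param set A [spectrum_set].
#' @param idx Integer or logical index over spectra.
#' @return A [spectrum_set] with the selected spectra.
#' @export
subset_spectra <- function(set, idx) {
  spectrum_set(set$wl, set$refl[, idx, drop = FALSE],
               set$meta[idx, , drop = FALSE], set$log)
}

# internal: assert the canonical 300..700 integer grid (or any 1 nm grid)
check_grid <- function(set, lo = NULL, hi = NULL) {
  d <- diff(set$wl)
  if (any(abs(d - 1) > 1e-9)) {
    stop("spectra must be on a 1 nm grid; run regrid_1nm() first")
  }
  if (!is.null(lo) && (abs(set$wl[1L] - lo) > 1e-9 ||
                       abs(set$wl[length(set$wl)] - hi) > 1e-9)) {
    stop(sprintf("spectra must span exactly %g-%g nm", lo, hi))
  }
  invisible(TRUE)
}
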