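#' Configuration for the synthetic badge-spectra generator
#'
#' The generator is phenomenological: each individual's throat-badge
#' spectrum is a Gaussian ornament peak over a sigmoidal long-wavelength
#' background, plus smooth replicate noise.
#'
#' The ornament centre shifts linearly with body temperature,
#' `mu_i(T) = peak_mu0 + peak_beta (T - Tbar) + offset_i`, emulating the
#' green-to-blue hue shift as temperature rises. The ornament amplitude
#' follows `log A_i(T) = a_i + slope_i (T - Tbar)` with
#' `a_i ~ N(mu_a, sigma_a^2)` per individual and
#' `slope_i = amp_slope_mean + amp_slope_coupling (a_i - mu_a) + e_i`,
#' `e_i ~ N(0, amp_slope_sd^2)`: a positive coupling makes individuals with
#' higher baseline ornament expression brighten faster with temperature,
#' which induces the positive slope-intercept correlation the reaction-norm
#' ladder is designed to detect. Unornamented females get a strong downward
#' shift of `a_i`, so at the cold temperature their reflectance is dominated
#' by the background (peak beyond 600 nm) while the temperature-driven
#' amplitude increase brings the ornament peak back below 600 nm when warm.
#' Female hue offsets are non-negative (weak ornaments skew to longer
#' wavelengths), guaranteeing cold peaks above 600 nm for weakly
#' ornamented females.
#'
#' Replicate noise is smooth (white noise on 25 nm knots, spline
#' interpolated) rather than white, so it exercises the loess smoother the
#' way real probe-replacement noise does.
#'
#' @param n_males,n_females Number of individuals per sex.
#' @param fraction_unornamented_females Fraction of females in the
#'   unornamented tier.
#' @param temperatures Named vector of treatment set-points in degrees C.
#' @param n_replicates Measurements per individual per treatment.
#' @param peak_mu0 Ornament-centre at the mean temperature, nm.
#' @param peak_beta Ornament-centre shift per degree C, nm.
#' @param peak_width Gaussian ornament width (sd), nm.
#' @param hue_offset_sd_male SD of the male per-individual hue offset, nm.
#' @param hue_offset_min_female,hue_offset_sd_female Female hue offsets are
#'   `min + |N(0, sd)|`, nm.
#' @param log_amp_mean_male,log_amp_mean_female Mean log ornament amplitude
#'   (percent reflectance) at the mean temperature.
#' @param log_amp_shift_unornamented Additive shift of the mean log
#'   amplitude for the unornamented female tier.
#' @param log_amp_sd SD of `a_i`.
#' @param amp_slope_mean,amp_slope_coupling,amp_slope_sd Amplitude
#'   reaction-norm slope model (per degree C).
#' @param amp_slope_unorn_boost Extra amplitude slope for the unornamented
#'   tier (their faint ornament is expressed only as temperature rises).
#' @param bg_base,bg_rise,bg_center,bg_scale Background
#'   `B(lambda) = bg_base + bg_rise / (1 + exp(-(lambda - bg_center) /
#'   bg_scale))`, percent reflectance.
#' @param bg_base_unornamented Flat background base for the unornamented
#'   tier (their dark throat skin reflects little outside the
#'   long-wavelength rise, which makes background-derived saturation
#'   scores spuriously large).
#' @param amp_replicate_sd SD of the per-replicate log-amplitude
#'   measurement noise (probe repositioning samples slightly different
#'   patches of the badge).
#' @param noise_sd SD of the smooth replicate noise, percent reflectance.
#' @param noise_knot_spacing Knot spacing of the replicate noise, nm.
#' @param max_reflectance Upper clamp on generated reflectance, percent.
#' @param seed Integer seed; every simulation call requires one (here or as
#'   a call argument).
#' @return A `generator_config` object (list).
#' @export
generator_config <- function(n_males = 17, n_females = 15,
                             fraction_unornamented_females = 0.2,
                             temperatures = c(cold = 23, warm = 33),
                             n_replicates = 3,
                             peak_mu0 = 533, peak_beta = -9,
                             peak_width = 35,
                             hue_offset_sd_male = 4,
                             hue_offset_min_female = 19,
                             hue_offset_sd_female = 4,
                             log_amp_mean_male = log(24),
                             log_amp_mean_female = log(20),
                             log_amp_shift_unornamented = -1.9,
                             log_amp_sd = 0.3,
                             amp_slope_mean = 0.08,
                             amp_slope_coupling = 0.13,
                             amp_slope_sd = 0.0242,
                             amp_slope_unorn_boost = 0.12,
                             bg_base = 4, bg_base_unornamented = 0.3,
                             bg_rise = 5,
                             bg_center = 650, bg_scale = 15,
                             amp_replicate_sd = 0.12,
                             noise_sd = 0.3, noise_knot_spacing = 25,
                             max_reflectance = 100,
                             seed = NULL) {
  cfg <- as.list(environment())
  if (length(temperatures) < 2L || anyDuplicated(temperatures)) {
    stop("temperatures must be distinct")
  }
  if (is.null(names(temperatures))) {
    names(cfg$temperatures) <- paste0("t", seq_along(temperatures))
  }
  if (fraction_unornamented_females < 0 ||
      fraction_unornamented_females > 1) {
    stop("fraction_unornamented_females must be in [0, 1]")
  }
  stopifnot(peak_width > 0, log_amp_sd >= 0, amp_slope_sd >= 0,
            amp_replicate_sd >= 0,
            noise_sd >= 0, n_replicates >= 1)
  class(cfg) <- "generator_config"
  cfg
}

#' The packaged study-emulation preset
#'
#' The generator configuration calibrated to the study conditions: 17
#' ornamented males and 15 females (a fifth of them unornamented, the rest
#' weakly ornamented), cold/warm treatments of 23 and 33 degrees C,
#' triplicate measurements, and a positive amplitude slope-intercept
#' coupling. Under this preset the population mean peak wavelength is close
#' to 600 nm when cold and 502 nm when warm, and every female's cold-state
#' reflectance peaks beyond 600 nm.
#'
#' @param seed Optional integer seed stored in the config.
#' @return A [generator_config].
#' @export
preset_paper_emulation <- function(seed = NULL) {
  generator_config(seed = seed)
}

#' Load a generator configuration from YAML
#'
#' Top-level keys mirror the [generator_config] arguments.
#'
#' @param path YAML file path.
#' @return A [generator_config].
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$temperatures)) {
    cfg$temperatures <- unlist(cfg$temperatures)
  }
  do.call(generator_config, cfg)
}

background_curve <- function(cfg, wl, base = cfg$bg_base) {
  base + cfg$bg_rise /
    (1 + exp(-(wl - cfg$bg_center) / cfg$bg_scale))
}

# draw the per-individual truth table
draw_individuals <- function(cfg) {
  n_unorn <- round(cfg$fraction_unornamented_females * cfg$n_females)
  ids <- c(sprintf("m%02d", seq_len(cfg$n_males)),
           sprintf("f%02d", seq_len(cfg$n_females)))
  sex <- c(rep("M", cfg$n_males), rep("F", cfg$n_females))
  tier <- c(rep("ornamented", cfg$n_males),
            rep("weak", cfg$n_females - n_unorn),
            rep("unornamented", n_unorn))
  mu_a <- ifelse(sex == "M", cfg$log_amp_mean_male,
                 cfg$log_amp_mean_female) +
    ifelse(tier == "unornamented", cfg$log_amp_shift_unornamented, 0)
  a <- mu_a + stats::rnorm(length(ids), 0, cfg$log_amp_sd)
  # ornamented tiers: slope coupled to baseline expression (coupling > 0
  # reproduces the higher-baseline-brightens-faster phenomenon);
  # unornamented tier: onset of faint expression with warmth, uncoupled
  unorn <- tier == "unornamented"
  slope <- cfg$amp_slope_mean +
    ifelse(unorn, cfg$amp_slope_unorn_boost,
           cfg$amp_slope_coupling * (a - mu_a)) +
    stats::rnorm(length(ids), 0, cfg$amp_slope_sd)
  hue_offset <- ifelse(
    sex == "M",
    stats::rnorm(length(ids), 0, cfg$hue_offset_sd_male),
    cfg$hue_offset_min_female +
      abs(stats::rnorm(length(ids), 0, cfg$hue_offset_sd_female)))
  data.frame(individual_id = ids, sex = sex, tier = tier,
             a = a, slope = slope, hue_offset = hue_offset,
             ornamented = tier == "ornamented",
             stringsAsFactors = FALSE)
}

smooth_noise <- function(cfg, wl) {
  if (cfg$noise_sd == 0) return(rep(0, length(wl)))
  knots <- seq(min(wl), max(wl), by = cfg$noise_knot_spacing)
  if (knots[length(knots)] < max(wl)) knots <- c(knots, max(wl))
  vals <- stats::rnorm(length(knots), 0, cfg$noise_sd)
  stats::spline(knots, vals, xout = wl)$y
}

#' Simulate reflectance spectra with known ground truth
#'
#' Generates the full synthetic data set described by a
#' [generator_config]: for every individual, treatment temperature and
#' replicate, `R(lambda) = B(lambda) + A_i(T) exp(-(lambda - mu_i(T))^2 /
#' (2 w^2)) + eps(lambda)`, clamped to `[0, max_reflectance]`. Fully
#' reproducible from the seed.
#'
#' @param cfg A [generator_config].
#' @param seed Integer seed (overrides `cfg$seed`; one of the two must be
#'   supplied).
#' @return List with `spectra` (a [spectrum_set] on the 300-700 nm grid)
#'   and `truth` (per-individual data frame of the generating parameters).
#' @export
simulate_spectra <- function(cfg = generator_config(), seed = cfg$seed) {
  if (is.null(seed)) stop("an explicit seed is required")
  set.seed(seed)
  wl <- 300:700
  truth <- draw_individuals(cfg)
  temps <- cfg$temperatures
  tbar <- mean(temps)
  n_spec <- nrow(truth) * length(temps) * cfg$n_replicates
  refl <- matrix(0, nrow = length(wl), ncol = n_spec)
  meta <- vector("list", n_spec)
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    bg <- background_curve(cfg, wl,
                           base = if (truth$tier[i] == "unornamented")
                             cfg$bg_base_unornamented else cfg$bg_base)
    for (tj in seq_along(temps)) {
      temp <- temps[[tj]]
      amp <- exp(truth$a[i] + truth$slope[i] * (temp - tbar))
      center <- cfg$peak_mu0 + cfg$peak_beta * (temp - tbar) +
        truth$hue_offset[i]
      for (rep_j in seq_len(cfg$n_replicates)) {
        k <- k + 1L
        amp_rep <- amp * exp(stats::rnorm(1L, 0, cfg$amp_replicate_sd))
        r <- bg + amp_rep *
          exp(-(wl - center)^2 / (2 * cfg$peak_width^2)) +
          smooth_noise(cfg, wl)
        refl[, k] <- pmin(pmax(r, 0), cfg$max_reflectance)
        meta[[k]] <- data.frame(
          individual_id = truth$individual_id[i], sex = truth$sex[i],
          treatment = names(temps)[tj], body_temperature = temp,
          replicate = paste0("r", rep_j), stringsAsFactors = FALSE)
      }
    }
  }
  set <- spectrum_set(wl, refl, do.call(rbind, meta))
  set <- append_log(set, sprintf(
    "simulated %d spectra (%d individuals, seed %d)", n_spec, nrow(truth),
    seed))
  list(spectra = set, truth = truth)
}

#' Simulate a metric panel directly from the mixed-model process
#'
#' Bypasses spectra entirely and draws log-metric values straight from the
#' random-intercept / random-slope data-generating process that the
#' reaction-norm ladder assumes:
#' `y = (b0 + u0_i) + (b1 + u1_i + b_int I[sex = M]) tc + b_sex I[sex = M]
#' + eps`, with `(u0, u1)` bivariate normal with the given SDs and
#' correlation and `tc` the centred temperature. This makes large
#' type-I-error, power and coverage studies cheap.
#'
#' @param n_males,n_females Individuals per sex.
#' @param temperatures Named vector of treatment temperatures.
#' @param n_replicates Replicates per individual per treatment.
#' @param intercept,slope Fixed intercept and temperature slope (log scale).
#' @param sex_effect,interaction Fixed male offset and male x temperature
#'   interaction.
#' @param sd_intercept,sd_slope,corr Random-effect SDs and their
#'   correlation.
#' @param sd_resid Residual SD.
#' @param metric Metric label stamped on the rows.
#' @param seed Integer seed (required).
#' @return List with `data` (a `long_measurements` table) and `truth`
#'   (per-individual intercepts and slopes).
#' @export
simulate_metric_panel <- function(n_males = 17, n_females = 15,
                                  temperatures = c(cold = 23, warm = 33),
                                  n_replicates = 3,
                                  intercept = -1, slope = 0.1,
                                  sex_effect = 0, interaction = 0,
                                  sd_intercept = 0.22, sd_slope = 0.022,
                                  corr = 0.85, sd_resid = 0.05,
                                  metric = "sim", seed = NULL) {
  if (is.null(seed)) stop("an explicit seed is required")
  if (abs(corr) > 1) stop("corr must lie in [-1, 1]")
  set.seed(seed)
  n <- n_males + n_females
  ids <- c(sprintf("m%02d", seq_len(n_males)),
           sprintf("f%02d", seq_len(n_females)))
  sex <- c(rep("M", n_males), rep("F", n_females))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  u0 <- sd_intercept * z1
  u1 <- sd_slope * (corr * z1 + sqrt(1 - corr^2) * z2)
  tbar <- mean(temperatures)
  rows <- expand.grid(idx = seq_len(n), tj = seq_along(temperatures),
                      rep_j = seq_len(n_replicates))
  tc <- temperatures[rows$tj] - tbar
  male <- as.numeric(sex[rows$idx] == "M")
  y <- (intercept + u0[rows$idx] + sex_effect * male) +
    (slope + u1[rows$idx] + interaction * male) * tc +
    stats::rnorm(nrow(rows), 0, sd_resid)
  data <- data.frame(
    individual_id = ids[rows$idx], sex = sex[rows$idx],
    treatment = names(temperatures)[rows$tj],
    body_temperature = unname(temperatures[rows$tj]),
    replicate = paste0("r", rows$rep_j),
    metric = metric, value = exp(y),
    band_lo = NA_real_, band_hi = NA_real_,
    temperature = unname(temperatures[rows$tj]),
    temperature_centered = unname(tc),
    value_transformed = y, stringsAsFactors = FALSE)
  class(data) <- c("long_measurements", "data.frame")
  truth <- data.frame(individual_id = ids, sex = sex,
                      intercept = intercept + u0, slope_true = slope + u1,
                      stringsAsFactors = FALSE)
  list(data = data, truth = truth)
}
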