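#' Build a long measurement table for mixed-model analysis
#'
#' Takes a tidy metric panel (one row per spectrum x metric, as produced by
#' [compute_metric_panel()] or [visual_panel_to_metric()]) and adds the
#' columns the reaction-norm models consume: `temperature` (from
#' `body_temperature`, or mapped from `treatment` via `temperatures`),
#' `temperature_centered` (centred on the grand mean, so intercepts sit at
#' the mean temperature) and `value_transformed`. Saturation metrics are
#' natural-log transformed before analysis; zero or negative values under
#' the log transform are a hard error.
#'
#' @param panel Tidy metric panel.
#' @param transform `"log_e"` (default, for saturation metrics) or `"none"`.
#' @param temperatures Optional named vector mapping treatment labels to
#'   degrees C (e.g. `c(cold = 23, warm = 33)`), used when
#'   `body_temperature` is missing.
#' @return Data frame of class `long_measurements`.
#' @export
build_long <- function(panel, transform = c("log_e", "none"),
                       temperatures = NULL) {
  transform <- match.arg(transform)
  out <- panel
  temp <- out$body_temperature
  if (any(is.na(temp))) {
    if (is.null(temperatures)) {
      stop("body_temperature missing; supply a treatment -> temperature map")
    }
    temp <- unname(temperatures[as.character(out$treatment)])
    if (any(is.na(temp))) stop("treatment level missing from temperature map")
  }
  out$temperature <- temp
  out$temperature_centered <- temp - mean(unique(temp))
  if (transform == "log_e") {
    bad <- which(out$value <= 0)
    if (length(bad)) {
      stop("log_e transform requires positive values; offending row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    out$value_transformed <- log(out$value)
  } else {
    out$value_transformed <- out$value
  }
  class(out) <- c("long_measurements", "data.frame")
  out
}

#' Convert a visual-model panel to metric-panel rows
#'
#' Reshapes the output of [visual_saturation_panel()] into the tidy metric
#' format, with `metric = "visual"` and `value = r_achieved`, so the
#' visual-model saturation enters the statistical framework exactly like
#' the spectral metrics.
#'
#' @param vpanel Output of [visual_saturation_panel()].
#' @return Tidy metric panel rows.
#' @export
visual_panel_to_metric <- function(vpanel) {
  data.frame(vpanel[c("individual_id", "sex", "treatment",
                      "body_temperature", "replicate")],
             metric = "visual", value = vpanel$r_achieved,
             band_lo = NA_real_, band_hi = NA_real_,
             stringsAsFactors = FALSE)
}

# likelihood-ratio test between two nested lmer fits
lrt <- function(small, big, df) {
  chisq <- max(0, 2 * (as.numeric(stats::logLik(big)) -
                       as.numeric(stats::logLik(small))))
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df = df, lower.tail = FALSE))
}

fit_lmer_quiet <- function(formula, data, reml) {
  messages <- character()
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  list(fit = fit, messages = messages,
       singular = lme4::isSingular(fit, tol = 1e-4))
}

# slope-intercept correlation from the random-effect covariance of a
# random-slope fit
ranef_correlation <- function(fit) {
  vc <- lme4::VarCorr(fit)$individual_id
  corr <- attr(vc, "correlation")[1, 2]
  if (!is.finite(corr)) corr <- NA_real_
  corr
}

#' Fit the reaction-norm model ladder
#'
#' Implements the five-model comparison used to characterize individual
#' reaction norms of a colour metric across temperature:
#' \describe{
#'   \item{model 1}{`value ~ temperature_centered * sex +
#'     (temperature_centered | individual_id)`}
#'   \item{model 2}{as model 1 without the sex x temperature interaction}
#'   \item{model 3}{`value ~ temperature_centered + (1 | individual_id)`}
#'   \item{model 4}{`value ~ temperature_centered +
#'     (temperature_centered | individual_id)`}
#'   \item{model 5}{as model 4 with the slope-intercept correlation
#'     constrained to zero (`||` random-effect syntax)}
#' }
#' The 1 vs 2 comparison (fixed effects; maximum likelihood, 1 df) asks
#' whether the sexes differ in their reaction norms; if so the data are
#' split by sex. The 3 vs 4 comparison (REML, 2 df) asks whether
#' individuals differ in slope; 4 vs 5 (REML, 1 df) whether slope and
#' intercept are correlated. Likelihood-ratio statistics are referred to a
#' plain chi-square with df equal to the parameter-count difference; at
#' variance boundaries this is conservative, and an equal-mixture
#' chi-square option is available via `boundary_mixture = TRUE` for the
#' 3 vs 4 test.
#'
#' @param data A `long_measurements` table restricted to one metric.
#' @param by_sex If `TRUE` (default) and both sexes are present, run the
#'   model 1 vs 2 interaction test and then the per-sex 3/4/5 ladder;
#'   otherwise run 3/4/5 on the pooled data as a single group.
#' @param boundary_mixture Use an equal-mixture chi-square reference for the
#'   3 vs 4 variance-boundary test (off by default).
#' @param groups If `FALSE`, stop after the model 1 vs 2 interaction test
#'   (useful in simulation studies of that test alone).
#' @return A `ladder_result` list: `lrt_1v2` (or `NULL`), and per-group
#'   results each holding model log-likelihoods, `lrt_3v4`, `lrt_4v5`, the
#'   slope-intercept correlation, per-individual BLUP intercepts and
#'   slopes, and convergence flags.
#' @export
fit_ladder <- function(data, by_sex = TRUE, boundary_mixture = FALSE,
                       groups = TRUE) {
  if (length(unique(data$metric)) > 1L) {
    stop("fit_ladder expects data for a single metric")
  }
  if (length(unique(data$temperature)) < 2L) {
    stop("at least two temperatures are required")
  }
  data$individual_id <- factor(data$individual_id)
  sexes <- unique(stats::na.omit(data$sex))
  run_interaction <- by_sex && length(sexes) == 2L
  lrt_1v2 <- NULL
  models_12 <- NULL
  if (run_interaction) {
    m1 <- fit_lmer_quiet(
      value_transformed ~ temperature_centered * sex +
        (temperature_centered | individual_id), data, reml = FALSE)
    m2 <- fit_lmer_quiet(
      value_transformed ~ temperature_centered + sex +
        (temperature_centered | individual_id), data, reml = FALSE)
    lrt_1v2 <- lrt(m2$fit, m1$fit, df = 1)
    models_12 <- list(model1 = model_summary(m1), model2 = model_summary(m2))
  }
  if (!groups) {
    return(structure(list(metric = data$metric[1L], lrt_1v2 = lrt_1v2,
                          models_12 = models_12, groups = list()),
                     class = "ladder_result"))
  }
  grp_data <- if (run_interaction) {
    stats::setNames(lapply(sexes, function(sx) data[data$sex %in% sx, ]),
                    sexes)
  } else {
    list(all = data)
  }
  group_results <- lapply(grp_data, function(d)
    fit_ladder_group(d, boundary_mixture))
  structure(list(metric = data$metric[1L], lrt_1v2 = lrt_1v2,
                 models_12 = models_12, groups = group_results),
            class = "ladder_result")
}

model_summary <- function(m) {
  list(logLik = as.numeric(stats::logLik(m$fit)),
       npar = attr(stats::logLik(m$fit), "df"),
       singular = m$singular, messages = m$messages)
}

fit_ladder_group <- function(d, boundary_mixture = FALSE) {
  m3 <- fit_lmer_quiet(
    value_transformed ~ temperature_centered + (1 | individual_id),
    d, reml = TRUE)
  m4 <- fit_lmer_quiet(
    value_transformed ~ temperature_centered +
      (temperature_centered | individual_id), d, reml = TRUE)
  m5 <- fit_lmer_quiet(
    value_transformed ~ temperature_centered +
      (temperature_centered || individual_id), d, reml = TRUE)
  l34 <- lrt(m3$fit, m4$fit, df = 2)
  if (boundary_mixture) {
    # equal mixture of chi-square(1) and chi-square(2) at the variance
    # boundary
    l34$p <- 0.5 * stats::pchisq(l34$chisq, 1, lower.tail = FALSE) +
      0.5 * stats::pchisq(l34$chisq, 2, lower.tail = FALSE)
  }
  l45 <- lrt(m5$fit, m4$fit, df = 1)
  corr <- ranef_correlation(m4$fit)
  re <- lme4::ranef(m4$fit)$individual_id
  fe <- lme4::fixef(m4$fit)
  blups <- data.frame(
    individual_id = rownames(re),
    intercept = fe[["(Intercept)"]] + re[["(Intercept)"]],
    slope = fe[["temperature_centered"]] + re[["temperature_centered"]],
    stringsAsFactors = FALSE)
  list(n_individuals = length(unique(d$individual_id)),
       model3 = model_summary(m3), model4 = model_summary(m4),
       model5 = model_summary(m5),
       lrt_3v4 = l34, lrt_4v5 = l45,
       slope_intercept_corr = corr,
       corr_boundary = is.finite(corr) && abs(corr) > 0.999,
       blups = blups,
       fit4 = m4$fit)
}

#' Slope-intercept correlation with a 95% confidence interval
#'
#' Extracts the correlation between individual random intercepts and random
#' slopes from a converged random-slope fit (model 4 of the ladder) and
#' computes a 95% confidence interval, by profile likelihood (default) or
#' by parametric bootstrap. Estimates pinned at +/-1 (singular covariance)
#' are flagged as boundary cases.
#'
#' @param group A group element of a [fit_ladder()] result (or an `lmerMod`
#'   random-slope fit).
#' @param method `"profile"` or `"parametric_bootstrap"`.
#' @param n_boot Bootstrap replicates (bootstrap method only).
#' @param seed Integer seed for the bootstrap.
#' @return List with `estimate`, `ci` (length 2), `method` and `boundary`.
#' @export
slope_intercept_correlation <- function(group,
                                        method = c("profile",
                                                   "parametric_bootstrap"),
                                        n_boot = 500, seed = 1) {
  method <- match.arg(method)
  fit <- if (inherits(group, "lmerMod")) group else group$fit4
  est <- ranef_correlation(fit)
  boundary <- is.finite(est) && abs(est) > 0.999
  ci <- c(NA_real_, NA_real_)
  if (method == "profile") {
    prof <- tryCatch(
      suppressWarnings(suppressMessages(
        stats::confint(fit, method = "profile", oldNames = FALSE,
                       quiet = TRUE))),
      error = function(e) NULL)
    if (!is.null(prof)) {
      row <- grep("^cor_", rownames(prof))
      if (length(row) == 1L) ci <- unname(prof[row, ])
    }
    if (anyNA(ci)) boundary <- TRUE
  } else {
    set.seed(seed)
    sims <- stats::simulate(fit, nsim = n_boot)
    vals <- vapply(seq_len(n_boot), function(b) {
      ref <- tryCatch(suppressWarnings(suppressMessages(
        lme4::refit(fit, sims[[b]]))), error = function(e) NULL)
      if (is.null(ref)) NA_real_ else ranef_correlation(ref)
    }, 0)
    ci <- unname(stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE))
  }
  list(estimate = est, ci = ci, method = method, boundary = boundary)
}

#' Repeatability of a metric within a treatment
#'
#' Intra-class correlation from a Gaussian random-intercept model fitted to
#' replicate measurements: `R = var_ID / (var_ID + var_residual)`. The 95%
#' confidence interval comes from parametric-bootstrap refits (simulate new
#' responses from the fitted model, refit, recompute R).
#'
#' @param data A `long_measurements` table for one metric (replicates
#'   present). One repeatability is computed per treatment level.
#' @param n_boot Number of parametric bootstrap replicates (default 1000;
#'   `0` skips the interval and returns `NA` bounds).
#' @param seed Integer seed.
#' @return Data frame with one row per treatment: `metric`, `treatment`,
#'   `R`, `ci_lo`, `ci_hi`, `n_boot`, `seed`.
#' @export
repeatability <- function(data, n_boot = 1000, seed = 1) {
  if (length(unique(data$metric)) > 1L) {
    stop("repeatability expects data for a single metric")
  }
  treatments <- unique(data$treatment)
  rows <- lapply(treatments, function(tr) {
    d <- data[data$treatment == tr, ]
    if (length(unique(d$individual_id)) < 2L) {
      stop("repeatability needs at least two individuals in treatment ", tr)
    }
    if (max(table(d$individual_id)) < 2L) {
      stop("repeatability needs replicate measurements in treatment ", tr)
    }
    fit <- fit_lmer_quiet(value_transformed ~ 1 + (1 | individual_id),
                          d, reml = TRUE)$fit
    r_of <- function(f) {
      vc <- as.data.frame(lme4::VarCorr(f))
      v_id <- vc$vcov[vc$grp == "individual_id"]
      v_res <- vc$vcov[vc$grp == "Residual"]
      v_id / (v_id + v_res)
    }
    if (n_boot > 0) {
      set.seed(seed)
      sims <- stats::simulate(fit, nsim = n_boot)
      boots <- vapply(seq_len(n_boot), function(b) {
        ref <- tryCatch(suppressWarnings(suppressMessages(
          lme4::refit(fit, sims[[b]]))), error = function(e) NULL)
        if (is.null(ref)) NA_real_ else r_of(ref)
      }, 0)
      ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(metric = d$metric[1L], treatment = tr, R = r_of(fit),
               ci_lo = unname(ci[1L]), ci_hi = unname(ci[2L]),
               n_boot = n_boot, seed = seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-temperature rank preservation (Spearman)
#'
#' Spearman rank correlation between per-individual metric values measured
#' in two environments, quantifying how well a metric conserves the
#' individuals' relative ordering. Ties receive average ranks; `S` is the
#' sum of squared rank differences; the p-value is exact for `n <= 9`
#' without ties and uses the t approximation otherwise.
#'
#' @param cold,warm Named numeric vectors of per-individual values (names
#'   are individual ids); every individual must appear in both.
#' @return List with `n`, `S`, `rho`, `p` and `method`.
#' @export
rank_preservation <- function(cold, warm) {
  if (is.null(names(cold)) || is.null(names(warm))) {
    stop("cold and warm must be named by individual")
  }
  unpaired <- c(setdiff(names(cold), names(warm)),
                setdiff(names(warm), names(cold)))
  if (length(unpaired)) {
    stop("unpaired individual(s): ", paste(unique(unpaired), collapse = ", "))
  }
  warm <- warm[names(cold)]
  n <- length(cold)
  if (n < 3L) stop("at least three paired individuals are required")
  ties <- anyDuplicated(cold) || anyDuplicated(warm)
  exact <- n <= 9L && !ties
  ct <- suppressWarnings(
    stats::cor.test(cold, warm, method = "spearman", exact = exact))
  list(n = n, S = unname(ct$statistic), rho = unname(ct$estimate),
       p = ct$p.value,
       method = if (exact) "exact" else "t-approximation")
}

per_individual_means <- function(data, treatment) {
  d <- data[data$treatment == treatment, ]
  tapply(d$value, d$individual_id, mean)
}

#' Compare saturation metrics across temperature environments
#'
#' Runs the full statistical framework for every metric present in a long
#' measurement table: the reaction-norm ladder (with the sex-interaction
#' test and per-sex split), the slope-intercept correlation, and the
#' cross-temperature Spearman rank preservation of per-individual means.
#'
#' @param long A `long_measurements` table covering one or more metrics.
#' @param treatments Character vector of the two treatment levels, ordered
#'   (reference first), default `c("cold", "warm")`.
#' @param ci_method Confidence-interval method for the slope-intercept
#'   correlation (see [slope_intercept_correlation()]), or `"none"` to skip
#'   CI computation.
#' @param seed Integer seed (bootstrap CI method only).
#' @return A `metric_comparison` report: data frame with one row per metric
#'   x group, holding the three likelihood-ratio records, the
#'   slope-intercept correlation (with CI when requested), Spearman `S`,
#'   `rho` and `p`, and convergence flags; sorted by `rho` (descending)
#'   within group.
#' @export
metric_comparison_report <- function(long, treatments = c("cold", "warm"),
                                     ci_method = "none", seed = 1) {
  metrics <- unique(long$metric)
  rows <- list()
  for (met in metrics) {
    d <- long[long$metric == met, ]
    ladder <- tryCatch(fit_ladder(d), error = function(e) e)
    if (inherits(ladder, "error")) {
      rows[[length(rows) + 1L]] <- report_row(
        met, "all", NULL, NULL, NULL, flag = conditionMessage(ladder))
      next
    }
    for (grp in names(ladder$groups)) {
      g <- ladder$groups[[grp]]
      dg <- if (grp %in% c("M", "F")) d[d$sex %in% grp, ] else d
      rk <- tryCatch({
        cold <- per_individual_means(dg, treatments[1L])
        warm <- per_individual_means(dg, treatments[2L])
        rank_preservation(cold, warm)
      }, error = function(e) NULL)
      ci <- if (identical(ci_method, "none")) {
        list(estimate = g$slope_intercept_corr, ci = c(NA, NA),
             boundary = g$corr_boundary)
      } else {
        slope_intercept_correlation(g, method = ci_method, seed = seed)
      }
      flag <- paste(unique(c(g$model3$messages, g$model4$messages,
                             g$model5$messages)), collapse = "; ")
      rows[[length(rows) + 1L]] <- report_row(met, grp, ladder$lrt_1v2,
                                              g, rk, ci, flag)
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(out$group, -ifelse(is.na(out$spearman_rho), -Inf,
                                  out$spearman_rho))
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("metric_comparison", "data.frame")
  out
}

report_row <- function(metric, group, l12, g, rk, ci = NULL, flag = "") {
  data.frame(
    metric = metric, group = group,
    chisq_1v2 = if (is.null(l12)) NA_real_ else l12$chisq,
    p_1v2 = if (is.null(l12)) NA_real_ else l12$p,
    chisq_3v4 = if (is.null(g)) NA_real_ else g$lrt_3v4$chisq,
    p_3v4 = if (is.null(g)) NA_real_ else g$lrt_3v4$p,
    chisq_4v5 = if (is.null(g)) NA_real_ else g$lrt_4v5$chisq,
    p_4v5 = if (is.null(g)) NA_real_ else g$lrt_4v5$p,
    slope_intercept_corr = if (is.null(ci)) NA_real_ else ci$estimate,
    corr_ci_lo = if (is.null(ci)) NA_real_ else ci$ci[1L],
    corr_ci_hi = if (is.null(ci)) NA_real_ else ci$ci[2L],
    corr_boundary = if (is.null(ci)) NA else isTRUE(ci$boundary),
    spearman_S = if (is.null(rk)) NA_real_ else rk$S,
    spearman_rho = if (is.null(rk)) NA_real_ else rk$rho,
    spearman_p = if (is.null(rk)) NA_real_ else rk$p,
    flags = flag, stringsAsFactors = FALSE)
}
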