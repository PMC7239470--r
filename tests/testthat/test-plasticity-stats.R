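test_that("build_long centres temperature and log-transforms values", {
  panel <- data.frame(
    individual_id = c("a", "a"), sex = "M", treatment = c("cold", "warm"),
    body_temperature = c(23, 33), replicate = "r1", metric = "S3",
    value = c(exp(1), exp(2)), band_lo = NA, band_hi = NA,
    stringsAsFactors = FALSE)
  long <- build_long(panel, "log_e")
  expect_equal(long$value_transformed, c(1, 2))
  expect_equal(long$temperature_centered, c(-5, 5))

  panel$value[1] <- 0
  expect_error(build_long(panel, "log_e"), "positive")

  panel$value[1] <- 5
  panel$body_temperature <- NA
  long2 <- build_long(panel, "none", temperatures = c(cold = 20, warm = 30))
  expect_equal(long2$temperature, c(20, 30))
  expect_equal(long2$value_transformed, panel$value)
})

test_that("repeatability hits the variance-ratio boundaries", {
  ids <- rep(sprintf("i%02d", 1:10), each = 3)
  # identical replicates within individuals, individuals differ -> R = 1
  vals <- rep(rnorm(10), each = 3)
  d1 <- make_long(ids, "cold", vals)
  r1 <- repeatability(d1, n_boot = 0)
  expect_equal(r1$R, 1, tolerance = 1e-6)

  # no between-individual signal -> R near 0
  set.seed(1)
  ids30 <- rep(sprintf("i%02d", 1:30), each = 3)
  d0 <- make_long(ids30, "cold", rnorm(90))
  r0 <- repeatability(d0, n_boot = 0)
  expect_lte(r0$R, 0.05)

  expect_error(repeatability(make_long(rep("a", 3), "cold", 1:3),
                             n_boot = 0), "two individuals")
})

test_that("repeatability recovers a known intraclass correlation", {
  set.seed(99)
  ests <- replicate(20, {
    b <- rnorm(50, 0, sqrt(3))
    y <- rep(b, each = 3) + rnorm(150, 0, 1)
    d <- make_long(rep(sprintf("i%02d", 1:50), each = 3), "cold", y)
    repeatability(d, n_boot = 0)$R
  })
  expect_lt(abs(mean(ests) - 0.75), 0.05)
})

test_that("repeatability bootstrap interval brackets the estimate", {
  set.seed(5)
  b <- rnorm(30, 0, sqrt(3))
  y <- rep(b, each = 3) + rnorm(90, 0, 1)
  d <- make_long(rep(sprintf("i%02d", 1:30), each = 3), "cold", y)
  r <- repeatability(d, n_boot = 100, seed = 2)
  expect_true(r$ci_lo <= r$R && r$R <= r$ci_hi)
  expect_true(r$ci_lo >= 0 && r$ci_hi <= 1)
  # deterministic given the seed
  r2 <- repeatability(d, n_boot = 100, seed = 2)
  expect_equal(r, r2)
})

test_that("the ladder recovers random-slope structure when present", {
  sim <- simulate_metric_panel(n_males = 25, n_females = 25,
                               sd_slope = 0.04, corr = 0.9, seed = 21)
  lad <- fit_ladder(sim$data, by_sex = FALSE)
  g <- lad$groups$all
  expect_lt(g$lrt_3v4$p, 0.01)        # slopes clearly vary
  expect_gt(g$slope_intercept_corr, 0)
  expect_gte(g$lrt_3v4$chisq, 0)
  expect_gte(g$lrt_4v5$chisq, 0)
  # nesting: constrained model 5 cannot beat model 4
  expect_lte(g$model5$logLik, g$model4$logLik + 1e-8)
  expect_equal(g$lrt_3v4$df, 2)
  expect_equal(g$lrt_4v5$df, 1)
  # BLUP slopes track the simulated individual slopes
  m <- merge(g$blups, sim$truth, by = "individual_id")
  expect_gt(stats::cor(m$slope, m$slope_true), 0.7)
})

test_that("the ladder prefers the random-intercept model when slopes are equal", {
  hits <- vapply(1:30, function(i) {
    sim <- simulate_metric_panel(sd_slope = 0, corr = 0, seed = 1000 + i)
    lad <- fit_ladder(sim$data, by_sex = FALSE)
    lad$groups$all$lrt_3v4$p > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the sex-interaction test runs on maximum-likelihood fits", {
  sim <- simulate_metric_panel(interaction = 0.05, seed = 77)
  lad <- fit_ladder(sim$data, groups = FALSE)
  expect_lt(lad$lrt_1v2$p, 0.05)
  expect_equal(lad$lrt_1v2$df, 1)
  expect_length(lad$groups, 0L)
  lad2 <- fit_ladder(sim$data)
  expect_setequal(names(lad2$groups), c("M", "F"))
})

test_that("slope-intercept correlation hits the boundary on degenerate data", {
  # slope proportional to intercept deterministically
  ids <- sprintf("i%02d", 1:20)
  b0 <- rnorm(20)
  rows <- expand.grid(id = ids, tc = c(-5, 5), rep = 1:3)
  y <- b0[match(rows$id, ids)] * (1 + 0.1 * rows$tc) +
    rnorm(nrow(rows), 0, 1e-3)
  d <- make_long(rows$id, ifelse(rows$tc < 0, "cold", "warm"), y)
  d$temperature_centered <- rows$tc
  d$temperature <- rows$tc + 28
  lad <- fit_ladder(d, by_sex = FALSE)
  ci <- slope_intercept_correlation(lad$groups$all, method = "profile")
  expect_gt(ci$estimate, 0.99)
  expect_true(ci$boundary)
})

test_that("bootstrap confidence intervals cover a strong true correlation", {
  sim <- simulate_metric_panel(n_males = 30, n_females = 30,
                               sd_slope = 0.04, corr = 0.85, seed = 8)
  lad <- fit_ladder(sim$data, by_sex = FALSE)
  ci <- slope_intercept_correlation(lad$groups$all,
                                    method = "parametric_bootstrap",
                                    n_boot = 60, seed = 3)
  expect_gt(ci$estimate, 0)
  expect_true(ci$ci[1] <= ci$estimate && ci$estimate <= ci$ci[2])
})

test_that("rank preservation reproduces textbook Spearman results", {
  x <- stats::setNames(1:5, letters[1:5])
  same <- rank_preservation(x, x * 3)
  expect_equal(same$S, 0)
  expect_equal(same$rho, 1)

  y3 <- stats::setNames(1:3, letters[1:3])
  rev3 <- rank_preservation(y3, stats::setNames(3:1, letters[1:3]))
  expect_equal(rev3$S, 8)
  expect_equal(rev3$rho, -1)
  expect_equal(rev3$method, "exact")

  # permutation case against the rank-definition oracle
  perm <- c(3, 1, 4, 5, 2)
  got <- rank_preservation(x, stats::setNames(perm, letters[1:5]))
  S <- sum((rank(1:5) - rank(perm))^2)
  expect_equal(got$S, S)
  expect_equal(got$rho, 1 - 6 * S / (5^3 - 5))

  expect_error(rank_preservation(x, y3), "unpaired")
  expect_error(rank_preservation(y3[1:2], y3[1:2]), "three")
})

test_that("Spearman rho is invariant under monotone transforms", {
  set.seed(13)
  x <- stats::setNames(runif(12), sprintf("i%02d", 1:12))
  y <- stats::setNames(runif(12), sprintf("i%02d", 1:12))
  base <- rank_preservation(x, y)$rho
  expect_equal(rank_preservation(exp(3 * x), y)$rho, base)
  expect_equal(rank_preservation(x, y^3)$rho, base)
})

test_that("the comparison report keeps one row per metric and group", {
  sim <- simulate_metric_panel(seed = 4)
  long <- sim$data
  metrics <- c("S1B", "S1Sc", "S1ScFull", "S3", "S3Sc", "S8", "visual")
  all <- do.call(rbind, lapply(metrics, function(m) {
    d <- long
    d$metric <- m
    d
  }))
  class(all) <- class(long)
  rep <- metric_comparison_report(all)
  expect_equal(nrow(rep), 14L)
  expect_setequal(rep$group, c("M", "F"))
  expect_true(all(c("chisq_3v4", "slope_intercept_corr", "spearman_rho",
                    "flags") %in% names(rep)))
  # sorted by rho (descending) within group
  for (g in c("M", "F")) {
    rho <- rep$spearman_rho[rep$group == g]
    expect_true(all(diff(rho) <= 1e-12))
  }
})
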